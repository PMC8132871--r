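test_that("compute_dihedral reproduces the planar reference geometries", {
  p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 1, 0)
  expect_equal(compute_dihedral(p1, p2, p3, c(1, 1, 0)), 0)        # cis
  expect_equal(compute_dihedral(p1, p2, p3, c(-1, 1, 0)), pi)      # trans
  expect_equal(compute_dihedral(p1, p2, p3, c(0, 1, 1)), -pi / 2)  # IUPAC sign
})

test_that("compute_dihedral agrees with brute-force rotation about the bond axis", {
  # Start from a cis configuration and rotate p4 about the p2->p3 axis by a
  # known angle phi (Rodrigues, right-handed about the axis): under the
  # clockwise-positive-looking-p2->p3 convention the measured dihedral is phi.
  set.seed(41)
  for (i in 1:25) {
    p2 <- rnorm(3); axis <- rnorm(3)
    p3 <- p2 + axis
    # build p1, p4 off-axis
    perp <- cross3_oracle(axis, rnorm(3)); perp <- perp / sqrt(sum(perp^2))
    p1 <- p2 + perp * runif(1, 0.5, 2)
    p4_cis <- p3 + perp * runif(1, 0.5, 2)
    phi <- runif(1, -pi + 0.01, pi - 0.01)
    p4 <- rotate_about_axis(p4_cis, p3, axis, phi)
    expect_equal(compute_dihedral(p1, p2, p3, p4), phi, tolerance = 1e-9)
  }
})

test_that("compute_dihedral matches an established trajectory-analysis implementation", {
  set.seed(7)
  for (i in 1:20) {
    pts <- matrix(runif(12, -2, 2), 4, 3, byrow = TRUE)
    ref_deg <- bio3d::torsion.xyz(as.vector(t(pts)), atm.inc = 4)
    ours <- compute_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(ours, ref_deg * pi / 180, tolerance = 1e-6)
  }
})

test_that("compute_dihedral is invariant under rigid motion and chain reversal", {
  # chain reversal flips both plane normals and the reference axis, so the
  # IUPAC torsion angle is unchanged: chi(ABCD) = chi(DCBA)
  set.seed(11)
  for (i in 1:20) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3, byrow = TRUE)
    ang <- try(compute_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
               silent = TRUE)
    if (inherits(ang, "try-error")) next
    moved <- random_rigid_motion(pts)
    expect_equal(compute_dihedral(moved[1, ], moved[2, ], moved[3, ], moved[4, ]),
                 ang, tolerance = 1e-9)
    expect_equal(compute_dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ]),
                 ang, tolerance = 1e-9)
  }
})

test_that("compute_dihedral rejects degenerate geometry", {
  o <- c(0, 0, 0)
  expect_error(compute_dihedral(o, o, c(0, 1, 0), c(1, 1, 0)),
               class = "desp_geometry_error")
  expect_error(compute_dihedral(c(1, 0, 0), o, c(2, 0, 0), c(1, 1, 0)),
               class = "desp_geometry_error")
})

test_that("identify_dihedrals enumerates backbone and chi1 quadruples", {
  # 3-residue Ala-Val-Ala: 2 omega, 2 phi, 2 psi, 1 chi1 (Val only)
  specs <- identify_dihedrals(make_topology(c("ALA", "VAL", "ALA")))
  kinds <- vapply(specs, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "omega"), 2L)
  expect_equal(sum(kinds == "phi"), 2L)
  expect_equal(sum(kinds == "psi"), 2L)
  expect_equal(sum(kinds == "chi1"), 1L)
  chi <- specs[[which(kinds == "chi1")]]
  expect_equal(chi$residue_index, 1L)  # 0-based: Val is residue 1

  # 12-residue all-Ala chain: 11 omega + 11 phi + 11 psi + 0 chi1 = 33
  specs12 <- identify_dihedrals(make_topology(rep("ALA", 12)))
  expect_length(specs12, 33L)

  # single Gly with no neighbors: no complete quadruple exists
  expect_length(identify_dihedrals(make_topology("GLY")), 0L)

  # deterministic ordering: residue index, then omega, phi, psi, chi1
  ord <- vapply(specs, function(s)
    s$residue_index * 4 + match(s$kind, c("omega", "phi", "psi", "chi1")),
    numeric(1))
  expect_false(is.unsorted(ord))
})

test_that("a missing atom skips its dihedral with a warning, never renumbers", {
  topo <- make_topology(c("ALA", "VAL", "ALA"))
  topo <- topo[!(topo$resno == 2 & topo$atom == "CA"), ]
  warns <- capture_warnings(specs <- identify_dihedrals(topo))
  expect_true(any(grepl("missing atom", warns)))
  kinds <- vapply(specs, `[[`, character(1), "kind")
  # residue 2's CA participates in omega2, phi2, psi2, chi1(Val), omega3
  expect_equal(unname(table(kinds)["psi"]), 1L)
  expect_false("chi1" %in% kinds)
})

test_that("encode/decode are exact inverses on (-pi, pi]", {
  expect_equal(encode_features(matrix(0))[1, ], c(1, 0))
  expect_equal(encode_features(matrix(pi / 2))[1, ], c(0, 1))
  expect_equal(encode_features(matrix(pi))[1, ], c(-1, 0),
               tolerance = 1e-15)
  expect_equal(decode_angles(matrix(c(1, 0), 1))$angles[1, 1], 0)
  expect_equal(decode_angles(matrix(c(0, -1), 1))$angles[1, 1], -pi / 2)
  expect_equal(decode_angles(matrix(c(0.6, 0.8), 1))$angles[1, 1],
               atan2(0.8, 0.6))

  set.seed(5)
  ang <- matrix(runif(200 * 6, -pi, pi), 200, 6)
  ang[ang == -pi] <- pi
  traj <- angle_trajectory(ang)
  feats <- encode_features(traj)
  # unit-circle invariant per pair
  D <- ncol(ang)
  expect_true(all(abs(feats[, 2 * (1:D) - 1]^2 + feats[, 2 * (1:D)]^2 - 1) <
                    1e-12))
  expect_equal(decode_angles(feats)$angles, ang, tolerance = 1e-9)
})

test_that("decode_angles flags undefined angles and odd column counts", {
  expect_error(decode_angles(matrix(c(1e-13, 1e-13), 1)),
               class = "desp_geometry_error")
  expect_error(decode_angles(matrix(1, 1, 3)), "even")
})

test_that("angle TSV round-trips a trajectory with spec comments", {
  specs <- identify_dihedrals(make_topology(c("ALA", "VAL", "ALA")))
  set.seed(3)
  ang <- matrix(runif(4 * length(specs), -pi, pi), 4)
  traj <- angle_trajectory(ang, specs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_angle_tsv(traj, path)
  back <- read_angle_tsv(path)
  expect_equal(back$angles, ang, tolerance = 1e-12)
  expect_match(attr(back, "spec_labels")[1], "psi:0")  # residue 0 has only psi
})

test_that("dihedral angles extracted from a multi-model PDB match bio3d's torsions", {
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  # two-model 3-Ala helix-ish synthetic structure written by hand
  set.seed(19)
  topo <- make_topology(c("ALA", "ALA", "ALA"))
  write_model <- function(con, xyz, model) {
    cat(sprintf("MODEL     %4d\n", model), file = con)
    for (i in seq_len(nrow(topo))) {
      cat(sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00\n",
        i, topo$atom[i], topo$resid[i], topo$resno[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3]), file = con)
    }
    cat("ENDMDL\n", file = con)
  }
  con <- file(pdb_path, "w")
  xyz1 <- matrix(rnorm(nrow(topo) * 3, sd = 3), ncol = 3)
  xyz2 <- xyz1 + matrix(rnorm(nrow(topo) * 3, sd = 0.3), ncol = 3)
  write_model(con, xyz1, 1); write_model(con, xyz2, 2)
  cat("END\n", file = con); close(con)

  s <- read_structure(pdb_path)
  expect_equal(nrow(s$coords), 2L)
  specs <- identify_dihedrals(s$topology)
  traj <- dihedral_trajectory(s$coords, specs)
  expect_equal(nrow(traj$angles), 2L)
  # cross-check one phi against bio3d directly
  phi_spec <- specs[[which(vapply(specs, `[[`, character(1), "kind") == "phi")[1]]]
  idx <- phi_spec$atom_indices + 1L
  parsed1 <- matrix(s$coords[1, ], ncol = 3, byrow = TRUE)  # as-parsed precision
  ref <- bio3d::torsion.xyz(as.vector(t(parsed1[idx, ])), atm.inc = 4) * pi / 180
  expect_equal(traj$angles[1, which(vapply(specs, `[[`, character(1),
                                           "kind") == "phi")[1]],
               ref, tolerance = 1e-6)
})
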