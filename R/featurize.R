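## Dihedral featurization: extract omega/phi/psi/chi1 dihedral angles from
## protein structures and encode angle trajectories as interleaved cos/sin
## feature matrices (the VAE's input representation).

#' Fourth atom of the chi1 dihedral per residue type
#'
#' For each standard amino acid possessing a chi1 angle, the heavy atom that
#' completes the N-CA-CB-X quadruple. Glycine and alanine have no chi1 and are
#' absent. Stored as data so alternative conventions can be swapped in.
#'
#' @format Named character vector, names are three-letter residue codes.
#' @export
chi1_fourth_atom <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1"
)

dihedral_kinds <- c("omega", "phi", "psi", "chi1")

#' Construct a dihedral specification
#'
#' @param kind one of `"omega"`, `"phi"`, `"psi"`, `"chi1"`.
#' @param residue_index 0-based index of the residue owning the angle.
#' @param atom_indices integer vector of four distinct 0-based atom indices,
#'   ordered p1..p4 along the dihedral.
#' @return A `dihedral_spec` object.
#' @export
dihedral_spec <- function(kind, residue_index, atom_indices) {
  kind <- match.arg(kind, dihedral_kinds)
  check_number(residue_index, "residue_index", lower = 0, integer = TRUE)
  if (length(atom_indices) != 4L || anyDuplicated(atom_indices))
    stop_desp("atom_indices must be 4 distinct indices")
  structure(list(kind = kind,
                 residue_index = as.integer(residue_index),
                 atom_indices = as.integer(atom_indices)),
            class = "dihedral_spec")
}

#' @export
format.dihedral_spec <- function(x, ...) {
  sprintf("%s:%d", x$kind, x$residue_index)
}

#' @export
print.dihedral_spec <- function(x, ...) {
  cat(format(x), " atoms [", paste(x$atom_indices, collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Signed dihedral angle of four points
#'
#' Returns the torsion angle about the p2-p3 axis in radians, in (-pi, pi],
#' following the IUPAC sign convention (positive clockwise looking from p2
#' toward p3; the cis arrangement is 0, trans is pi).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Cartesian coordinates).
#' @return Angle in radians in (-pi, pi].
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  eps <- 1e-12
  if (sum(b1^2) < eps || sum(b2^2) < eps || sum(b3^2) < eps)
    stop_desp("degenerate geometry: zero-length bond vector",
              class = "desp_geometry_error")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < eps || sum(n2^2) < eps)
    stop_desp("degenerate geometry: collinear points",
              class = "desp_geometry_error")
  m <- cross3(n1, n2)
  y <- sum(m * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  theta <- atan2(y, x)
  if (theta <= -pi) theta <- theta + TWO_PI
  theta
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Enumerate backbone and chi1 dihedrals of a protein topology
#'
#' Builds the atom quadruples for the omega, phi, psi, and chi1 dihedrals:
#' omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i), phi(i) = C(i-1)-N(i)-CA(i)-C(i),
#' psi(i) = N(i)-CA(i)-C(i)-N(i+1), chi1(i) = N-CA-CB-X with X from
#' [chi1_fourth_atom]. Terminal residues contribute only the dihedrals whose
#' atoms all exist; residues lacking a chi1 (Gly, Ala) contribute none. A
#' missing required atom skips that dihedral with a warning rather than
#' failing the run. Output is ordered by residue index, then omega, phi, psi,
#' chi1.
#'
#' @param topology data frame with one row per atom and columns `atom` (PDB
#'   atom name), `resno` (residue number, any monotone labelling), and
#'   optionally `resid` (three-letter residue code, required for chi1).
#' @return List of [dihedral_spec] objects (0-based atom/residue indices into
#'   the topology rows).
#' @export
identify_dihedrals <- function(topology) {
  need <- c("atom", "resno")
  if (!is.data.frame(topology) || !all(need %in% names(topology)))
    stop_desp("topology must be a data frame with columns atom, resno")
  res_levels <- unique(topology$resno)
  nres <- length(res_levels)
  ridx <- match(topology$resno, res_levels)  # 1..nres, order of appearance

  ## atom lookup: 0-based row index of a named atom in residue i (1-based)
  find_atom <- function(i, name) {
    if (i < 1L || i > nres) return(NA_integer_)
    hit <- which(ridx == i & topology$atom == name)
    if (length(hit) == 0L) NA_integer_ else hit[1L] - 1L
  }

  specs <- list()
  for (i in seq_len(nres)) {
    resname <- if ("resid" %in% names(topology))
      topology$resid[match(i, ridx)] else NA_character_
    quads <- list(
      omega = c(find_atom(i - 1L, "CA"), find_atom(i - 1L, "C"),
                find_atom(i, "N"), find_atom(i, "CA")),
      phi   = c(find_atom(i - 1L, "C"), find_atom(i, "N"),
                find_atom(i, "CA"), find_atom(i, "C")),
      psi   = c(find_atom(i, "N"), find_atom(i, "CA"),
                find_atom(i, "C"), find_atom(i + 1L, "N")),
      chi1  = if (!is.na(resname) && resname %in% names(chi1_fourth_atom))
        c(find_atom(i, "N"), find_atom(i, "CA"), find_atom(i, "CB"),
          find_atom(i, chi1_fourth_atom[[resname]]))
      else NULL
    )
    for (kind in dihedral_kinds) {
      q <- quads[[kind]]
      if (is.null(q)) next
      boundary <- (kind == "omega" || kind == "phi") && i == 1L ||
        kind == "psi" && i == nres
      if (anyNA(q)) {
        if (!boundary)
          warning(sprintf("residue %d (%s): missing atom, skipping %s",
                          i - 1L, resname, kind), call. = FALSE)
        next
      }
      specs[[length(specs) + 1L]] <-
        dihedral_spec(kind, i - 1L, q)
    }
  }
  specs
}

#' Construct an angle trajectory
#'
#' @param angles T x D numeric matrix of dihedral angles in radians; every
#'   entry must lie in (-pi, pi].
#' @param specs optional list of D [dihedral_spec] objects naming the columns.
#' @return An `angle_trajectory` object.
#' @export
angle_trajectory <- function(angles, specs = NULL) {
  angles <- as.matrix(angles)
  if (!is.numeric(angles) || nrow(angles) < 1L || ncol(angles) < 1L)
    stop_desp("angles must be a non-empty numeric matrix")
  if (any(!is.finite(angles)))
    stop_desp("angles must be finite")
  if (any(angles <= -pi - 1e-12) || any(angles > pi + 1e-12))
    stop_desp("angles must lie in (-pi, pi]")
  if (!is.null(specs) && length(specs) != ncol(angles))
    stop_desp("specs length must equal the number of angle columns")
  structure(list(angles = unname(angles), specs = specs),
            class = "angle_trajectory")
}

#' @export
print.angle_trajectory <- function(x, ...) {
  cat(sprintf("angle_trajectory: %d frames x %d dihedrals\n",
              nrow(x$angles), ncol(x$angles)))
  invisible(x)
}

#' @export
dim.angle_trajectory <- function(x) dim(x$angles)

#' Compute a dihedral-angle trajectory from Cartesian frames
#'
#' @param coords T x (3 natoms) matrix of coordinates (bio3d `xyz` layout:
#'   x1, y1, z1, x2, ...) or a numeric vector for a single frame.
#' @param specs list of [dihedral_spec] objects (0-based atom indices).
#' @return An [angle_trajectory] with one column per spec.
#' @export
dihedral_trajectory <- function(coords, specs) {
  if (is.vector(coords)) coords <- matrix(coords, nrow = 1L)
  if (length(specs) == 0L) stop_desp("no dihedral specs supplied")
  T_ <- nrow(coords)
  ang <- matrix(NA_real_, T_, length(specs))
  for (t in seq_len(T_)) {
    xyz <- matrix(coords[t, ], ncol = 3L, byrow = TRUE)
    for (j in seq_along(specs)) {
      a <- specs[[j]]$atom_indices + 1L
      ang[t, j] <- compute_dihedral(xyz[a[1], ], xyz[a[2], ],
                                    xyz[a[3], ], xyz[a[4], ])
    }
  }
  angle_trajectory(ang, specs)
}

#' Read a (possibly multi-model) PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] returning the atom topology and the
#' per-model coordinate matrix in the layout [dihedral_trajectory()] expects.
#'
#' @param path PDB file.
#' @return List with `topology` (data frame: atom, resno, resid, chain) and
#'   `coords` (models x 3*natoms matrix).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  topology <- data.frame(atom = atom$elety, resno = atom$resno,
                         resid = atom$resid, chain = atom$chain,
                         stringsAsFactors = FALSE)
  coords <- pdb$xyz
  if (is.vector(coords)) coords <- matrix(coords, nrow = 1L)
  list(topology = topology, coords = unclass(coords))
}

#' Encode angles as interleaved cos/sin features
#'
#' Maps a T x D angle matrix to the T x 2D feature matrix
#' `[cos th1, sin th1, cos th2, sin th2, ...]` used as VAE input; the paired
#' representation removes the 2*pi discontinuity of raw angles.
#'
#' @param traj an [angle_trajectory] or a T x D angle matrix.
#' @return T x 2D numeric matrix of class `feature_matrix`.
#' @export
encode_features <- function(traj) {
  ang <- if (inherits(traj, "angle_trajectory")) traj$angles else as.matrix(traj)
  D <- ncol(ang)
  feats <- matrix(NA_real_, nrow(ang), 2L * D)
  feats[, 2L * seq_len(D) - 1L] <- cos(ang)
  feats[, 2L * seq_len(D)] <- sin(ang)
  class(feats) <- c("feature_matrix", class(feats))
  feats
}

#' Decode interleaved cos/sin features back to angles
#'
#' Inverse of [encode_features()] via `atan2(sin, cos)` per column pair. Rows
#' need not lie on the unit circle (VAE reconstructions generally do not); the
#' angle of the projection is returned. A pair with both components below
#' 1e-12 in magnitude has no defined angle and raises an error.
#'
#' @param features T x 2D feature matrix.
#' @return An [angle_trajectory].
#' @export
decode_angles <- function(features) {
  features <- as.matrix(features)
  if (ncol(features) %% 2L != 0L)
    stop_desp("feature matrix must have an even number of columns")
  D <- ncol(features) %/% 2L
  cosm <- features[, 2L * seq_len(D) - 1L, drop = FALSE]
  sinm <- features[, 2L * seq_len(D), drop = FALSE]
  if (any(abs(cosm) < 1e-12 & abs(sinm) < 1e-12))
    stop_desp("undefined angle: cos and sin components both ~0",
              class = "desp_geometry_error")
  ang <- atan2(sinm, cosm)
  ang[ang <= -pi] <- pi  # atan2(-0, x<0) returns -pi; canonical form is +pi
  angle_trajectory(ang)
}

#' Write an angle trajectory as TSV
#'
#' Header `theta_1 .. theta_D`, one row per frame, radians. Dihedral specs,
#' when present, are recorded as leading `# kind:residue` comment lines.
#'
#' @param traj an [angle_trajectory].
#' @param path output file.
#' @export
write_angle_tsv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$specs))
    writeLines(paste0("# ", vapply(traj$specs, format, character(1))), con)
  D <- ncol(traj$angles)
  writeLines(paste(sprintf("theta_%d", seq_len(D)), collapse = "\t"), con)
  utils::write.table(format(traj$angles, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an angle trajectory TSV written by [write_angle_tsv()]
#'
#' @param path input file.
#' @return An [angle_trajectory] (specs, if present in comments, are restored
#'   as kind/residue pairs without atom indices).
#' @export
read_angle_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) stop_desp("angle TSV has no data rows")
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(grepl("^theta_\\d+$", header)))
    stop_desp("malformed angle TSV header: ", body[1L])
  dat <- utils::read.delim(text = body, sep = "\t", check.names = FALSE)
  traj <- angle_trajectory(wrap_angle(as.matrix(dat)))
  attr(traj, "spec_labels") <- sub("^# ", "", meta)
  traj
}
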