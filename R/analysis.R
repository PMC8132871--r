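## Trajectory analysis: dihedral PCA on cos/sin features, radius of
## gyration, and RMSD with optimal rigid superposition (Kabsch) -- the
## collective variables used to map sampled conformation spaces.

#' Dihedral principal component analysis
#'
#' PCA of the mean-centered (unscaled) cos/sin feature matrix. Operating on
#' the circular features rather than raw angles avoids periodicity
#' artifacts. Component signs are fixed by making each component's
#' largest-magnitude entry positive, so results are deterministic.
#'
#' @param features T x 2D feature matrix (see [encode_features()]).
#' @param n_components number of leading components to project onto.
#' @return A `dpca_result`: `components` (2D x n orthonormal matrix),
#'   `eigenvalues` (all 2D, non-increasing), `projections`
#'   (T x n_components scores).
#' @export
dpca <- function(features, n_components = 2L) {
  X <- as.matrix(features)
  if (nrow(X) < 2L) stop_desp("dpca needs at least 2 frames")
  check_number(n_components, "n_components", lower = 1, integer = TRUE)
  if (n_components > ncol(X))
    stop_desp("n_components exceeds the feature dimension",
              class = "desp_config_error")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2L, flip, "*")
  scores <- sweep(pc$x, 2L, flip, "*")
  structure(list(components = rot[, seq_len(n_components), drop = FALSE],
                 eigenvalues = eig,
                 projections = scores[, seq_len(n_components), drop = FALSE],
                 center = pc$center),
            class = "dpca_result")
}

#' @export
print.dpca_result <- function(x, ...) {
  cat(sprintf("dpca_result: %d components, leading eigenvalues %s\n",
              ncol(x$components),
              paste(signif(utils::head(x$eigenvalues, 3), 4),
                    collapse = ", ")))
  invisible(x)
}

#' Export dPCA projections and eigenvalues as TSV
#'
#' @param res a [dpca()] result.
#' @param proj_path output file for (frame, pc1..pcK).
#' @param eig_path optional output file for (component, eigenvalue).
#' @export
write_dpca_tsv <- function(res, proj_path, eig_path = NULL) {
  proj <- as.data.frame(res$projections)
  names(proj) <- paste0("pc", seq_len(ncol(proj)))
  utils::write.table(cbind(frame = seq_len(nrow(proj)) - 1L, proj),
                     proj_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(eig_path))
    utils::write.table(data.frame(component = seq_along(res$eigenvalues),
                                  eigenvalue = res$eigenvalues),
                       eig_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(proj_path)
}

#' Radius of gyration of a coordinate frame
#'
#' Mass-weighted root-mean-square distance of the atoms from their center of
#' mass.
#'
#' @param coords natoms x 3 coordinate matrix (Angstrom).
#' @param masses per-atom masses; default all 1.
#' @return RoG in the coordinate units.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1L) stop_desp("empty coordinate frame")
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n)
    stop_desp("mass count must equal atom count", class = "desp_shape_error")
  M <- sum(masses)
  if (M <= 0) stop_desp("zero total mass")
  com <- colSums(coords * masses) / M
  d2 <- rowSums(sweep(coords, 2L, com)^2)
  sqrt(sum(masses * d2) / M)
}

#' RMSD between two coordinate frames
#'
#' With `superpose = TRUE` (default) the frame is first optimally aligned to
#' the reference by the Kabsch algorithm (mass-unweighted rigid rotation +
#' translation minimizing the RMSD); without, the raw deviation is returned.
#'
#' @param frame,reference natoms x 3 coordinate matrices with matching atom
#'   order.
#' @param superpose align before evaluating.
#' @return RMSD in the coordinate units.
#' @export
rmsd <- function(frame, reference, superpose = TRUE) {
  P <- as.matrix(frame); Q <- as.matrix(reference)
  if (!all(dim(P) == dim(Q)))
    stop_desp("atom-count mismatch", class = "desp_shape_error")
  if (superpose) P <- kabsch_align(P, Q)
  sqrt(mean(rowSums((P - Q)^2)))
}

## Optimal rigid superposition of P onto Q (Kabsch via SVD, unweighted).
kabsch_align <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P0 %*% t(R), 2L, cq, "+")
}

#' Per-frame collective-variable series from a coordinate trajectory
#'
#' @param coords T x (3 natoms) matrix (bio3d `xyz` layout).
#' @param fun per-frame function taking an natoms x 3 matrix, e.g.
#'   [radius_of_gyration()].
#' @param ... passed to `fun`.
#' @return numeric vector of length T.
#' @export
cv_series <- function(coords, fun, ...) {
  coords <- as.matrix(coords)
  vapply(seq_len(nrow(coords)), function(t)
    fun(matrix(coords[t, ], ncol = 3L, byrow = TRUE), ...), numeric(1))
}
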