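## Synthetic metastable dihedral dynamics: a hidden Markov chain over
## Ramachandran-like basins with independent von Mises noise per angle.
## Supplies ground-truth-labelled fixtures for the VAE, dPCA and loop tests.

#' Construct a basin model
#'
#' @param centers B x D matrix of basin-center angles in (-pi, pi].
#' @param concentration von Mises concentration kappa (> 0) shared by all
#'   angles; larger values give tighter basins.
#' @param transition B x B row-stochastic matrix of per-frame basin hopping
#'   probabilities.
#' @param initial_basin 1-based index of the starting basin.
#' @param seed integer seed for the generator.
#' @return A `basin_model` object.
#' @export
basin_model <- function(centers, concentration, transition,
                        initial_basin = 1L, seed = 1L) {
  centers <- as.matrix(centers)
  B <- nrow(centers)
  check_number(concentration, "concentration", lower = 1e-12)
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(B, B)))
    stop_desp("transition must be ", B, " x ", B)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12))
    stop_desp("transition rows must be non-negative and sum to 1")
  if (any(centers <= -pi) || any(centers > pi))
    stop_desp("centers must lie in (-pi, pi]")
  check_number(initial_basin, "initial_basin", lower = 1, upper = B,
               integer = TRUE)
  structure(list(centers = unname(centers), concentration = concentration,
                 transition = unname(transition),
                 initial_basin = as.integer(initial_basin),
                 seed = as.integer(seed)),
            class = "basin_model")
}

#' Two-basin model with Ramachandran-like centers
#'
#' The default fixture: basin A near the alpha-helical region (-60, -45
#' degrees alternating across dimensions) and basin B near the beta region
#' (-120, +130 degrees), kappa = 20, stay probability 0.995 per frame.
#'
#' @param D number of dihedral dimensions (>= 2).
#' @param seed integer seed.
#' @return A [basin_model] with 2 basins.
#' @export
default_two_basin_model <- function(D, seed = 1L) {
  check_number(D, "D", lower = 2, integer = TRUE)
  deg <- pi / 180
  a <- rep(c(-60, -45), length.out = D) * deg
  b <- rep(c(-120, 130), length.out = D) * deg
  P <- matrix(c(0.995, 0.005,
                0.005, 0.995), 2, 2, byrow = TRUE)
  basin_model(rbind(a, b), concentration = 20, transition = P,
              initial_basin = 1L, seed = seed)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; values are returned in (-pi, pi].
#'
#' @param n number of draws.
#' @param mu center (radians).
#' @param kappa concentration (> 0).
#' @return numeric vector of n angles.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5)[ok] * acos(f[ok])
    take <- min(length(th), n - got)
    if (take > 0L) out[(got + 1L):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  wrap_angle(out + mu)
}

#' Generate a labelled metastable angle trajectory
#'
#' Simulates the hidden basin path from the Markov chain, then draws each
#' frame's angles independently per dimension from von Mises(center, kappa).
#'
#' @param model a [basin_model].
#' @param T_ number of frames.
#' @return List with `trajectory` (an [angle_trajectory]) and `labels`
#'   (integer vector of the hidden basin path, 1-based).
#' @export
generate_basin_trajectory <- function(model, T_) {
  check_number(T_, "T", lower = 1, integer = TRUE)
  stream <- rng_stream_new(model$seed)
  res <- with_stream(stream, {
    B <- nrow(model$centers)
    D <- ncol(model$centers)
    labels <- integer(T_)
    labels[1L] <- model$initial_basin
    if (T_ > 1L) {
      u <- stats::runif(T_ - 1L)
      cum <- t(apply(model$transition, 1L, cumsum))
      for (t in 2:T_) {
        labels[t] <- which(u[t - 1L] <= cum[labels[t - 1L], ])[1L]
      }
    }
    ang <- matrix(NA_real_, T_, D)
    for (b in seq_len(B)) {
      idx <- which(labels == b)
      if (length(idx) == 0L) next
      for (d in seq_len(D)) {
        ang[idx, d] <- rvonmises(length(idx), model$centers[b, d],
                                 model$concentration)
      }
    }
    list(trajectory = angle_trajectory(ang), labels = labels)
  })
  res$value
}

#' Write basin labels as TSV (columns frame, basin)
#'
#' @param labels integer vector of basin labels.
#' @param path output file.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(data.frame(frame = seq_along(labels) - 1L,
                                basin = labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
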