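## Latent-space biasing: the KL divergence between the current conformation's
## latent Gaussian and those of previously sampled conformations defines a
## repulsive potential V_bias = (V_KL_upper / V_KL)^2; its exact gradient with
## respect to the dihedral angles (through the cos/sin featurization and the
## encoder) is the biasing force applied to the dynamics.

#' Bias configuration
#'
#' @param v_kl_upper scale parameter of the bias (energy^0 units of KL);
#'   default 1e-5. Setting it to 0 switches the bias off entirely.
#' @param n_representatives number K of pool frames drawn per bias update;
#'   default 32.
#' @param aggregation reduction of the per-representative KL divergences:
#'   `"min"` (default; the bias responds to the nearest visited state) or
#'   `"mean"`.
#' @param v_kl_floor lower clamp on V_KL before inversion (prevents blow-up
#'   when the current frame coincides with a pool frame); default 1e-12.
#' @param v_bias_cap upper clamp on the bias potential; default 1e6. In the
#'   clamped regimes the bias force is zero (the potential is constant).
#' @param energy_unit label for the energy scale; the toy backend works in
#'   multiples of k_B T.
#' @return A `bias_config`.
#' @export
bias_config <- function(v_kl_upper = 1e-5, n_representatives = 32L,
                        aggregation = c("min", "mean"), v_kl_floor = 1e-12,
                        v_bias_cap = 1e6, energy_unit = "kbt") {
  aggregation <- match.arg(aggregation)
  check_number(v_kl_upper, "v_kl_upper", lower = 0)
  check_number(n_representatives, "n_representatives", lower = 1,
               integer = TRUE)
  check_number(v_kl_floor, "v_kl_floor", lower = 1e-300)
  check_number(v_bias_cap, "v_bias_cap", lower = 1e-300)
  structure(list(v_kl_upper = v_kl_upper,
                 n_representatives = as.integer(n_representatives),
                 aggregation = aggregation, v_kl_floor = v_kl_floor,
                 v_bias_cap = v_bias_cap, energy_unit = energy_unit),
            class = "bias_config")
}

#' KL divergence between two diagonal Gaussians
#'
#' `D_KL(N0 || N1)` for `N0 = N(mu0, diag(s0^2))`, `N1 = N(mu1, diag(s1^2))`:
#' `0.5 * [sum s0^2/s1^2 + sum (mu1-mu0)^2/s1^2 - k + sum ln(s1^2/s0^2)]`.
#'
#' @param g0,g1 [latent_gaussian] objects of equal dimension.
#' @return Non-negative scalar, 0 iff the distributions coincide.
#' @export
kl_divergence_gaussians <- function(g0, g1) {
  if (length(g0$mean) != length(g1$mean))
    stop_desp("latent dimensions differ", class = "desp_shape_error")
  k <- length(g0$mean)
  0.5 * (sum(exp(g0$ln_var - g1$ln_var)) +
           sum((g1$mean - g0$mean)^2 * exp(-g1$ln_var)) -
           k + sum(g1$ln_var - g0$ln_var))
}

#' Aggregate the KL divergence of the current frame from pool representatives
#'
#' Computes `D_KL(current || rep)` for each representative and reduces by the
#' configured rule (default: minimum, i.e. the divergence from the nearest
#' previously visited latent state).
#'
#' @param current a [latent_gaussian].
#' @param reps non-empty list of [latent_gaussian] representatives.
#' @param config a [bias_config].
#' @return V_KL (scalar >= 0); attribute `"argmin"` holds the index of the
#'   minimizing representative (first index on ties) when aggregation is
#'   `"min"`.
#' @export
aggregate_kl <- function(current, reps, config) {
  if (length(reps) == 0L)
    stop_desp("empty representative set", class = "desp_config_error")
  kls <- vapply(reps, function(g) kl_divergence_gaussians(current, g),
                numeric(1))
  if (config$aggregation == "min") {
    i <- which.min(kls)
    structure(kls[i], argmin = i)
  } else {
    mean(kls)
  }
}

#' Biasing potential from the aggregated KL divergence
#'
#' `V_bias = (v_kl_upper / max(v_kl, v_kl_floor))^2`, capped at `v_bias_cap`;
#' monotone non-increasing in `v_kl`. With `v_kl_upper = 0` the bias is
#' identically zero.
#'
#' @param v_kl aggregated KL divergence (>= 0).
#' @param config a [bias_config].
#' @return V_bias (scalar in `[0, v_bias_cap]`).
#' @export
bias_potential <- function(v_kl, config) {
  if (config$v_kl_upper == 0) return(0)
  min((config$v_kl_upper / max(v_kl, config$v_kl_floor))^2,
      config$v_bias_cap)
}

#' Biasing force on the dihedral angles
#'
#' Exact gradient `-dV_bias/dtheta` of the composition angles -> cos/sin
#' features -> encoder -> KL divergence -> bias potential, using the argmin
#' representative under min-aggregation (first index at ties) or the average
#' of per-representative gradients under mean-aggregation. In the clamped
#' regimes (V_KL at the floor, V_bias at the cap, or `v_kl_upper = 0`) the
#' potential is locally constant and the force is the zero vector.
#'
#' @param model a trained `desp_vae`.
#' @param angles current D-vector of dihedral angles.
#' @param reps non-empty list of [latent_gaussian] representatives.
#' @param config a [bias_config].
#' @return D-vector of generalized forces; attributes `"v_kl"` and `"v_bias"`
#'   carry the potential bookkeeping for the bias record.
#' @export
bias_force <- function(model, angles, reps, config) {
  D <- model$config$d_dihedrals
  angles <- as.numeric(angles)
  if (length(angles) != D)
    stop_desp("angles length must equal d_dihedrals",
              class = "desp_shape_error")
  feats <- encode_features(matrix(angles, nrow = 1L))
  fwd <- encoder_forward(model, feats)
  current <- latent_gaussian(fwd$mu[1L, ], fwd$lv[1L, ])
  v_kl <- aggregate_kl(current, reps, config)
  v_bias <- bias_potential(as.numeric(v_kl), config)
  zero <- structure(numeric(D), v_kl = as.numeric(v_kl), v_bias = v_bias)
  if (config$v_kl_upper == 0) return(zero)
  if (as.numeric(v_kl) <= config$v_kl_floor) return(zero)
  raw <- (config$v_kl_upper / as.numeric(v_kl))^2
  if (raw >= config$v_bias_cap) return(zero)

  ## dV_bias / dV_KL = -2 * upper^2 / v_kl^3
  dv_dkl <- -2 * config$v_kl_upper^2 / as.numeric(v_kl)^3

  ## dV_KL / d(mu0, lv0): for D_KL(N0 || N1),
  ##   d/dmu0_i  = (mu0_i - mu1_i) / s1_i^2
  ##   d/dlv0_i  = 0.5 * (s0_i^2 / s1_i^2 - 1)
  kl_grad <- function(g1) {
    list(dmu = (current$mean - g1$mean) * exp(-g1$ln_var),
         dlv = 0.5 * (exp(current$ln_var - g1$ln_var) - 1))
  }
  if (config$aggregation == "min") {
    gr <- kl_grad(reps[[attr(v_kl, "argmin")]])
  } else {
    parts <- lapply(reps, kl_grad)
    gr <- list(dmu = Reduce(`+`, lapply(parts, `[[`, "dmu")) / length(reps),
               dlv = Reduce(`+`, lapply(parts, `[[`, "dlv")) / length(reps))
  }
  dX <- encoder_backward_input(model, fwd,
                               matrix(gr$dmu, nrow = 1L),
                               matrix(gr$dlv, nrow = 1L))[1L, ]
  ## features are (cos th_j, sin th_j): d/dth_j = -sin * dcos + cos * dsin
  j <- seq_len(D)
  dkl_dtheta <- dX[2L * j - 1L] * (-sin(angles)) + dX[2L * j] * cos(angles)
  force <- -dv_dkl * dkl_dtheta
  if (any(!is.finite(force)))
    stop_desp("non-finite bias force", class = "desp_numeric_error")
  structure(force, v_kl = as.numeric(v_kl), v_bias = v_bias)
}

#' Write / read a bias trajectory TSV (columns step, v_kl, v_bias)
#'
#' @param records data frame with columns `step`, `v_kl`, `v_bias`.
#' @param path file path.
#' @export
write_bias_tsv <- function(records, path) {
  stopifnot(all(c("step", "v_kl", "v_bias") %in% names(records)))
  utils::write.table(records[, c("step", "v_kl", "v_bias")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bias_tsv
#' @export
read_bias_tsv <- function(path) {
  dat <- utils::read.delim(path)
  if (!all(c("step", "v_kl", "v_bias") %in% names(dat)))
    stop_desp("malformed bias TSV: ", path)
  dat
}
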