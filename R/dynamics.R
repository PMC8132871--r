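## Toy dynamics backend: overdamped Langevin dynamics on periodic model
## potentials. This is the desk-scale stand-in for an MD engine: its
## stationary distribution is Boltzmann, its coordinates ARE the dihedral
## angles, so the latent-space bias force applies directly.

#' Periodic model potential on the D-torus
#'
#' A sum of cosine well terms, each acting on one coordinate:
#' `U_t(theta) = (height/2) * (1 - cos(mult * (theta - center)))`.
#'
#' @param terms data frame with columns `dim` (1-based coordinate index),
#'   `height` (> 0, energy units), `mult` (integer multiplicity; 2 gives a
#'   double well), `center` (radians).
#' @param D number of coordinates.
#' @return A `torus_potential` with `$energy(theta)` and `$gradient(theta)`.
#' @export
make_torus_potential <- function(terms, D) {
  stopifnot(is.data.frame(terms),
            all(c("dim", "height", "mult", "center") %in% names(terms)))
  if (any(terms$dim < 1) || any(terms$dim > D))
    stop_desp("term dim out of range")
  if (any(terms$height <= 0)) stop_desp("heights must be > 0")
  force(terms); force(D)
  energy <- function(theta) {
    sum(terms$height / 2 *
          (1 - cos(terms$mult * (theta[terms$dim] - terms$center))))
  }
  gradient <- function(theta) {
    g <- numeric(D)
    gt <- terms$height * terms$mult / 2 *
      sin(terms$mult * (theta[terms$dim] - terms$center))
    for (i in seq_len(nrow(terms))) g[terms$dim[i]] <- g[terms$dim[i]] + gt[i]
    g
  }
  structure(list(energy = energy, gradient = gradient, terms = terms, D = D),
            class = "torus_potential")
}

#' One-dimensional double-well potential
#'
#' `U(theta) = (barrier_height/2) * (1 - cos(2 * (theta - center)))`: minima
#' at `center` and `center + pi`, separated by barriers of height
#' `barrier_height`.
#'
#' @param center location of one minimum (radians).
#' @param barrier_height barrier between the two minima (> 0, energy units).
#' @return A [make_torus_potential()] object with D = 1.
#' @export
make_double_well <- function(center = 0, barrier_height = 1) {
  check_number(barrier_height, "barrier_height", lower = 1e-12)
  make_torus_potential(
    data.frame(dim = 1L, height = barrier_height, mult = 2, center = center),
    D = 1L)
}

#' Langevin integrator configuration
#'
#' @param dt time step (reduced units, > 0).
#' @param friction friction coefficient (> 0).
#' @param kbt thermal energy k_B T (> 0); the toy backend measures all
#'   energies in multiples of k_B T = 1 by default.
#' @param seed integer seed for the noise stream.
#' @return A `langevin_config`.
#' @export
langevin_config <- function(dt = 0.01, friction = 1, kbt = 1, seed = 1L) {
  check_number(dt, "dt", lower = 1e-12)
  check_number(friction, "friction", lower = 1e-12)
  check_number(kbt, "kbt", lower = 1e-300)
  structure(list(dt = dt, friction = friction, kbt = kbt,
                 seed = as.integer(seed)),
            class = "langevin_config")
}

#' Initialize a simulation state
#'
#' @param angles starting D-vector of angles (wrapped to (-pi, pi]).
#' @param cfg a [langevin_config]; its seed initializes the state's private
#'   noise stream.
#' @return A `sim_state` with fields `angles`, `step`, `rng_state`.
#' @export
sim_state <- function(angles, cfg) {
  structure(list(angles = wrap_angle(as.numeric(angles)), step = 0L,
                 rng_state = rng_stream_new(cfg$seed)),
            class = "sim_state")
}

check_stability <- function(pot, extra_force, cfg) {
  gmax <- sum(abs(pot$terms$height * pot$terms$mult) / 2) +
    max(abs(extra_force))
  if (cfg$dt * gmax / cfg$friction >= pi / 4)
    stop_desp("unstable step: dt * max|force| / friction = ",
              signif(cfg$dt * gmax / cfg$friction, 3),
              " must be well below pi", class = "desp_stability_error")
  invisible(TRUE)
}

## Internal: advance n steps under pot + constant extra force, consuming the
## state's private RNG stream. Returns list(state, frames matrix).
advance_langevin <- function(state, pot, extra_force, n_steps, save_every,
                             cfg) {
  D <- length(state$angles)
  if (length(extra_force) == 1L) extra_force <- rep(extra_force, D)
  if (length(extra_force) != D)
    stop_desp("extra_force length must match the coordinate count",
              class = "desp_shape_error")
  check_stability(pot, extra_force, cfg)
  res <- with_stream(state$rng_state,
    cpp_langevin_run(state$angles,
                     as.integer(pot$terms$dim) - 1L,
                     as.numeric(pot$terms$height),
                     as.numeric(pot$terms$mult),
                     as.numeric(pot$terms$center),
                     as.numeric(extra_force),
                     as.integer(n_steps), as.integer(save_every),
                     cfg$dt, cfg$friction, cfg$kbt))
  state$angles <- res$value$theta
  state$step <- state$step + as.integer(n_steps)
  state$rng_state <- res$state
  list(state = state, frames = res$value$frames)
}

#' Advance one overdamped Langevin step
#'
#' Euler-Maruyama update
#' `theta <- wrap(theta + (-grad U + extra_force) * dt / friction +
#' sqrt(2 kbt dt / friction) * xi)` with standard normal `xi` per coordinate
#' drawn from the state's seeded stream.
#'
#' @param state a [sim_state].
#' @param pot a [make_torus_potential()] object.
#' @param extra_force D-vector of additional generalized forces (e.g. the
#'   bias force); defaults to zero.
#' @param cfg a [langevin_config].
#' @return The updated `sim_state`.
#' @export
langevin_step <- function(state, pot, extra_force = NULL, cfg) {
  if (is.null(extra_force)) extra_force <- numeric(pot$D)
  advance_langevin(state, pot, extra_force, 1L, 0L, cfg)$state
}

#' Engine adapter contract
#'
#' The boundary a real dynamics engine must implement to drive the sampling
#' loop: `advance(n_steps, force_provider)` advances the engine's own
#' dynamics, calling `force_provider(current_angles)` at least once per
#' bias block and applying the returned generalized forces to its own
#' coordinates, returning saved frames as angle rows; `current_angles()`
#' reports the present D-vector of dihedral angles. How generalized
#' dihedral forces map onto the engine's native coordinates is the engine's
#' responsibility. Contract violations surface as classed adapter errors and
#' never corrupt the loop state.
#'
#' @param advance function(n_steps, force_provider) -> matrix of saved
#'   angle frames (possibly 0-row).
#' @param current_angles function() -> numeric D-vector.
#' @return An `engine_adapter` object.
#' @export
engine_adapter <- function(advance, current_angles) {
  if (!is.function(advance) || length(formals(advance)) < 2L)
    stop_desp("advance must be a function(n_steps, force_provider)",
              class = "desp_adapter_error")
  if (!is.function(current_angles))
    stop_desp("current_angles must be a function()",
              class = "desp_adapter_error")
  structure(list(advance = advance, current_angles = current_angles),
            class = "engine_adapter")
}

#' Run unbiased Langevin dynamics
#'
#' @param state a [sim_state].
#' @param pot a [make_torus_potential()] object.
#' @param n_steps total number of steps (a multiple of `save_every`).
#' @param save_every save a frame every this many steps.
#' @param cfg a [langevin_config].
#' @return List with `trajectory` (an [angle_trajectory] of
#'   `n_steps / save_every` frames, in order) and `state` (final
#'   [sim_state]).
#' @export
run_unbiased <- function(state, pot, n_steps, save_every, cfg) {
  check_number(n_steps, "n_steps", lower = 1, integer = TRUE)
  check_number(save_every, "save_every", lower = 1, integer = TRUE)
  if (n_steps %% save_every != 0L)
    stop_desp("n_steps must be a multiple of save_every",
              class = "desp_config_error")
  res <- advance_langevin(state, pot, numeric(pot$D), n_steps, save_every,
                          cfg)
  list(trajectory = angle_trajectory(res$frames), state = res$state)
}
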