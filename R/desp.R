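## The DESP loop: unbiased bootstrap -> initial VAE training -> biased
## stepping with periodic pool growth and VAE retraining -> bias bookkeeping.
##
## Counter semantics: n_short steps of unbiased dynamics seed the frame pool
## (one frame per n_saving steps); thereafter the dynamics advances in
## n_biasing-step blocks, each under a bias force computed once from the
## latent KL divergence of the current conformation to pool representatives,
## until n_completed reaches n_needed. The counters must satisfy
## n_biasing << n_saving << n_short << n_needed ("<<" = factor >= 10).

#' DESP run configuration
#'
#' @param n_needed total number of dynamics steps.
#' @param n_short length of the unbiased bootstrap phase (steps).
#' @param n_saving frame-saving cadence (steps).
#' @param n_biasing bias-update cadence (steps).
#' @param retrain_every retraining cadence in steps; default
#'   `n_saving * 100` (i.e. every 100 new pool frames).
#' @param retrain_subset maximum number of pool frames drawn (uniformly,
#'   without replacement) for each retraining; default 50000 (effectively the
#'   full pool at desk scale).
#' @param retrain_epochs epoch budget per retraining cycle; default 200.
#' @param bias a [bias_config].
#' @param vae a [vae_config] (its `d_dihedrals` must match the potential
#'   dimension).
#' @param langevin a [langevin_config] for the built-in toy backend.
#' @param potential a [make_torus_potential()] object.
#' @param start_angles initial D-vector of angles; default all zero.
#' @param seed global run seed; fans out to per-component streams
#'   (representative sampling, retraining subsets). The dynamics noise stream
#'   is owned by `langevin$seed` and the VAE streams by `vae$seed`.
#' @return A validated `desp_config`.
#' @export
desp_config <- function(n_needed, n_short, n_saving, n_biasing,
                        retrain_every = n_saving * 100, retrain_subset = 50000L,
                        retrain_epochs = 200L, bias = bias_config(),
                        vae, langevin = langevin_config(),
                        potential, start_angles = NULL, seed = 1L) {
  cfg <- structure(list(n_needed = as.double(n_needed),
                        n_short = as.double(n_short),
                        n_saving = as.double(n_saving),
                        n_biasing = as.double(n_biasing),
                        retrain_every = as.double(retrain_every),
                        retrain_subset = as.integer(retrain_subset),
                        retrain_epochs = as.integer(retrain_epochs),
                        bias = bias, vae = vae, langevin = langevin,
                        potential = potential,
                        start_angles = start_angles,
                        seed = as.integer(seed)),
                   class = "desp_config")
  validate_desp_config(cfg)
}

#' Validate a DESP configuration
#'
#' Checks the counter ordering (each ratio >= 10) and divisibility relations
#' together, reporting every violated relation in one error.
#'
#' @param cfg a `desp_config`.
#' @return The config, invisibly usable, if valid.
#' @export
validate_desp_config <- function(cfg) {
  bad <- character()
  rel <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  for (f in c("n_needed", "n_short", "n_saving", "n_biasing"))
    rel(is.finite(cfg[[f]]) && cfg[[f]] >= 1 && cfg[[f]] == round(cfg[[f]]),
        paste0(f, " must be a positive integer"))
  if (length(bad) == 0L) {
    rel(cfg$n_biasing * 10 <= cfg$n_saving, "n_biasing * 10 <= n_saving")
    rel(cfg$n_saving * 10 <= cfg$n_short, "n_saving * 10 <= n_short")
    rel(cfg$n_short * 10 <= cfg$n_needed, "n_short * 10 <= n_needed")
    rel(cfg$n_short %% cfg$n_saving == 0, "n_short divisible by n_saving")
    rel(cfg$n_saving %% cfg$n_biasing == 0, "n_saving divisible by n_biasing")
    rel((cfg$n_needed - cfg$n_short) %% cfg$n_biasing == 0,
        "(n_needed - n_short) divisible by n_biasing")
    rel(cfg$retrain_every %% cfg$n_saving == 0,
        "retrain_every divisible by n_saving")
  }
  if (!is.null(cfg$potential) && !is.null(cfg$vae))
    rel(cfg$potential$D == cfg$vae$d_dihedrals,
        "potential dimension equals vae d_dihedrals")
  if (length(bad) > 0L)
    stop_desp("invalid DESP configuration:\n  - ",
              paste(bad, collapse = "\n  - "), class = "desp_config_error")
  cfg
}

pool_new <- function(D, k) {
  list(frames = matrix(numeric(0), 0L, D), steps = numeric(0),
       phase = character(0),
       mu = matrix(numeric(0), 0L, k), lv = matrix(numeric(0), 0L, k))
}

pool_append <- function(pool, angles, step, phase, model = NULL) {
  pool$frames <- rbind(pool$frames, angles)
  pool$steps <- c(pool$steps, step)
  pool$phase <- c(pool$phase, phase)
  if (!is.null(model)) {
    g <- vae_encode(model, encode_features(matrix(angles, nrow = 1L)))
    pool$mu <- rbind(pool$mu, g$mean)
    pool$lv <- rbind(pool$lv, g$ln_var)
  }
  pool
}

pool_refresh_latents <- function(pool, model) {
  g <- vae_encode(model, encode_features(pool$frames))
  pool$mu <- g$mean
  pool$lv <- g$ln_var
  pool
}

#' Run the DESP algorithm on the toy dynamics backend
#'
#' Phase 1: `n_short` unbiased steps, saving a frame to the pool every
#' `n_saving` steps. Phase 2: initial VAE training on the pool. Phase 3:
#' while fewer than `n_needed` steps are done, encode the current
#' conformation, aggregate its latent KL divergence against `K` pool
#' representatives, advance `n_biasing` steps with the bias force held fixed
#' over the block, record (step, V_KL, V_bias); frames keep joining the pool
#' every `n_saving` steps and every `retrain_every` steps the VAE is trained
#' further on a random pool subset and the pool's latent cache refreshed.
#'
#' @param cfg a validated [desp_config()].
#' @param run_dir optional directory; when given, the resolved config, angle
#'   / bias / loss TSVs, a progress log, and a resumable checkpoint (written
#'   at every retraining boundary) are stored there.
#' @param stop_after_step optional step count at which the run checkpoints
#'   and returns `NULL` instead of finishing (a controlled interruption;
#'   requires `run_dir`). [resume_desp()] continues such a run to a result
#'   bit-identical with the uninterrupted one.
#' @return A `desp_result`: `trajectory` (all saved frames), `frame_steps`,
#'   `frame_phase` (`"bootstrap"` or `"biased"`), `bias_records`,
#'   `loss_trace`, `model`, `n_completed`, `state`.
#' @export
run_desp <- function(cfg, run_dir = NULL, stop_after_step = NULL) {
  cfg <- validate_desp_config(cfg)
  if (!is.null(stop_after_step) && is.null(run_dir))
    stop_desp("stop_after_step requires a run_dir",
              class = "desp_config_error")
  if (!is.null(run_dir) && !dir.exists(run_dir))
    dir.create(run_dir, recursive = TRUE)
  D <- cfg$potential$D
  start <- if (is.null(cfg$start_angles)) numeric(D) else
    wrap_angle(as.numeric(cfg$start_angles))

  st <- list(cfg = cfg,
             sim = sim_state(start, cfg$langevin),
             pool = pool_new(D, cfg$vae$latent_dim),
             model = NULL,
             n_completed = 0,
             bias_records = list(),
             reps_stream = rng_stream_new(derive_seed(cfg$seed, "reps")),
             subset_stream = rng_stream_new(derive_seed(cfg$seed, "retrain")))
  log_line(run_dir, "run start: seed=%d D=%d n_needed=%g", cfg$seed, D,
           cfg$n_needed)

  ## Phase 1: unbiased bootstrap
  boot <- run_unbiased(st$sim, cfg$potential, cfg$n_short, cfg$n_saving,
                       cfg$langevin)
  st$sim <- boot$state
  nb <- nrow(boot$trajectory$angles)
  for (i in seq_len(nb))
    st$pool <- pool_append(st$pool, boot$trajectory$angles[i, ],
                           i * cfg$n_saving, "bootstrap")
  st$n_completed <- cfg$n_short
  log_line(run_dir, "bootstrap done: %d frames pooled", nb)

  ## Phase 2: initial VAE training on the pool
  st$model <- build_vae(cfg$vae)
  st$model <- train_vae(st$model, encode_features(st$pool$frames))
  st$pool <- pool_refresh_latents(st$pool, st$model)
  log_line(run_dir, "initial training done: %d epochs, loss %.6g",
           st$model$trained_epochs,
           st$model$trace$loss_model[nrow(st$model$trace)])
  desp_checkpoint(st, run_dir)

  desp_biased_phase(st, run_dir, stop_after_step)
}

## Phase 3 driver, shared by run_desp and resume.
desp_biased_phase <- function(st, run_dir, stop_after_step = NULL) {
  cfg <- st$cfg
  interrupted <- FALSE
  flush_on_error(run_dir, st, {
    while (st$n_completed < cfg$n_needed) {
      if (!is.null(stop_after_step) && st$n_completed >= stop_after_step) {
        desp_checkpoint(st, run_dir)
        log_line(run_dir, "interrupted at step %g", st$n_completed)
        interrupted <- TRUE
        break
      }
      n_pool <- nrow(st$pool$frames)
      pick <- with_stream(st$reps_stream,
        sample.int(n_pool, min(cfg$bias$n_representatives, n_pool)))
      st$reps_stream <- pick$state
      reps <- lapply(pick$value, function(i)
        latent_gaussian(st$pool$mu[i, ], st$pool$lv[i, ]))
      force <- bias_force(st$model, st$sim$angles, reps, cfg$bias)
      st$bias_records[[length(st$bias_records) + 1L]] <-
        data.frame(step = st$n_completed, v_kl = attr(force, "v_kl"),
                   v_bias = attr(force, "v_bias"))
      ## stability clip: the inverse-square bias diverges near visited
      ## states; per-coordinate forces are clamped so one step can displace
      ## at most 0.5 rad, keeping the integrator inside its stability bound
      f_max <- 0.5 * cfg$langevin$friction / cfg$langevin$dt
      adv <- advance_langevin(st$sim, cfg$potential,
                              pmin(pmax(as.numeric(force), -f_max), f_max),
                              cfg$n_biasing, 0L, cfg$langevin)
      st$sim <- adv$state
      st$n_completed <- st$n_completed + cfg$n_biasing
      if (st$n_completed %% cfg$n_saving == 0)
        st$pool <- pool_append(st$pool, st$sim$angles, st$n_completed,
                               "biased", st$model)
      if ((st$n_completed - cfg$n_short) %% cfg$retrain_every == 0) {
        n_pool <- nrow(st$pool$frames)
        sub <- with_stream(st$subset_stream,
          sample.int(n_pool, min(cfg$retrain_subset, n_pool)))
        st$subset_stream <- sub$state
        st$model <- train_vae(st$model,
                              encode_features(st$pool$frames[sub$value, ,
                                                             drop = FALSE]),
                              max_epochs = cfg$retrain_epochs)
        st$pool <- pool_refresh_latents(st$pool, st$model)
        st$n_retrainings <- (st$n_retrainings %||% 0L) + 1L
        log_line(run_dir, "retrained at step %g (pool %d)",
                 st$n_completed, n_pool)
        desp_checkpoint(st, run_dir)
      }
    }
    st
  })
  if (interrupted) return(invisible(NULL))
  desp_finish(st, run_dir)
}

desp_finish <- function(st, run_dir) {
  cfg <- st$cfg
  bias_records <- if (length(st$bias_records))
    do.call(rbind, st$bias_records)
  else data.frame(step = numeric(), v_kl = numeric(), v_bias = numeric())
  res <- structure(list(
    trajectory = angle_trajectory(st$pool$frames),
    frame_steps = st$pool$steps,
    frame_phase = st$pool$phase,
    bias_records = bias_records,
    loss_trace = st$model$trace,
    model = st$model,
    n_completed = st$n_completed,
    n_retrainings = st$n_retrainings %||% 0L,
    state = st$sim,
    config = cfg), class = "desp_result")
  if (!is.null(run_dir)) {
    write_angle_tsv(res$trajectory, file.path(run_dir, "trajectory.tsv"))
    write_bias_tsv(res$bias_records, file.path(run_dir, "bias.tsv"))
    write_loss_tsv(res$loss_trace, file.path(run_dir, "loss.tsv"))
    save_vae(res$model, file.path(run_dir, "model.rds"))
    desp_checkpoint(st, run_dir)
    log_line(run_dir, "run complete: n_completed=%g, %d frames, %d bias records",
             res$n_completed, nrow(st$pool$frames), nrow(bias_records))
  }
  res
}

#' @export
print.desp_result <- function(x, ...) {
  cat(sprintf(paste0("desp_result: %g steps completed, %d saved frames ",
                     "(%d bootstrap), %d bias records\n"),
              x$n_completed, nrow(x$trajectory$angles),
              sum(x$frame_phase == "bootstrap"), nrow(x$bias_records)))
  invisible(x)
}

desp_checkpoint <- function(st, run_dir) {
  if (is.null(run_dir)) return(invisible(NULL))
  tmp <- file.path(run_dir, "checkpoint.rds.tmp")
  saveRDS(list(format = "desp_checkpoint_v1", state = st), tmp)
  file.rename(tmp, file.path(run_dir, "checkpoint.rds"))
  cfg_snapshot <- st$cfg
  cfg_snapshot$potential <- cfg_snapshot$potential$terms
  yaml::write_yaml(rapply(unclass(cfg_snapshot), unclass, how = "replace"),
                   file.path(run_dir, "config.yaml"))
  invisible(NULL)
}

log_line <- function(run_dir, fmt, ...) {
  if (is.null(run_dir)) return(invisible(NULL))
  cat(sprintf(paste0(format(Sys.time(), "%H:%M:%S "), fmt, "\n"), ...),
      file = file.path(run_dir, "run.log"), append = TRUE)
  invisible(NULL)
}

flush_on_error <- function(run_dir, st, expr) {
  tryCatch(expr, error = function(e) {
    desp_checkpoint(st, run_dir)
    log_line(run_dir, "ABORT: %s", conditionMessage(e))
    stop(e)
  })
}

#' Resume an interrupted DESP run from its checkpoint
#'
#' Continuation reproduces the uninterrupted run bit-for-bit: the checkpoint
#' stores the frame pool with its latent cache, the model (parameters,
#' optimizer and RNG stream), the dynamics state and every auxiliary RNG
#' stream. Resuming a completed run returns the finished result unchanged
#' (idempotent).
#'
#' @param run_dir directory of a run started with `run_desp(cfg, run_dir)`.
#' @return A `desp_result`.
#' @export
resume_desp <- function(run_dir) {
  path <- file.path(run_dir, "checkpoint.rds")
  if (!file.exists(path))
    stop_desp("no checkpoint found in ", run_dir, class = "desp_resume_error")
  ck <- tryCatch(readRDS(path), error = function(e)
    stop_desp("corrupted checkpoint: ", conditionMessage(e),
              class = "desp_resume_error"))
  if (!identical(ck$format, "desp_checkpoint_v1") || is.null(ck$state))
    stop_desp("corrupted checkpoint in ", run_dir,
              class = "desp_resume_error")
  st <- ck$state
  st$model <- structure(st$model, class = "desp_vae")
  log_line(run_dir, "resume at step %g", st$n_completed)
  desp_biased_phase(st, run_dir)
}
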