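## Variational autoencoder on cos/sin dihedral features.
##
## Architecture: input(2D) -> N fully connected layers with PReLU
## activations, layer n having floor(2D/n) nodes -> two linear heads of size
## k = floor(2D/(N+1)) emitting the latent mean and log-variance; the decoder
## mirrors the encoder (hidden layers m = N..1 of floor(2D/m) nodes) and ends
## in a linear output of size 2D. Training minimizes
## (1-w)*MSE + w*KL(N(mu, diag(sigma^2)) || N(0, I)) with AdamW, a multistep
## learning-rate schedule and early stopping. The network is small by design;
## all passes are dense matrix products, with backpropagation written out
## explicitly so the encoder's input gradient (needed for the bias force) is
## exact.

#' VAE configuration
#'
#' @param d_dihedrals number of dihedral angles D (input size is 2D).
#' @param n_hidden number of hidden layers N in the encoder (the decoder
#'   mirrors it); default 7.
#' @param w weight of the KL term in the composite loss, in `[0, 1]`;
#'   default 0.1 (reconstruction keeps weight 0.9).
#' @param learning_rate initial Adam learning rate; default 1e-4.
#' @param betas Adam running-average coefficients; default (0.9, 0.999).
#' @param weight_decay decoupled weight decay; default 0.01.
#' @param lr_milestones number of equally spaced epoch milestones at which
#'   the learning rate is rescaled; default 50.
#' @param lr_gamma factor applied at each milestone; default 0.99.
#' @param batch_size minibatch size; default 512.
#' @param max_epochs training epoch budget; default 5000.
#' @param patience early-stopping patience (consecutive epochs without
#'   improvement of the best loss); default 250. Must be >= 1.
#' @param seed integer seed for parameter initialization, shuffling, and
#'   reparameterization draws.
#' @return A `vae_config`.
#' @export
vae_config <- function(d_dihedrals, n_hidden = 7L, w = 0.1,
                       learning_rate = 1e-4, betas = c(0.9, 0.999),
                       weight_decay = 0.01, lr_milestones = 50L,
                       lr_gamma = 0.99, batch_size = 512L,
                       max_epochs = 5000L, patience = 250L, seed = 1L) {
  check_number(d_dihedrals, "d_dihedrals", lower = 1, integer = TRUE)
  check_number(n_hidden, "n_hidden", lower = 1, integer = TRUE)
  check_number(w, "w", lower = 0, upper = 1)
  check_number(learning_rate, "learning_rate", lower = 1e-300)
  check_number(weight_decay, "weight_decay", lower = 0)
  check_number(lr_milestones, "lr_milestones", lower = 1, integer = TRUE)
  check_number(lr_gamma, "lr_gamma", lower = 1e-12)
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(max_epochs, "max_epochs", lower = 1, integer = TRUE)
  check_number(patience, "patience", lower = 1, integer = TRUE)
  d <- as.integer(d_dihedrals); n <- as.integer(n_hidden)
  latent_dim <- (2L * d) %/% (n + 1L)
  widths <- (2L * d) %/% seq_len(n)
  if (latent_dim < 1L || any(widths < 1L))
    stop_desp("layer widths collapse to 0: 2*d_dihedrals = ", 2L * d,
              " is too small for n_hidden = ", n,
              class = "desp_config_error")
  structure(list(d_dihedrals = d, n_hidden = n, latent_dim = latent_dim,
                 hidden_widths = widths, w = w,
                 learning_rate = learning_rate, betas = as.numeric(betas),
                 weight_decay = weight_decay,
                 lr_milestones = as.integer(lr_milestones),
                 lr_gamma = lr_gamma, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "vae_config")
}

## Linear-layer init: U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for weights and bias.
init_linear <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -bound, bound),
                  fan_in, fan_out),
       b = stats::runif(fan_out, -bound, bound))
}

#' Build an (untrained) VAE with seeded parameter initialization
#'
#' @param config a [vae_config].
#' @return A `desp_vae` object exposing [vae_encode()] and [vae_decode()].
#' @export
build_vae <- function(config) {
  stopifnot(inherits(config, "vae_config"))
  stream <- rng_stream_new(config$seed)
  built <- with_stream(stream, {
    two_d <- 2L * config$d_dihedrals
    k <- config$latent_dim
    enc_dims <- c(two_d, config$hidden_widths)
    dec_dims <- c(k, rev(config$hidden_widths))
    params <- list()
    for (l in seq_len(config$n_hidden)) {
      lin <- init_linear(enc_dims[l], enc_dims[l + 1L])
      params[[paste0("enc_W", l)]] <- lin$W
      params[[paste0("enc_b", l)]] <- lin$b
      params[[paste0("enc_a", l)]] <- 0.25  # PReLU slope
    }
    for (head in c("mu", "lv")) {
      lin <- init_linear(enc_dims[config$n_hidden + 1L], k)
      params[[paste0(head, "_W")]] <- lin$W
      params[[paste0(head, "_b")]] <- lin$b
    }
    for (l in seq_len(config$n_hidden)) {
      lin <- init_linear(dec_dims[l], dec_dims[l + 1L])
      params[[paste0("dec_W", l)]] <- lin$W
      params[[paste0("dec_b", l)]] <- lin$b
      params[[paste0("dec_a", l)]] <- 0.25
    }
    lin <- init_linear(dec_dims[config$n_hidden + 1L], two_d)
    params[["out_W"]] <- lin$W
    params[["out_b"]] <- lin$b
    params
  })
  structure(list(config = config, params = built$value,
                 rng_state = built$state, trace = empty_trace(),
                 opt_state = NULL, trained_epochs = 0L),
            class = "desp_vae")
}

#' @export
print.desp_vae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("desp_vae: D = %d (input 2D = %d), %d hidden layers ",
                     "(%s), latent k = %d, trained %d epochs\n"),
              cfg$d_dihedrals, 2L * cfg$d_dihedrals, cfg$n_hidden,
              paste(cfg$hidden_widths, collapse = ", "), cfg$latent_dim,
              x$trained_epochs))
  invisible(x)
}

empty_trace <- function() {
  data.frame(epoch = integer(), loss_model = numeric(),
             loss_mse = numeric(), loss_kl = numeric(),
             learning_rate = numeric())
}

prelu <- function(s, a) {
  neg <- s < 0
  s + (a - 1) * (s * neg)
}

## Forward through a stack of PReLU layers; returns activations (incl. input)
## and pre-activations for backprop.
stack_forward <- function(params, prefix, n_layers, X) {
  H <- list(X); S <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    S[[l]] <- sweep(H[[l]] %*% params[[paste0(prefix, "_W", l)]], 2L,
                    params[[paste0(prefix, "_b", l)]], "+")
    H[[l + 1L]] <- prelu(S[[l]], params[[paste0(prefix, "_a", l)]])
  }
  list(H = H, S = S)
}

## Backward through a PReLU stack; dH is the gradient at the stack output.
## Returns parameter grads (appended into `grads`) and the input gradient.
stack_backward <- function(params, prefix, n_layers, cache, dH, grads) {
  for (l in rev(seq_len(n_layers))) {
    a <- params[[paste0(prefix, "_a", l)]]
    S <- cache$S[[l]]
    neg <- S < 0
    grads[[paste0(prefix, "_a", l)]] <- sum(dH * S * neg)
    dS <- dH + (a - 1) * (dH * neg)
    grads[[paste0(prefix, "_W", l)]] <- crossprod(cache$H[[l]], dS)
    grads[[paste0(prefix, "_b", l)]] <- colSums(dS)
    dH <- dS %*% t(params[[paste0(prefix, "_W", l)]])
  }
  list(grads = grads, dX = dH)
}

encoder_forward <- function(model, X) {
  p <- model$params
  cache <- stack_forward(p, "enc", model$config$n_hidden, X)
  Htop <- cache$H[[model$config$n_hidden + 1L]]
  mu <- sweep(Htop %*% p$mu_W, 2L, p$mu_b, "+")
  lv <- sweep(Htop %*% p$lv_W, 2L, p$lv_b, "+")
  list(mu = mu, lv = lv, cache = cache, Htop = Htop)
}

## Gradient of a scalar w.r.t. the encoder INPUT given gradients at the two
## latent heads (each B x k). Used by the bias force.
encoder_backward_input <- function(model, fwd, dmu, dlv) {
  p <- model$params
  dH <- dmu %*% t(p$mu_W) + dlv %*% t(p$lv_W)
  stack_backward(p, "enc", model$config$n_hidden, fwd$cache, dH,
                 list())$dX
}

#' Encode feature rows to latent Gaussian parameters
#'
#' Deterministic: returns the latent mean and log-variance vectors (no
#' sampling).
#'
#' @param model a `desp_vae`.
#' @param features numeric vector of length 2D or a B x 2D matrix.
#' @return List with `mean` and `ln_var`, each B x k matrices.
#' @export
vae_encode <- function(model, features) {
  X <- to_batch(features, 2L * model$config$d_dihedrals)
  fwd <- encoder_forward(model, X)
  list(mean = fwd$mu, ln_var = fwd$lv)
}

#' Decode latent vectors to reconstructed feature rows
#'
#' @param model a `desp_vae`.
#' @param z numeric vector of length k or a B x k matrix.
#' @return B x 2D matrix of reconstructed cos/sin features.
#' @export
vae_decode <- function(model, z) {
  Z <- to_batch(z, model$config$latent_dim)
  p <- model$params
  cache <- stack_forward(p, "dec", model$config$n_hidden, Z)
  sweep(cache$H[[model$config$n_hidden + 1L]] %*% p$out_W, 2L, p$out_b, "+")
}

to_batch <- function(x, width) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != width)
    stop_desp("expected ", width, " columns, got ", ncol(x),
              class = "desp_shape_error")
  x
}

#' Single latent Gaussian
#'
#' @param mean latent mean vector.
#' @param ln_var latent log-variance vector (same length).
#' @return A `latent_gaussian`.
#' @export
latent_gaussian <- function(mean, ln_var) {
  mean <- as.numeric(mean); ln_var <- as.numeric(ln_var)
  if (length(mean) != length(ln_var))
    stop_desp("mean and ln_var lengths differ", class = "desp_shape_error")
  if (any(!is.finite(mean)) || any(!is.finite(ln_var)))
    stop_desp("latent parameters must be finite")
  structure(list(mean = mean, ln_var = ln_var), class = "latent_gaussian")
}

## Row i of an encode() batch as a latent_gaussian.
latent_row <- function(batch, i) {
  latent_gaussian(batch$mean[i, ], batch$ln_var[i, ])
}

#' Reparameterization draw from a latent Gaussian
#'
#' `z = mu + exp(ln_var / 2) * eps`, `eps ~ N(0, I)`, drawn from the ambient
#' RNG stream (seed with `set.seed()` for reproducibility).
#'
#' @param g a [latent_gaussian].
#' @return numeric vector z of length k.
#' @export
reparameterize <- function(g) {
  stopifnot(inherits(g, "latent_gaussian"))
  g$mean + exp(g$ln_var / 2) * stats::rnorm(length(g$mean))
}

#' Reconstruction loss: mean squared error over all batch elements
#'
#' @param y,y_hat equally shaped feature batches.
#' @return Mean of squared element-wise differences.
#' @export
loss_mse <- function(y, y_hat) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  if (!all(dim(y) == dim(y_hat)))
    stop_desp("shape mismatch in loss_mse", class = "desp_shape_error")
  mean((y - y_hat)^2)
}

#' KL regularization loss to the standard normal
#'
#' Per sample `0.5 * sum_i (sigma_i^2 + mu_i^2 - ln sigma_i^2 - 1)`; the
#' batch value is the mean over samples.
#'
#' @param mean B x k matrix (or vector) of latent means.
#' @param ln_var matching matrix of latent log-variances.
#' @return Non-negative scalar.
#' @export
loss_kl <- function(mean, ln_var) {
  mu <- if (is.null(dim(mean))) matrix(mean, nrow = 1L) else as.matrix(mean)
  lv <- if (is.null(dim(ln_var))) matrix(ln_var, nrow = 1L) else as.matrix(ln_var)
  if (!all(dim(mu) == dim(lv)))
    stop_desp("shape mismatch in loss_kl", class = "desp_shape_error")
  mean(0.5 * rowSums(exp(lv) + mu^2 - lv - 1))
}

#' Composite model loss
#'
#' `(1 - w) * mse + w * kl`.
#'
#' @param mse reconstruction loss.
#' @param kl KL loss.
#' @param w KL weight in `[0, 1]`.
#' @return Weighted sum.
#' @export
loss_model <- function(mse, kl, w) {
  check_number(w, "w", lower = 0, upper = 1)
  (1 - w) * mse + w * kl
}

## Full forward + backward on one minibatch; z uses the reparameterization
## sample (eps supplied). Returns loss components and parameter gradients.
vae_batch_grad <- function(model, X, eps) {
  p <- model$params
  cfg <- model$config
  B <- nrow(X); two_d <- 2L * cfg$d_dihedrals
  enc <- encoder_forward(model, X)
  mu <- enc$mu; lv <- enc$lv
  sd_ <- exp(lv / 2)
  Z <- mu + sd_ * eps
  dec_cache <- stack_forward(p, "dec", cfg$n_hidden, Z)
  Y <- sweep(dec_cache$H[[cfg$n_hidden + 1L]] %*% p$out_W, 2L, p$out_b, "+")

  ## Reconstruction term: mean over samples of the squared error summed over
  ## the 2D feature components (the per-sample vector reading of the MSE);
  ## keeps the composite loss on the scale where w = 0.1 balances the terms.
  mse <- mean(rowSums((Y - X)^2))
  kl <- mean(0.5 * rowSums(exp(lv) + mu^2 - lv - 1))
  w <- cfg$w
  grads <- list()

  dY <- (1 - w) * 2 * (Y - X) / B
  grads$out_W <- crossprod(dec_cache$H[[cfg$n_hidden + 1L]], dY)
  grads$out_b <- colSums(dY)
  dH <- dY %*% t(p$out_W)
  bk <- stack_backward(p, "dec", cfg$n_hidden, dec_cache, dH, grads)
  grads <- bk$grads
  dZ <- bk$dX

  dmu <- dZ + w * mu / B
  dlv <- dZ * eps * sd_ / 2 + w * 0.5 * (exp(lv) - 1) / B
  grads$mu_W <- crossprod(enc$Htop, dmu)
  grads$mu_b <- colSums(dmu)
  grads$lv_W <- crossprod(enc$Htop, dlv)
  grads$lv_b <- colSums(dlv)
  dHtop <- dmu %*% t(p$mu_W) + dlv %*% t(p$lv_W)
  bk <- stack_backward(p, "enc", cfg$n_hidden, enc$cache, dHtop, grads)
  list(grads = bk$grads, mse = mse, kl = kl,
       loss = loss_model(mse, kl, w))
}

adamw_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adamw_step <- function(params, grads, opt, lr, betas, weight_decay,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

## Deterministic epoch-level loss: latent sample replaced by its mean, so the
## early-stopping monitor is noise-free. The recorded loss_mse is the
## per-sample summed squared error (the objective's reconstruction term);
## divide by 2D for the per-element mean that [loss_mse()] reports.
vae_eval_loss <- function(model, X) {
  enc <- vae_encode(model, X)
  Y <- vae_decode(model, enc$mean)
  mse <- mean(rowSums((X - Y)^2))
  kl <- loss_kl(enc$mean, enc$ln_var)
  list(mse = mse, kl = kl, loss = loss_model(mse, kl, model$config$w))
}

#' Train (or continue training) a VAE
#'
#' AdamW (decoupled weight decay) on minibatches shuffled each epoch, with
#' `lr_milestones` equally spaced milestones each multiplying the learning
#' rate by `lr_gamma`, and early stopping: if the epoch loss has not improved
#' for `patience` consecutive epochs, training stops and the best-loss
#' parameters are restored. The recorded epoch loss is evaluated with the
#' latent sample replaced by its mean, making the early-stopping monitor
#' deterministic; minibatch gradients use genuine reparameterization draws.
#'
#' @param model a `desp_vae` (fresh from [build_vae()] or already trained —
#'   training continues from the current parameters and optimizer state).
#' @param data T x 2D feature matrix.
#' @param max_epochs optional override of the config epoch budget (used for
#'   the short retraining cycles inside the sampling loop).
#' @return The trained `desp_vae`; `model$trace` accumulates the per-epoch
#'   (epoch, loss_model, loss_mse, loss_kl, learning_rate) records.
#' @export
train_vae <- function(model, data, max_epochs = NULL) {
  stopifnot(inherits(model, "desp_vae"))
  cfg <- model$config
  X <- to_batch(data, 2L * cfg$d_dihedrals)
  T_ <- nrow(X)
  if (T_ < 1L) stop_desp("empty training data")
  n_epochs <- if (is.null(max_epochs)) cfg$max_epochs else as.integer(max_epochs)
  milestones <- unique(floor(seq_len(cfg$lr_milestones) *
                               n_epochs / cfg$lr_milestones))
  milestones <- milestones[milestones >= 1L]
  if (is.null(model$opt_state)) model$opt_state <- adamw_init(model$params)

  res <- with_stream(model$rng_state, {
    params <- model$params
    opt <- model$opt_state
    best_loss <- Inf; best_params <- params; best_opt <- opt
    stall <- 0L
    trace <- vector("list", n_epochs)
    mtmp <- model
    for (epoch in seq_len(n_epochs)) {
      lr <- cfg$learning_rate * cfg$lr_gamma^sum(milestones <= epoch)
      perm <- sample.int(T_)
      starts <- seq(1L, T_, by = cfg$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, T_)]
        Xb <- X[idx, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(idx) * cfg$latent_dim),
                      length(idx), cfg$latent_dim)
        mtmp$params <- params
        bg <- vae_batch_grad(mtmp, Xb, eps)
        if (!is.finite(bg$loss))
          stop_desp("non-finite training loss at epoch ", epoch,
                    class = "desp_training_error")
        upd <- adamw_step(params, bg$grads, opt, lr, cfg$betas,
                          cfg$weight_decay)
        params <- upd$params; opt <- upd$opt
      }
      mtmp$params <- params
      ev <- vae_eval_loss(mtmp, X)
      trace[[epoch]] <- c(ev$loss, ev$mse, ev$kl, lr)
      if (ev$loss < best_loss) {
        best_loss <- ev$loss; best_params <- params; best_opt <- opt
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    done <- !vapply(trace, is.null, logical(1))
    tr <- do.call(rbind, trace[done])
    list(params = best_params, opt = best_opt,
         trace = data.frame(epoch = which(done), loss_model = tr[, 1],
                            loss_mse = tr[, 2], loss_kl = tr[, 3],
                            learning_rate = tr[, 4]))
    })
  out <- res$value
  out$trace$epoch <- out$trace$epoch + model$trained_epochs
  model$params <- out$params
  model$opt_state <- out$opt
  model$rng_state <- res$state
  model$trace <- rbind(model$trace, out$trace)
  model$trained_epochs <- model$trained_epochs + nrow(out$trace)
  model
}

#' Save / load a VAE checkpoint
#'
#' The checkpoint stores the config, all parameter tensors, the optimizer
#' state, the RNG stream and the loss trace; a load followed by
#' [vae_encode()] reproduces the pre-save outputs exactly.
#'
#' @param model a `desp_vae`.
#' @param path checkpoint file.
#' @return `save_vae` the path, invisibly; `load_vae` the restored model.
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "desp_vae"))
  saveRDS(list(format = "desp_vae_checkpoint_v1", model = unclass(model)),
          path)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "desp_vae_checkpoint_v1"))
    stop_desp("not a desp VAE checkpoint: ", path)
  structure(x$model, class = "desp_vae")
}

#' Export a loss trace as TSV
#'
#' @param trace the `trace` data frame of a trained `desp_vae`.
#' @param path output file.
#' @export
write_loss_tsv <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
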