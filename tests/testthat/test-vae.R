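test_that("the architecture follows the mirrored floor(2D/n) width formula", {
  cfg <- vae_config(d_dihedrals = 28, n_hidden = 7, seed = 1)
  expect_equal(cfg$hidden_widths, c(56L, 28L, 18L, 14L, 11L, 9L, 8L))
  expect_equal(cfg$latent_dim, 7L)  # one-eighth of the input dimension 2D
  m <- build_vae(cfg)
  expect_equal(dim(m$params$enc_W1), c(56L, 56L))
  expect_equal(dim(m$params$enc_W7), c(9L, 8L))
  expect_equal(dim(m$params$mu_W), c(8L, 7L))
  expect_equal(dim(m$params$dec_W1), c(7L, 8L))  # decoder mirrors: 8, 9, ...
  expect_equal(dim(m$params$dec_W7), c(28L, 56L))
  expect_equal(dim(m$params$out_W), c(56L, 56L))

  expect_equal(vae_config(d_dihedrals = 4, n_hidden = 7, seed = 1)$latent_dim,
               1L)
  expect_error(vae_config(d_dihedrals = 1, n_hidden = 7, seed = 1),
               class = "desp_config_error")
})

test_that("encode and decode are deterministic and batch-consistent", {
  m <- tiny_vae(D = 5, n_hidden = 3)
  set.seed(2)
  X <- encode_features(matrix(runif(4 * 5, -pi, pi), 4, 5))
  e1 <- vae_encode(m, X)
  e2 <- vae_encode(m, X)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1$mean)) && all(is.finite(e1$ln_var)))
  # identical rows give identical latents
  e3 <- vae_encode(m, X[c(1, 1), ])
  expect_identical(e3$mean[1, ], e3$mean[2, ])
  # batch equals the stacked single-row calls, through decode too
  for (i in 1:4) {
    ei <- vae_encode(m, X[i, ])
    expect_equal(ei$mean[1, ], e1$mean[i, ])
    expect_equal(vae_decode(m, ei$mean)[1, ],
                 vae_decode(m, e1$mean)[i, ])
  }
  expect_error(vae_encode(m, X[, 1:4]), class = "desp_shape_error")
  expect_error(vae_decode(m, matrix(0, 1, 7)), class = "desp_shape_error")
})

test_that("reparameterization is the scaled-and-shifted standard normal", {
  g <- latent_gaussian(c(2, -1), c(-60, -60))  # variance -> 0 limit
  expect_lt(max(abs(reparameterize(g) - g$mean)), 1e-12)

  g2 <- latent_gaussian(c(0.5, -0.25), c(0.2, -0.4))
  set.seed(10); z1 <- reparameterize(g2)
  set.seed(10); z2 <- reparameterize(g2)
  expect_identical(z1, z2)

  set.seed(11)
  n <- 1e5
  draws <- matrix(NA_real_, n, 2)
  eps <- matrix(rnorm(n * 2), n, 2)
  draws <- sweep(sweep(eps, 2, exp(g2$ln_var / 2), "*"), 2, g2$mean, "+")
  # law of large numbers: the sample mean of z approaches mu
  for (i in 1:2)
    expect_lt(abs(mean(draws[, i]) - g2$mean[i]),
              4 * exp(g2$ln_var[i] / 2) / sqrt(n))
})

test_that("loss components match their closed forms and a brute-force oracle", {
  expect_equal(loss_mse(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(loss_mse(matrix(c(1, 0), 1), matrix(c(0, 0), 1)), 0.5)
  set.seed(3)
  y <- matrix(rnorm(30), 5); yh <- matrix(rnorm(30), 5)
  acc <- 0
  for (i in 1:5) for (j in 1:6) acc <- acc + (y[i, j] - yh[i, j])^2
  expect_equal(loss_mse(y, yh), acc / 30, tolerance = 1e-12)

  expect_equal(loss_kl(c(0, 0), c(0, 0)), 0)
  expect_equal(loss_kl(1, 0), 0.5)
  expect_equal(loss_kl(c(0, 0), c(1, 1)), exp(1) - 2)

  expect_equal(loss_model(1, 1, 0.1), 1)
  expect_equal(loss_model(2, 0, 0.1), 1.8)
  expect_equal(loss_model(3.3, 99, 0), 3.3)

  # loss_kl >= 0 with equality only at the standard normal
  set.seed(4)
  for (i in 1:50) {
    mu <- matrix(rnorm(8), 2); lv <- matrix(rnorm(8, sd = 0.5), 2)
    expect_gte(loss_kl(mu, lv), 0)
    if (max(abs(mu)) > 1e-3 || max(abs(lv)) > 1e-3)
      expect_gt(loss_kl(mu, lv), 0)
  }
})

test_that("minibatch gradients match central finite differences", {
  m <- tiny_vae(D = 3, n_hidden = 2, seed = 3)
  set.seed(7)
  X <- encode_features(matrix(runif(5 * 3, -pi, pi), 5, 3))
  eps <- matrix(rnorm(5 * m$config$latent_dim), 5)
  bg <- desp:::vae_batch_grad(m, X, eps)
  lossfun <- function(params) {
    m2 <- m; m2$params <- params
    enc <- desp:::encoder_forward(m2, X)
    Z <- enc$mu + exp(enc$lv / 2) * eps
    Y <- vae_decode(m2, Z)
    (1 - m$config$w) * mean(rowSums((X - Y)^2)) +
      m$config$w * loss_kl(enc$mu, enc$lv)
  }
  h <- 1e-6
  for (nm in names(m$params)) {
    for (i in seq_len(min(length(m$params[[nm]]), 3))) {
      pp <- m$params; pm <- m$params
      pp[[nm]][i] <- pp[[nm]][i] + h
      pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (lossfun(pp) - lossfun(pm)) / (2 * h)
      expect_equal(as.numeric(bg$grads[[nm]][i]), fd, tolerance = 1e-4)
    }
  }
})

test_that("training contracts: patience, scheduler trace, early-stop bookkeeping", {
  expect_error(vae_config(d_dihedrals = 4, patience = 0, seed = 1),
               class = "desp_config_error")

  # constant dataset: reconstruction trends to ~0 (a healthy learning rate
  # is a config choice; the protocol defaults are exercised at full scale in
  # the acceptance suite)
  cfg <- vae_config(d_dihedrals = 4, n_hidden = 2, learning_rate = 1e-2,
                    max_epochs = 200, patience = 200, batch_size = 256,
                    seed = 12)
  X <- encode_features(matrix(rep(c(0.3, -1, 2, 0.5), each = 256), 256, 4))
  m <- train_vae(build_vae(cfg), X)
  expect_lt(utils::tail(m$trace$loss_mse, 1), 0.1 * m$trace$loss_mse[1])
  expect_lte(utils::tail(m$trace$loss_model, 1), m$trace$loss_model[1])

  # learning-rate column equals lr0 * gamma^(#milestones <= epoch)
  milestones <- unique(floor(seq_len(cfg$lr_milestones) *
                               cfg$max_epochs / cfg$lr_milestones))
  expected_lr <- vapply(m$trace$epoch, function(e)
    cfg$learning_rate * cfg$lr_gamma^sum(milestones <= e), numeric(1))
  expect_equal(m$trace$learning_rate, expected_lr)

  # early stopping returns the best model: its deterministic loss equals the
  # minimum of the trace
  cfg2 <- vae_config(d_dihedrals = 4, n_hidden = 2, learning_rate = 5e-3,
                     max_epochs = 300, patience = 10, batch_size = 64,
                     seed = 5)
  set.seed(31)
  X2 <- encode_features(matrix(runif(64 * 4, -pi, pi), 64, 4))
  m2 <- train_vae(build_vae(cfg2), X2)
  ev <- desp:::vae_eval_loss(m2, X2)
  expect_equal(ev$loss, min(m2$trace$loss_model), tolerance = 1e-12)

  # patience = 1 stops right after the first non-improving epoch
  cfg3 <- vae_config(d_dihedrals = 4, n_hidden = 2, max_epochs = 300,
                     patience = 1, seed = 5)
  m3 <- train_vae(build_vae(cfg3), X2)
  trace_after_best <- m3$trace$loss_model[-seq_len(which.min(m3$trace$loss_model))]
  expect_lte(length(trace_after_best), 1L)
})

test_that("checkpoints round-trip the model bit-exactly", {
  m <- tiny_vae(D = 4, n_hidden = 2, seed = 8)
  set.seed(1)
  X <- encode_features(matrix(runif(20 * 4, -pi, pi), 20, 4))
  m <- train_vae(m, X, max_epochs = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_vae(m, path)
  m2 <- load_vae(path)
  expect_identical(vae_encode(m2, X), vae_encode(m, X))
  expect_identical(m2$trace, m$trace)
  suppressWarnings(
    expect_error(load_vae(withr::local_tempfile(fileext = ".rds"))))
})

test_that("training rejects empty data and records strictly increasing epochs", {
  m <- tiny_vae(D = 4, n_hidden = 2)
  expect_error(train_vae(m, matrix(numeric(0), 0, 8)))
  set.seed(2)
  X <- encode_features(matrix(runif(10 * 4, -pi, pi), 10, 4))
  m <- train_vae(m, X, max_epochs = 4)
  m <- train_vae(m, X, max_epochs = 3)  # continued training appends
  expect_equal(m$trace$epoch, 1:7)
})
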