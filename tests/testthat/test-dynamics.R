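flat_potential <- function(D = 1L) {
  make_torus_potential(data.frame(dim = integer(), height = numeric(),
                                  mult = numeric(), center = numeric()),
                       D = D)
}

test_that("the double well has the advertised minima, barrier and gradient", {
  pot <- make_double_well(center = 0.3, barrier_height = 2.5)
  expect_equal(pot$energy(0.3), 0)
  expect_equal(pot$energy(0.3 + pi), 0, tolerance = 1e-12)
  expect_equal(pot$energy(0.3 + pi / 2), 2.5)
  expect_equal(pot$gradient(0.3), 0, tolerance = 1e-12)
  expect_equal(pot$gradient(0.3 + pi), 0, tolerance = 1e-12)

  set.seed(8)
  h <- 1e-6
  for (theta in runif(100, -pi, pi)) {
    fd <- (pot$energy(theta + h) - pot$energy(theta - h)) / (2 * h)
    expect_equal(pot$gradient(theta), fd, tolerance = 1e-6)
  }
})

test_that("torus potentials are 2*pi periodic", {
  pot <- make_torus_potential(
    data.frame(dim = c(1, 2, 2), height = c(2, 1, 0.5), mult = c(2, 1, 3),
               center = c(0, 1, -2)), D = 2)
  set.seed(2)
  for (i in 1:20) {
    th <- runif(2, -pi, pi)
    shift <- sample(c(-1, 1, 2), 2, replace = TRUE) * 2 * pi
    expect_equal(pot$energy(th + shift), pot$energy(th), tolerance = 1e-9)
  }
})

test_that("langevin_step is a deterministic descent at a minimum when kbt -> 0", {
  pot <- make_double_well(0, 1)
  cfg <- langevin_config(kbt = 1e-12, seed = 1)
  st <- sim_state(0, cfg)
  for (i in 1:100) st <- langevin_step(st, pot, cfg = cfg)
  expect_lt(abs(st$angles), 1e-5)
  expect_equal(st$step, 100L)
})

test_that("identical seeds give identical steps; different seeds diverge", {
  pot <- make_double_well(0, 2)
  cfg <- langevin_config(seed = 5)
  s1 <- langevin_step(sim_state(0.4, cfg), pot, cfg = cfg)
  s2 <- langevin_step(sim_state(0.4, cfg), pot, cfg = cfg)
  expect_identical(s1$angles, s2$angles)
  r1 <- run_unbiased(sim_state(0.4, cfg), pot, 500, 50, cfg)
  r2 <- run_unbiased(sim_state(0.4, langevin_config(seed = 6)), pot, 500, 50,
                     langevin_config(seed = 6))
  expect_false(identical(r1$trajectory$angles, r2$trajectory$angles))
})

test_that("free diffusion matches the Einstein relation", {
  cfg <- langevin_config(dt = 0.02, friction = 1.5, kbt = 0.8, seed = 99)
  res <- run_unbiased(sim_state(0, cfg), flat_potential(), 1e5, 1, cfg)
  steps <- wrap_angle(diff(res$trajectory$angles[, 1]))
  msd <- mean(steps^2)
  expect_equal(msd, 2 * cfg$kbt * cfg$dt / cfg$friction, tolerance = 0.05)
})

test_that("unbiased sampling reproduces the Boltzmann distribution in 1D and 2D", {
  # 1D double well, barrier 2 kbt
  pot <- make_double_well(0, 2)
  cfg <- langevin_config(seed = 17)
  res <- run_unbiased(sim_state(0, cfg), pot, 4e5, 10, cfg)
  edges <- seq(-pi, pi, length.out = 41)
  emp <- hist(res$trajectory$angles[, 1], breaks = edges, plot = FALSE)$counts
  emp <- emp / sum(emp)
  ref <- boltzmann_bins(function(x) pot$energy(x), edges)
  expect_lt(sum(abs(emp - ref)), 0.08)

  # 2D: independent wells factorize; check both marginals
  pot2 <- make_torus_potential(
    data.frame(dim = c(1, 2), height = c(1.5, 1), mult = c(2, 1),
               center = c(0, 0.5)), D = 2)
  cfg2 <- langevin_config(seed = 23)
  res2 <- run_unbiased(sim_state(c(0, 0), cfg2), pot2, 4e5, 10, cfg2)
  for (d in 1:2) {
    empd <- hist(res2$trajectory$angles[, d], breaks = edges,
                 plot = FALSE)$counts
    empd <- empd / sum(empd)
    refd <- boltzmann_bins(function(x) {
      th <- c(0, 0); th[d] <- x
      terms <- pot2$terms[pot2$terms$dim == d, , drop = FALSE]
      sum(terms$height / 2 * (1 - cos(terms$mult * (x - terms$center))))
    }, edges)
    expect_lt(sum(abs(empd - refd)), 0.08)
  }
})

test_that("run_unbiased counts frames, wraps angles, and validates divisibility", {
  pot <- make_double_well(0, 1)
  cfg <- langevin_config(seed = 3)
  res <- run_unbiased(sim_state(0, cfg), pot, 10 * 7, 7, cfg)
  expect_equal(nrow(res$trajectory$angles), 10L)
  expect_true(all(res$trajectory$angles > -pi & res$trajectory$angles <= pi))
  expect_error(run_unbiased(sim_state(0, cfg), pot, 101, 10, cfg),
               class = "desp_config_error")
})

test_that("the stability guard rejects step sizes that can jump over the torus", {
  pot <- make_double_well(0, 1000)
  cfg <- langevin_config(dt = 0.1, seed = 1)
  expect_error(run_unbiased(sim_state(0, cfg), pot, 10, 1, cfg),
               class = "desp_stability_error")
})

test_that("a biased run with zero extra force is bit-identical to run_unbiased", {
  pot <- make_double_well(0, 2)
  cfg <- langevin_config(seed = 77)
  ref <- run_unbiased(sim_state(0.2, cfg), pot, 400, 40, cfg)
  st <- sim_state(0.2, cfg)
  frames <- NULL
  for (b in 1:10) {  # 10 blocks of 40 with explicit zero bias
    adv <- desp:::advance_langevin(st, pot, 0, 40, 40, cfg)
    st <- adv$state
    frames <- rbind(frames, adv$frames)
  }
  expect_identical(frames, ref$trajectory$angles)
  expect_identical(st$angles, ref$state$angles)
})

test_that("the engine adapter contract validates its surface and runs the toy engine", {
  expect_error(engine_adapter("not a function", function() 0),
               class = "desp_adapter_error")
  expect_error(engine_adapter(function(n, fp) NULL, 3),
               class = "desp_adapter_error")

  # toy engine behind the adapter: constant zero bias must reproduce the
  # plain unbiased trajectory
  pot <- make_double_well(0, 2)
  cfg <- langevin_config(seed = 123)
  state <- sim_state(0.3, cfg)
  env <- new.env()
  env$state <- state
  ad <- engine_adapter(
    advance = function(n_steps, force_provider) {
      f <- force_provider(env$state$angles)
      adv <- desp:::advance_langevin(env$state, pot, f, n_steps, n_steps, cfg)
      env$state <- adv$state
      adv$frames
    },
    current_angles = function() env$state$angles)
  frames <- NULL
  for (b in 1:5) frames <- rbind(frames, ad$advance(100, function(a) 0))
  ref <- run_unbiased(sim_state(0.3, cfg), pot, 500, 100, cfg)
  expect_identical(frames, ref$trajectory$angles)
  expect_identical(ad$current_angles(), ref$state$angles)
})
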