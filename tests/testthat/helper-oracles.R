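# Shared oracles and fixture builders, independent of the code paths they
# check.

# Rotate point p about the axis through `origin` with unit direction `u` by
# angle phi (Rodrigues). Used as the brute-force dihedral oracle.
rotate_about_axis <- function(p, origin, u, phi) {
  v <- p - origin
  u <- u / sqrt(sum(u^2))
  origin + v * cos(phi) + cross3_oracle(u, v) * sin(phi) +
    u * sum(u * v) * (1 - cos(phi))
}

cross3_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Quadrature Boltzmann probabilities for a 1D potential on (-pi, pi]:
# probability mass per bin, by trapezoid rule on a fine grid.
boltzmann_bins <- function(energy_fun, edges, kbt = 1, n_grid = 4000) {
  vapply(seq_len(length(edges) - 1L), function(b) {
    x <- seq(edges[b], edges[b + 1L], length.out = n_grid)
    y <- exp(-vapply(x, energy_fun, numeric(1)) / kbt)
    sum((y[-1] + y[-n_grid]) / 2 * diff(x))
  }, numeric(1)) -> mass
  mass / sum(mass)
}

# Random rigid motion (proper rotation + translation) applied to an n x 3
# matrix of points.
random_rigid_motion <- function(pts) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::rnorm(3, sd = 5)
  sweep(pts %*% R, 2L, shift, "+")
}

# Monte-Carlo estimate of D_KL(N0 || N1) for diagonal Gaussians:
# E_{x ~ N0}[log p0(x) - log p1(x)], with standard error.
mc_kl_estimate <- function(mu0, lv0, mu1, lv1, n = 1e6) {
  k <- length(mu0)
  x <- matrix(stats::rnorm(n * k), n, k)
  x <- sweep(sweep(x, 2L, exp(lv0 / 2), "*"), 2L, mu0, "+")
  logp <- function(x, mu, lv) {
    -0.5 * rowSums(sweep(sweep(x, 2L, mu)^2, 2L, exp(lv), "/")) -
      0.5 * sum(lv) - k / 2 * log(2 * pi)
  }
  d <- logp(x, mu0, lv0) - logp(x, mu1, lv1)
  list(estimate = mean(d), se = stats::sd(d) / sqrt(n))
}

# Minimal protein topology builder: one row per atom, in residue order.
make_topology <- function(resnames) {
  heavy <- list(
    ALA = c("N", "CA", "C", "O", "CB"),
    GLY = c("N", "CA", "C", "O"),
    VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
    SER = c("N", "CA", "C", "O", "CB", "OG"))
  rows <- do.call(rbind, lapply(seq_along(resnames), function(i) {
    data.frame(atom = heavy[[resnames[i]]], resno = i,
               resid = resnames[i], stringsAsFactors = FALSE)
  }))
  rows
}

# Small VAE + feature fixture for gradient and shape tests.
tiny_vae <- function(D = 3, n_hidden = 2, seed = 3, ...) {
  build_vae(vae_config(d_dihedrals = D, n_hidden = n_hidden, seed = seed,
                       ...))
}

random_latents <- function(n, k, sd_mu = 1, sd_lv = 0.4) {
  lapply(seq_len(n), function(i)
    latent_gaussian(stats::rnorm(k, sd = sd_mu),
                    stats::rnorm(k, sd = sd_lv)))
}
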