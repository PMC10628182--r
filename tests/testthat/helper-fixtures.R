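# Shared fixtures, generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# von Mises sampler (rejection from uniform; adequate for kappa <= ~30)
rvonmises0 <- function(n, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(2 * n, -pi, pi)
    keep <- stats::runif(2 * n) < exp(kappa * (cos(x) - 1))
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# mixture-model sample: target VM + nontarget VM + uniform
rmixture_errors <- function(n, p_t, p_n, p_u, kappa) {
  comp <- sample.int(3L, n, TRUE, c(p_t, p_n, p_u))
  delta <- stats::runif(n, -pi, pi)   # nontarget offsets
  e <- numeric(n)
  e[comp == 1] <- rvonmises0(sum(comp == 1), kappa)
  e[comp == 2] <- wmattractor:::wrap_pi(delta[comp == 2] +
                                          rvonmises0(sum(comp == 2), kappa))
  e[comp == 3] <- stats::runif(sum(comp == 3), -pi, pi)
  list(errors = e, nontarget_errors = wmattractor:::wrap_pi(e - delta))
}

# ground-truth 6-attractor generative model at the generator's default
# noise scales, with drift during both encoding and memory
attractor6_model <- function() {
  generative_model(demo_drift_field(6),
                   beta_encode = c(0.15, 0.15), sigma_encode = c(0.15, 0.25),
                   beta_memory = c(0.15, 0.15), sigma_memory = c(0.25, 0.35),
                   p_swap = 0.15, p_guess = c(0.03, 0.08))
}

fixture_attractor6 <- function(n_trials = 18000L, seed = 421L) {
  fixture(paste0("attractor6_", n_trials, "_", seed), function() {
    tr <- generate_sessions(session_config(n_trials, seed = seed,
                                           n_sessions = 6L))
    generate_responses(tr, attractor6_model(),
                       seed = wmattractor:::substream_seed(seed, "resp"))
  })
}

# total-variation distance between a propagated density and a Monte-Carlo
# endpoint histogram on n_bins cells (cell-centered); propagation runs on a
# 3x nested finer grid and is aggregated onto the histogram cells
fp_mc_tv <- function(field, beta, sigma, t, theta0 = pi / 2,
                     n_samples = 2e5, n_bins = 128L, dt = 0.005,
                     grid_mult = 3L) {
  h <- 2 * pi / n_bins
  th <- simulate_trajectory(rep(theta0, n_samples), field, beta, sigma, t,
                            dt = dt)
  cnt <- tabulate((floor((th + h / 2) / h) %% n_bins) + 1, n_bins) / n_samples
  pf <- propagate(delta_field(theta0, n_bins * grid_mult), field, beta,
                  sigma, t)
  idx <- (floor((pf$grid + h / 2) / h) %% n_bins) + 1
  q <- as.numeric(tapply(pf$p * pf$h, idx, sum))
  0.5 * sum(abs(cnt - q))
}

density_mass_near <- function(pf, center, halfwidth) {
  d <- abs(wmattractor:::wrap_pi(pf$grid - center))
  sum(pf$p[d <= halfwidth]) * pf$h
}

angle_set_error <- function(found, truth) {
  if (!length(found)) return(Inf)
  max(vapply(found, function(a)
    min(abs(wmattractor:::wrap_pi(a - truth))), numeric(1)))
}
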