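test_that("von Mises-derivative basis: size, zero mean, translation equivariance", {
  B <- build_basis(2 * pi / 12, 128L)
  expect_identical(ncol(B), 12L)
  expect_lt(max(abs(colSums(B))), 1e-10)
  # column k is column 1 circularly shifted by (k-1) * spacing; checked at
  # the columns whose center shift is an integer number of grid bins
  for (k in c(4L, 7L, 10L)) {
    s <- as.integer(round((k - 1) * 128 / 12))
    expect_equal(B[, k], B[(seq_len(128) - 1 - s) %% 128 + 1, 1],
                 tolerance = 1e-12)
  }
  expect_error(build_basis(1.0), "divide")
})

test_that("drift evaluation: zero field, projection oracle, periodicity", {
  z <- drift_field(rep(0, 12))
  expect_equal(evaluate_drift(z, seq(0, 6, by = 0.5)), rep(0, 13))
  f <- wmattractor:::project_drift(function(th) -sin(th))
  expect_equal(evaluate_drift(f, pi / 2), -1, tolerance = 0.02)
  th <- seq(0, 2 * pi, length.out = 50)
  expect_equal(evaluate_drift(f, th + 2 * pi), evaluate_drift(f, th),
               tolerance = 1e-12)
})

test_that("Fokker-Planck propagation: identity, diffusion oracle, conservation", {
  f <- demo_drift_field(6)
  p0 <- delta_field(pi, 128L)
  same <- propagate(p0, f, 0, 0, 5)
  expect_equal(same$p, p0$p)
  # pure diffusion matches the wrapped normal
  out <- propagate(p0, f, 0, 0.5, 2)
  wn <- rowSums(sapply(-8:8, function(k)
    dnorm(out$grid, pi + 2 * pi * k, sqrt(0.5^2 * 2))))
  expect_lt(max(abs(out$p - wn)), 1e-3)
  # mass conservation and non-negativity across a parameter sweep
  for (beta in c(0, 1.5)) for (sigma in c(0.1, 0.5)) {
    pf <- propagate(p0, f, beta, sigma, 1.7)
    expect_equal(sum(pf$p) * pf$h, 1, tolerance = 1e-9)
    expect_true(all(pf$p >= 0))
  }
})

test_that("propagation satisfies the semigroup property and rotation equivariance", {
  f <- demo_drift_field(6)
  p0 <- delta_field(1, 128L)
  a <- propagate(propagate(p0, f, 1.5, 0.3, 1.0), f, 1.5, 0.3, 2.2)
  b <- propagate(p0, f, 1.5, 0.3, 3.2)
  expect_lt(max(abs(a$p - b$p)), 1e-6)

  # rotating the drift field and the start angle by three basis spacings
  # (pi/2, an exact number of grid bins) rotates the output density
  frot <- drift_field(f$weights[c(10:12, 1:9)])
  shift <- pi / 2
  bins <- as.integer(round(shift / p0$h))
  o1 <- propagate(delta_field(1, 128L), f, 1.2, 0.3, 2)
  o2 <- propagate(delta_field(1 + shift, 128L), frot, 1.2, 0.3, 2)
  expect_lt(max(abs(o2$p - o1$p[(seq_len(128) - 1 - bins) %% 128 + 1])),
            1e-9)
})

test_that("Monte-Carlo endpoints agree with the Fokker-Planck density", {
  withr::with_seed(101, {
    tv <- fp_mc_tv(demo_drift_field(6), beta = 1.5, sigma = 0.3, t = 1.2)
    expect_lt(tv, 0.02)
  })
})

test_that("predicted response distributions mix target, swap, and guess mass", {
  f <- demo_drift_field(6)
  guess_all <- ddm_params(f, c(0, 0), c(0.2, 0.2), c(0, 0), c(0.2, 0.2),
                          p_guess = c(1, 1))
  pr <- predict_response_distribution(1, 1.2, target = 2, params = guess_all)
  expect_lt(max(abs(pr$p - 1 / (2 * pi))), 1e-9)

  sharp <- ddm_params(f, c(0, 0), c(0.01, 0.01), c(0, 0), c(0.01, 0.01))
  pr2 <- predict_response_distribution(1, 1.2, target = 2, params = sharp)
  expect_gt(density_mass_near(pr2, 2, 0.2), 0.99)

  swapy <- ddm_params(f, c(0, 0), c(0.05, 0.05), c(0, 0), c(0.05, 0.05),
                      p_swap = 0.3)
  pr3 <- predict_response_distribution(2, 1.2, target = 1, nontarget = 4,
                                       params = swapy)
  expect_lt(abs(density_mass_near(pr3, 4, 0.2) - 0.3), 0.01)
  expect_error(predict_response_distribution(2, 1.2, target = 1,
                                             params = swapy), "nontarget")
})

test_that("negative log-likelihood closed forms and additivity", {
  tr <- fixture_attractor6()[1:2000, ]
  mt <- modeled_trials(tr)
  f <- demo_drift_field(6)
  guess_all <- ddm_params(f, c(0, 0), c(0.2, 0.2), c(0, 0), c(0.2, 0.2),
                          p_guess = c(1, 1))
  expect_equal(negative_log_likelihood(guess_all, mt),
               nrow(mt) * log(2 * pi), tolerance = 1e-9)
  truth <- ddm_params(f, c(0.15, 0.15), c(0.15, 0.25), c(0.15, 0.15),
                      c(0.25, 0.35), p_swap = 0.15, p_guess = c(0.03, 0.08))
  v1 <- negative_log_likelihood(truth, mt)
  doubled <- rbind(mt, mt)
  expect_equal(negative_log_likelihood(truth, doubled), 2 * v1,
               tolerance = 1e-9)
  # generating parameters sit near a likelihood optimum
  withr::with_seed(103, {
    for (i in 1:20) {
      pert <- truth
      pert$beta_memory <- pmax(truth$beta_memory + rnorm(2, 0, 0.3), 0)
      pert$sigma_memory <- pmax(truth$sigma_memory + rnorm(2, 0, 0.08), 0.02)
      pert$sigma_encode <- pmax(truth$sigma_encode + rnorm(2, 0, 0.05), 0.02)
      expect_gt(negative_log_likelihood(pert, mt), v1 - 3)
    }
  })
})

test_that("attractor extraction finds the analytic roots with correct stability", {
  expect_identical(find_attractors(drift_field(rep(0, 12)), 1)$n_attractors, 0L)
  expect_identical(find_attractors(demo_drift_field(6), 0)$n_attractors, 0L)
  att <- find_attractors(demo_drift_field(6), 1.5)
  expect_identical(att$n_attractors, 6L)
  expect_identical(length(att$repellers), 6L)
  expect_lt(angle_set_error(att$attractors, (0:5) * pi / 3), 1e-3)
  expect_lt(angle_set_error(att$repellers, (0:5) * pi / 3 + pi / 6), 1e-3)
  # attractors and repellers alternate around the circle
  both <- sort(c(att$attractors, att$repellers))
  labels <- ifelse(both %in% att$attractors, "a", "r")
  expect_true(all(labels != c(labels[-1], labels[1])))
})

test_that("model fitting is deterministic given seed and data", {
  tr <- fixture_attractor6()[1:3000, ]
  cfg <- ddm_config(subsample = 400L, restarts = 1L, maxit = 15L, seed = 77L)
  f1 <- fit_model(tr, "pure_diffusion", cfg)
  f2 <- fit_model(tr, "pure_diffusion", cfg)
  expect_identical(f1$nll, f2$nll)
  expect_identical(f1$params$sigma_memory, f2$params$sigma_memory)
  expect_identical(f1$params$drift$weights, rep(0, 12))
})
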