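test_that("mixture fit handles the point-mass and uniform limits", {
  pm <- fit_mixture(rep(0, 100))
  expect_gt(pm$p_t, 0.99)
  expect_gte(pm$kappa, 1e4 - 1)   # capped concentration

  withr::with_seed(81, {
    fu <- fit_mixture(runif(5000, -pi, pi))
    expect_equal(fu$p_u, 1, tolerance = 0.02)
    expect_true(fu$collapsed_uniform)
  })
})

test_that("mixture fit recovers generating parameters", {
  withr::with_seed(82, {
    s <- rmixture_errors(5000, 0.6, 0.2, 0.2, 8)
    f <- fit_mixture(s$errors, s$nontarget_errors)
    expect_lt(abs(f$p_t - 0.6), 0.05)
    expect_lt(abs(f$p_n - 0.2), 0.05)
    expect_lt(abs(f$p_u - 0.2), 0.05)
    expect_lt(abs(f$kappa - 8), 8 * 0.15)
    expect_true(all(diff(f$trace) >= -1e-9))   # EM monotonicity
    expect_equal(f$p_t + f$p_n + f$p_u, 1, tolerance = 1e-9)

    # load-1 data force pN = 0
    s1 <- rmixture_errors(3000, 0.8, 0, 0.2, 8)
    f1 <- fit_mixture(s1$errors)
    expect_identical(f1$p_n, 0)
    expect_lt(abs(f1$p_t - 0.8), 0.05)
  })
})

test_that("mixture log-likelihood closed forms and local optimality", {
  e <- seq(-3, 3, length.out = 100)
  unif <- list(kappa = 5, p_t = 0, p_n = 0, p_u = 1)
  expect_equal(mixture_loglik(unif, e), -100 * log(2 * pi))
  # VM(kappa = 0) is uniform
  flat <- list(kappa = 0, p_t = 1, p_n = 0, p_u = 0)
  expect_equal(mixture_loglik(flat, e), -100 * log(2 * pi))

  withr::with_seed(83, {
    s <- rmixture_errors(2000, 0.6, 0.2, 0.2, 8)
    f <- fit_mixture(s$errors, s$nontarget_errors)
    ll0 <- mixture_loglik(f, s$errors, s$nontarget_errors)
    expect_equal(ll0, f$loglik, tolerance = 1e-6)
    for (i in 1:20) {
      p <- abs(c(f$p_t, f$p_n, f$p_u) + rnorm(3, 0, 0.03))
      p <- p / sum(p)
      pert <- list(kappa = max(f$kappa * exp(rnorm(1, 0, 0.1)), 0.1),
                   p_t = p[1], p_n = p[2], p_u = p[3])
      expect_lte(mixture_loglik(pert, s$errors, s$nontarget_errors),
                 ll0 + 1e-6)
    }
  })
})

test_that("kappa estimation matches the closed-form von Mises MLE", {
  # Bessel-ratio inversion round-trips
  for (k in c(0.1, 0.5, 2, 8, 50, 500))
    expect_equal(wmattractor:::bessel_ratio_inv(
      wmattractor:::bessel_ratio(k)), k, tolerance = 1e-6 * (1 + k))
  # on pure von Mises data with negligible guessing the EM kappa matches
  # the closed form A^{-1}(Rbar)
  withr::with_seed(84, {
    e <- rvonmises0(4000, 6)
    f <- fit_mixture(e)
    closed <- wmattractor:::bessel_ratio_inv(wmattractor:::circ_resultant(e))
    expect_lt(f$p_u, 0.02)
    expect_lt(abs(f$kappa - closed), 0.05 * closed)
  })
})

test_that("mixture fit is invariant to a global rotation of the data", {
  tr <- fixture_attractor6()[1:4000, ]
  te <- trial_errors(tr)
  f <- fit_mixture(te$error_rad, te$nontarget_error_rad, restarts = 2)
  rot <- tr
  shift <- 11L
  rot$target_idx <- ((rot$target_idx - 1L + shift) %% 64L) + 1L
  rot$nontarget_idx <- ((rot$nontarget_idx - 1L + shift) %% 64L) + 1L
  rot$response_angle <- wmattractor:::wrap_0_2pi(
    rot$response_angle + shift * 2 * pi / 64)
  rot$response_idx <- ((rot$response_idx - 1L + shift) %% 64L) + 1L
  ter <- trial_errors(rot)
  fr <- fit_mixture(ter$error_rad, ter$nontarget_error_rad, restarts = 2)
  expect_equal(fr$p_t, f$p_t, tolerance = 1e-6)
  expect_equal(fr$kappa, f$kappa, tolerance = 1e-6)
})

test_that("swap-error rate recovers the injected swap probability", {
  load2_weights <- c(0, 0, 0, 1, 1, 1, 1, 1, 1)
  base <- generate_sessions(session_config(5000, load2_weights, seed = 85))
  none <- generate_responses(base, generative_model(
    demo_drift_field(6), sigma_encode = c(0.15, 0.2),
    sigma_memory = c(0.2, 0.25), p_swap = 0), seed = 86)
  r0 <- swap_error_rate(none)
  expect_lt(r0$p_n, 0.02)

  swapped <- generate_responses(base, generative_model(
    demo_drift_field(6), sigma_encode = c(0.15, 0.2),
    sigma_memory = c(0.2, 0.25), p_swap = 0.2), seed = 87)
  r <- swap_error_rate(swapped)
  expect_lt(abs(r$p_n - 0.2), 0.03)

  # all responses on the non-target
  pure <- generate_responses(base, generative_model(
    demo_drift_field(6), sigma_encode = c(0, 0), sigma_memory = c(0, 0),
    p_swap = 1), seed = 88)
  rp <- swap_error_rate(pure)
  expect_gt(rp$p_n, 0.95)
  expect_gt(rp$responsibility_rate, 0.9)
  expect_error(swap_error_rate(none[none$load == 1L, ]), "load-2")
})
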