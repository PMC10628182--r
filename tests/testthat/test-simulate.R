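test_that("session generation is deterministic and covers the 9 trial types", {
  cfg <- session_config(500, seed = 99)
  a <- generate_sessions(cfg)
  b <- generate_sessions(cfg)
  expect_identical(a, b)
  expect_identical(nrow(a), 500L)
  big <- generate_sessions(session_config(90000, seed = 100))
  combos <- unique(big[, c("load", "cue", "delay_class")])
  expect_identical(nrow(combos), 9L)
  # equal weights: each type frequency within 3 binomial standard errors
  freq <- table(paste(big$load, big$cue, big$delay_class)) / nrow(big)
  se <- sqrt((1 / 9) * (8 / 9) / nrow(big))
  expect_true(all(abs(freq - 1 / 9) < 3 * se))
  expect_error(session_config(100, trial_type_weights = rep(0, 9)),
               "zero")
})

test_that("prev_target_idx carries the previous trial's target within sessions", {
  tr <- generate_sessions(session_config(300, seed = 3, n_sessions = 3))
  first <- !duplicated(tr$session_id)
  expect_true(all(is.na(tr$prev_target_idx[first])))
  expect_identical(tr$prev_target_idx[!first],
                   tr$target_idx[which(!first) - 1L])
})

test_that("Euler-Maruyama endpoints match closed forms in degenerate regimes", {
  f <- demo_drift_field(6)
  th0 <- c(0.3, 2, 5)
  expect_identical(simulate_trajectory(th0, f, 0, 0, 4), th0)
  expect_identical(simulate_trajectory(th0, f, 2, 0.5, 0), th0)
  # pure diffusion: resultant of endpoints matches the wrapped normal
  # R = exp(-sigma^2 t / 2) within 2%
  withr::with_seed(11, {
    th <- simulate_trajectory(rep(1, 1e5), f, 0, 0.5, 2)
    r <- wmattractor:::circ_resultant(th)
    expect_equal(r, exp(-0.5^2 * 2 / 2), tolerance = 0.02)
  })
})

test_that("strong drift with weak noise funnels trajectories into the attractor", {
  f1 <- wmattractor:::project_drift(function(th) -sin(th))
  withr::with_seed(12, {
    th0 <- runif(2000, 0, 2 * pi)
    th <- simulate_trajectory(th0, f1, 2, 0.05, 5)
    d <- abs(wmattractor:::wrap_pi(th))
    expect_gt(mean(d < 0.3), 0.99)
  })
})

test_that("deterministic generative model reproduces targets exactly", {
  tr <- generate_sessions(session_config(300, seed = 5))
  m <- generative_model(demo_drift_field(6), beta_encode = c(0, 0),
                        sigma_encode = c(0, 0), beta_memory = c(0, 0),
                        sigma_memory = c(0, 0))
  out <- generate_responses(tr, m, seed = 6)
  expect_identical(out$response_idx, out$target_idx)
  expect_true(all(out$reward_pellets == 3L))
  # determinism
  out2 <- generate_responses(tr, m, seed = 6)
  expect_identical(out, out2)
})

test_that("guessing-only model produces uniform responses", {
  tr <- generate_sessions(session_config(2000, seed = 15))
  m <- generative_model(demo_drift_field(6), p_guess = c(1, 1))
  out <- generate_responses(tr, m, seed = 16)
  ha <- hodges_ajne_test(out$response_angle - out$wheel_rotation)
  expect_gt(ha$p_value, 0.05)
})

test_that("swap branch hits the injected swap rate", {
  tr <- generate_sessions(session_config(
    10000, trial_type_weights = c(0, 0, 0, 1, 1, 1, 1, 1, 1), seed = 17))
  m <- generative_model(demo_drift_field(6), sigma_encode = c(0.05, 0.05),
                        sigma_memory = c(0.05, 0.05), p_swap = 0.2)
  out <- generate_responses(tr, m, seed = 18)
  te <- trial_errors(out)
  nearer_nt <- abs(te$nontarget_error_rad) < abs(te$error_rad)
  expect_lt(abs(mean(nearer_nt) - 0.2 * 63 / 64), 0.02)
  # swap on a load-1-only table is rejected
  tr1 <- generate_sessions(session_config(
    100, trial_type_weights = c(1, 1, 1, 0, 0, 0, 0, 0, 0), seed = 19))
  expect_error(generate_responses(tr1, m, seed = 20), "load-2")
})

test_that("injected serial dependence is recovered by regression on sin(delta)", {
  tr <- generate_sessions(session_config(8000, seed = 23))
  m <- generative_model(demo_drift_field(6), sigma_encode = c(0.1, 0.1),
                        sigma_memory = c(0.15, 0.2))
  out <- generate_responses(tr, m, seed = 24, serial_bias_gain = 0.1)
  te <- trial_errors(out)
  ok <- !is.na(te$prev_target_idx)
  delta <- signed_angular_error(index_to_angle(te$prev_target_idx[ok]),
                                index_to_angle(te$target_idx[ok]))
  slope <- coef(lm(te$error_rad[ok] ~ sin(delta)))[2]
  expect_lt(abs(unname(slope) - 0.1), 0.03)
})
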