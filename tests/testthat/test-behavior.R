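test_that("performance matrices: perfect, chance, and nesting behavior", {
  tr <- generate_sessions(session_config(2000, seed = 31))
  exact <- generate_responses(tr, generative_model(
    demo_drift_field(6), sigma_encode = c(0, 0), sigma_memory = c(0, 0)),
    seed = 32)
  pm <- performance_by_condition(exact)
  expect_true(all(pm$full == 1 & pm$inner == 1 & pm$exact == 1))

  guess <- generate_responses(tr, generative_model(
    demo_drift_field(6), p_guess = c(1, 1)), seed = 33)
  pmg <- performance_by_condition(guess)
  # pooled full-range proportion at the 7/64 chance level
  pooled <- sum(pmg$full * pmg$counts, na.rm = TRUE) / sum(pmg$counts)
  se <- sqrt((7 / 64) * (57 / 64) / nrow(guess))
  expect_lt(abs(pooled - 7 / 64), 4 * se)

  # accuracy-level nesting in every cell of a structured dataset
  pma <- performance_by_condition(fixture_attractor6())
  expect_true(all(pma$exact <= pma$inner + 1e-12, na.rm = TRUE))
  expect_true(all(pma$inner <= pma$full + 1e-12, na.rm = TRUE))
  expect_equal(dim(pma$full), c(3L, 3L))
})

test_that("bias and precision: fixed offset, uniform chance, Bessel oracle", {
  bp <- bias_and_precision(rep(0.2, 50))
  expect_equal(bp$bias, 0.2)
  expect_true(bp$degenerate)

  withr::with_seed(41, {
    # chance correction removes the ~0.31 uniform-sample bias of 1/SD;
    # averaged over replicate uniform datasets the corrected precision is 0
    prec <- replicate(10, bias_and_precision(runif(1000, -pi, pi))$precision)
    expect_lt(abs(mean(prec)), 0.05)
    # uncorrected 1/circular-SD of von Mises kappa=2 data approaches
    # 1/sqrt(-2 log(I1(2)/I0(2)))
    e <- rvonmises0(20000, 2)
    oracle <- 1 / sqrt(-2 * log(besselI(2, 1) / besselI(2, 0)))
    expect_equal(1 / wmattractor:::circ_sd(e), oracle, tolerance = 0.02)
  })
})

test_that("normalized response frequency conserves mass and flags unused colors", {
  tr <- generate_sessions(session_config(3000, seed = 43))
  exact <- generate_responses(tr, generative_model(
    demo_drift_field(6), sigma_encode = c(0, 0), sigma_memory = c(0, 0)),
    seed = 44)
  nf <- normalized_response_frequency(exact)
  expect_equal(nf$ratio, rep(1, 64))
  # mass conservation on a structured dataset
  tra <- fixture_attractor6()
  nfa <- normalized_response_frequency(tra)
  expect_equal(sum(nfa$ratio * nfa$n_target), nrow(tra))
  bad <- exact
  bad$target_idx[bad$target_idx == 7L] <- 8L
  bad$response_idx <- bad$target_idx
  bad$response_angle <- wmattractor:::wrap_0_2pi(
    index_to_angle(bad$target_idx) + bad$wheel_rotation)
  expect_error(normalized_response_frequency(bad), "7")
})

test_that("Hodges-Ajne: exact formula, uniform branch, and permutation oracle", {
  withr::with_seed(51, {
    ha <- hodges_ajne_test(runif(10, 0, pi))
    expect_identical(ha$m, 0L)
    expect_equal(ha$p_value, 10 / 2^9)

    # antipodal pairs evenly spread: maximally uniform, m = n/2 branch
    anti <- (0:11) * pi / 6 + 0.01
    hau <- hodges_ajne_test(anti)
    expect_identical(hau$m, 6L)
    expect_gt(hau$p_value, 0.5)

    # strong clustering is detected
    hac <- hodges_ajne_test(rnorm(2000, pi, 0.4) %% (2 * pi))
    expect_lt(hac$p_value, 1e-4)

    # exact p agrees with a Monte-Carlo null for small n
    for (nn in c(9, 17)) {
      x <- runif(nn, 0, 0.8 * pi)
      ex <- hodges_ajne_test(x)
      if (ex$method != "exact") next
      mc <- mean(replicate(20000, {
        wmattractor:::hodges_ajne_m(runif(nn, 0, 2 * pi)) <= ex$m
      }))
      se <- sqrt(max(mc * (1 - mc), 1e-6) / 20000)
      expect_lt(abs(ex$p_value - mc), 4 * se + 1e-3)
    }
  })
})

test_that("Cochran's Q: degenerate, worked example, and power", {
  same <- cbind(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0))
  q0 <- cochrans_q_test(same)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p_value, 1)
  expect_true(q0$degenerate)
  # 5 blocks x 2 groups worked example: equals McNemar (b-c)^2/(b+c) = 3
  q <- cochrans_q_test(rbind(c(1, 0), c(1, 0), c(1, 0), c(1, 1), c(0, 0)))
  expect_equal(q$Q, 3)
  expect_equal(q$df, 1L)
  withr::with_seed(53, {
    strong <- cbind(rbinom(100, 1, 0.9), rbinom(100, 1, 0.1))
    expect_lt(cochrans_q_test(strong)$p_value, 0.001)
  })
  q2 <- cochrans_q_test(rbind(c(1, 1), c(0, 0)))
  expect_true(q2$degenerate)
  expect_equal(q2$Q, 0)
})

test_that("binomial chance test matches exact tail enumeration", {
  expect_equal(binomial_chance_test(0, 10, 0.11), 1)
  expect_equal(binomial_chance_test(50, 50, 0.11), 0.11^50)
  enum <- sum(sapply(5:10, function(i) choose(10, i) * 0.11^i * 0.89^(10 - i)))
  expect_equal(binomial_chance_test(5, 10, 0.11), enum, tolerance = 1e-12)
})

test_that("partial omega-squared: null unbiasedness and effect ordering", {
  make_data <- function(load_eff, delay_eff, sd = 0.05, sessions = 4) {
    g <- expand.grid(session_id = seq_len(sessions), load = 1:3, delay = 1:3)
    g$value <- load_eff * g$load + delay_eff * g$delay + rnorm(nrow(g), 0, sd)
    g
  }
  withr::with_seed(61, {
    nulls <- replicate(200, {
      vp <- variance_partitioning(make_data(0, 0))
      vp$omega_sq_partial
    })
    expect_true(all(abs(rowMeans(nulls)) < 0.02))
    vp <- variance_partitioning(make_data(0.2, 0.05))
    om <- setNames(vp$omega_sq_partial, vp$term)
    expect_gt(om[["load"]], om[["delay"]])
    expect_gt(om[["load"]], 0.5)
    vp0 <- variance_partitioning(make_data(0.3, 0))
    om0 <- setNames(vp0$omega_sq_partial, vp0$term)
    expect_lt(abs(om0[["delay"]]), 0.3)
    expect_gt(om0[["load"]], 0.8)
  })
  unbal <- data.frame(session_id = 1:4, load = c(1, 1, 2, 2),
                      delay = c(1, 2, 1, 1), value = rnorm(4))
  expect_error(variance_partitioning(unbal), "cell|balanced")
})

test_that("Friedman test: degenerate, perfect concordance, and sensitivity", {
  flat <- matrix(1, 5, 3)
  f0 <- friedman_test(flat)
  expect_equal(f0$chisq, 0)
  expect_equal(f0$p_value, 1)
  expect_equal(f0$kendall_w, 0)
  perfect <- matrix(rep(c(1, 2, 3), each = 20), 20, 3)
  expect_equal(friedman_test(perfect)$kendall_w, 1)
  withr::with_seed(63, {
    shifted <- matrix(rnorm(60), 20, 3) +
      matrix(rep(c(0, 1, 2), each = 20), 20, 3)
    ft <- friedman_test(shifted)
    expect_lt(ft$p_value, 0.01)
    # permutation oracle: permute conditions within blocks
    perm <- replicate(500, {
      p <- t(apply(shifted, 1, sample))
      friedman_test(p)$chisq
    })
    expect_lt(mean(perm >= ft$chisq), 0.01)
  })
})

test_that("serial-dependence curve recovers injected attraction and dies under shuffling", {
  tr <- generate_sessions(session_config(20000, seed = 71))
  m <- generative_model(demo_drift_field(6), sigma_encode = c(0.1, 0.1),
                        sigma_memory = c(0.15, 0.2))
  none <- generate_responses(tr, m, seed = 72, serial_bias_gain = 0)
  sb0 <- serial_dependence_curve(none)
  expect_lt(abs(sb0$peak_magnitude), 0.03)

  biased <- generate_responses(tr, m, seed = 72, serial_bias_gain = 0.1)
  sb <- serial_dependence_curve(biased)
  expect_lt(abs(sb$peak_magnitude - 0.1), 0.02)
  expect_lt(abs(sb$peak_location_deg - 90), 10)

  withr::with_seed(73, {
    shuffled <- biased
    ok <- !is.na(shuffled$prev_target_idx)
    shuffled$prev_target_idx[ok] <- sample(shuffled$prev_target_idx[ok])
    sbs <- serial_dependence_curve(shuffled)
    expect_lt(abs(sbs$peak_magnitude), 0.03)
  })
  expect_error(serial_dependence_curve(biased[1:10, ]), "usable")
})
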