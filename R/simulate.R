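# Synthetic-data generator: sessions and responses from a known
# generative attractor drift-diffusion model.

#' Session generator configuration
#'
#' @param n_trials number of trials to generate.
#' @param trial_type_weights 9 non-negative weights over the trial-type grid
#'   of [trial_types()] (3 load conditions x 3 delay classes); equal by
#'   default, matching the pseudorandomized type schedule of the task.
#' @param n_colors number of hues on the wheel.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param serial_bias_gain amplitude (radians) of the injected serial
#'   dependence on the previous target; 0 disables it.
#' @param n_sessions number of equally sized sessions the trials are split
#'   into (session labels are needed for session-level analyses).
#' @param delay_map named map from delay class to seconds.
#' @return an object of class `session_config`.
#' @export
session_config <- function(n_trials, trial_type_weights = rep(1, 9),
                           n_colors = 64L, seed = 1L,
                           serial_bias_gain = 0, n_sessions = 1L,
                           delay_map = default_delay_map()) {
  if (n_trials < 1) stop_wm("n_trials must be >= 1")
  if (length(trial_type_weights) != 9 || any(trial_type_weights < 0))
    stop_wm("trial_type_weights must be 9 non-negative numbers")
  if (sum(trial_type_weights) <= 0)
    stop_wm("trial_type_weights must not all be zero")
  structure(list(n_trials = as.integer(n_trials),
                 trial_type_weights = trial_type_weights,
                 n_colors = as.integer(n_colors), seed = as.integer(seed),
                 serial_bias_gain = serial_bias_gain,
                 n_sessions = as.integer(n_sessions),
                 delay_map = delay_map),
            class = "session_config")
}

#' Generative attractor drift-diffusion model
#'
#' The memory of a color angle theta evolves by the stochastic differential
#' equation `d theta = beta * G(theta) dt + sigma dW`, with a 1-s encoding
#' phase (encoding gains/noise) followed by the trial's delay (memory
#' gains/noise); gains and noise are load-specific. Responses are a mixture:
#' with probability `p_guess` a uniform guess, otherwise (load 2 only) with
#' probability `p_swap` the simulated trajectory of the non-target, and
#' otherwise the trajectory of the target.
#'
#' @param drift a [drift_field()].
#' @param beta_encode,beta_memory numeric length-2 vectors, drift gain per
#'   load (1/s scale).
#' @param sigma_encode,sigma_memory numeric length-2 vectors, diffusion per
#'   load (radians per sqrt-second).
#' @param p_swap probability of a swap response on load-2 trials.
#' @param p_guess length-2 vector, guess probability per load.
#' @param encode_duration_s encoding duration (seconds).
#' @return object of class `generative_model`.
#' @export
generative_model <- function(drift, beta_encode = c(0, 0),
                             sigma_encode = c(0.15, 0.25),
                             beta_memory = c(0, 0),
                             sigma_memory = c(0.25, 0.35),
                             p_swap = 0, p_guess = c(0, 0),
                             encode_duration_s = 1) {
  stopifnot(inherits(drift, "drift_field"))
  rep2 <- function(x) if (length(x) == 1) rep(x, 2) else x
  beta_encode <- rep2(beta_encode); beta_memory <- rep2(beta_memory)
  sigma_encode <- rep2(sigma_encode); sigma_memory <- rep2(sigma_memory)
  p_guess <- rep2(p_guess)
  if (any(c(sigma_encode, sigma_memory) < 0)) stop_wm("sigma must be >= 0")
  if (any(c(beta_encode, beta_memory) < 0))
    stop_wm("beta must be >= 0 (signs belong to the drift weights)")
  if (p_swap < 0 || p_swap > 1 || any(p_guess < 0 | p_guess > 1))
    stop_wm("probabilities must lie in [0, 1]")
  if (any(p_swap + p_guess > 1)) stop_wm("p_swap + p_guess must be <= 1")
  structure(list(drift = drift, beta_encode = beta_encode,
                 sigma_encode = sigma_encode, beta_memory = beta_memory,
                 sigma_memory = sigma_memory, p_swap = p_swap,
                 p_guess = p_guess, encode_duration_s = encode_duration_s),
            class = "generative_model")
}

#' Generate task sessions (trials without responses)
#'
#' Trial types are drawn from the 9-type grid with the configured weights;
#' target (and, on load-2 trials, non-target) indices are i.i.d. uniform over
#' the wheel; the wheel rotation is i.i.d. uniform on `[0, 2*pi)`;
#' `prev_target_idx` carries the preceding trial's target within each
#' session (NA on the first trial of a session).
#'
#' @param config a [session_config()].
#' @return trial data.frame (responses absent), deterministic given the seed.
#' @export
generate_sessions <- function(config) {
  stopifnot(inherits(config, "session_config"))
  tt <- trial_types(config$delay_map)
  n <- config$n_trials
  with_seed(config$seed, {
    type <- sample.int(9L, n, replace = TRUE,
                       prob = config$trial_type_weights / sum(config$trial_type_weights))
    target <- sample.int(config$n_colors, n, replace = TRUE)
    nontarget <- sample.int(config$n_colors, n, replace = TRUE)
    rotation <- stats::runif(n, 0, 2 * pi)
    session <- sort(rep_len(seq_len(config$n_sessions), n))
    load <- tt$load[type]
    nontarget[load == 1L] <- NA_integer_
    prev <- c(NA_integer_, target[-n])
    prev[c(TRUE, diff(session) != 0)] <- NA_integer_
    trials <- data.frame(
      bird_id = "SYN", session_id = sprintf("s%03d", session),
      trial_index = stats::ave(seq_len(n), session, FUN = seq_along),
      load = load, cue = tt$cue[type], delay_class = tt$delay_class[type],
      delay_s = tt$delay_s[type], target_idx = target,
      nontarget_idx = nontarget, wheel_rotation = rotation,
      response_angle = NA_real_, response_idx = NA_integer_,
      prev_target_idx = prev, reward_pellets = NA_integer_,
      stringsAsFactors = FALSE
    )
    validate_trials(trials, color_wheel(config$n_colors), config$delay_map)
  })
}

#' Euler-Maruyama simulation of the memory diffusion
#'
#' Integrates `d theta = beta * G(theta) dt + sigma dW` on the circle and
#' returns the endpoint(s), wrapped to `[0, 2*pi)`. Vectorized over
#' `theta0`: all trajectories advance in lock-step, sharing the drift
#' lookup table. With `duration_s = 0` the start angles are returned
#' unchanged. Consumes the caller's RNG stream.
#'
#' @param theta0 start angle(s), radians.
#' @param drift a [drift_field()].
#' @param beta drift gain.
#' @param sigma diffusion (radians per sqrt-second).
#' @param duration_s integration time (seconds).
#' @param dt time step (seconds); the default 0.01 keeps the integration
#'   bias far below the statistical tolerances used in the test bed.
#' @return endpoint angles in `[0, 2*pi)`.
#' @export
simulate_trajectory <- function(theta0, drift, beta, sigma, duration_s,
                                dt = 0.01) {
  if (dt <= 0) stop_wm("dt must be positive")
  if (duration_s < 0) stop_wm("duration must be >= 0")
  theta <- wrap_0_2pi(theta0)
  if (duration_s == 0) return(theta)
  n_steps <- ceiling(duration_s / dt - 1e-9)
  dt_last <- duration_s - (n_steps - 1) * dt
  use_drift <- beta != 0 && any(drift$weights != 0)
  lut <- if (use_drift) drift_lookup(drift) else NULL
  m <- length(theta)
  for (s in seq_len(n_steps)) {
    h <- if (s == n_steps) dt_last else dt
    incr <- if (sigma > 0) stats::rnorm(m, 0, sigma * sqrt(h)) else 0
    v <- if (use_drift) beta * drift_lookup_eval(lut, theta) else 0
    theta <- wrap_0_2pi(theta + v * h + incr)
  }
  theta
}

#' Generate responses for a trial table from the generative model
#'
#' For each trial, with probability `p_guess[load]` the response is a uniform
#' guess; otherwise, on load-2 trials with probability `p_swap`, the response
#' is the simulated trajectory of the non-target through encoding and delay;
#' otherwise that of the target. The trajectory runs the encoding phase with
#' the load's encoding gain and noise, then the trial's delay with the
#' memory gain and noise. An optional serial bias shifts the response toward
#' the previous target by `serial_bias_gain * sin(prev - current)` (first
#' circular harmonic). `response_angle` (wheel frame), `response_idx` and
#' `reward_pellets` are filled consistently.
#'
#' @param trials table from [generate_sessions()].
#' @param model a [generative_model()].
#' @param dt Euler-Maruyama step (seconds).
#' @param seed integer seed.
#' @param serial_bias_gain serial-dependence amplitude in radians.
#' @param wheel a [color_wheel()].
#' @return the trial table with responses, deterministic given the seed.
#' @export
generate_responses <- function(trials, model, dt = 0.01, seed = 1L,
                               serial_bias_gain = 0,
                               wheel = color_wheel()) {
  stopifnot(inherits(model, "generative_model"))
  n <- nrow(trials)
  if (model$p_swap > 0 && !any(trials$load == 2L))
    stop_wm("p_swap > 0 requires load-2 trials")
  with_seed(seed, {
    u <- stats::runif(n)
    branch <- rep("target", n)
    pg <- model$p_guess[trials$load]
    branch[u < pg] <- "guess"
    is_swap <- trials$load == 2L & u >= pg & u < pg + model$p_swap
    branch[is_swap] <- "swap"
    start_idx <- trials$target_idx
    start_idx[branch == "swap"] <- trials$nontarget_idx[branch == "swap"]
    theta <- index_to_angle(start_idx, wheel)
    # advance all memory trials in lock-step groups: encoding per load,
    # then delay per (load, delay)
    sim <- branch != "guess"
    for (ld in 1:2) {
      g <- sim & trials$load == ld
      if (!any(g)) next
      theta[g] <- simulate_trajectory(theta[g], model$drift,
                                      model$beta_encode[ld],
                                      model$sigma_encode[ld],
                                      model$encode_duration_s, dt)
      for (d in unique(trials$delay_s[g])) {
        gd <- g & trials$delay_s == d
        theta[gd] <- simulate_trajectory(theta[gd], model$drift,
                                         model$beta_memory[ld],
                                         model$sigma_memory[ld], d, dt)
      }
    }
    theta[branch == "guess"] <- stats::runif(sum(branch == "guess"), 0, 2 * pi)
    if (serial_bias_gain != 0) {
      has_prev <- !is.na(trials$prev_target_idx)
      delta <- signed_angular_error(
        index_to_angle(trials$prev_target_idx[has_prev], wheel),
        index_to_angle(trials$target_idx[has_prev], wheel))
      theta[has_prev] <- wrap_0_2pi(theta[has_prev] +
                                      serial_bias_gain * sin(delta))
    }
    trials$response_angle <- wrap_0_2pi(theta + trials$wheel_rotation)
    trials$response_idx <- angle_to_index(theta, wheel)
    trials$reward_pellets <- reward_level(
      index_error(trials$response_idx, trials$target_idx, wheel), wheel)
    trials
  })
}
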