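# Fokker-Planck propagation of memory densities on the periodic grid.

#' Probability density over the circular color space
#'
#' @param p non-negative density values on a uniform periodic grid over
#'   `[0, 2*pi)`; normalized to integrate to 1.
#' @param grid_size number of grid points (used when `p` is a single delta
#'   location, see `delta_field()`).
#' @param time time stamp in seconds.
#' @return object of class `probability_field` with `p`, `grid`, `h`, `time`.
#' @export
probability_field <- function(p, time = 0) {
  n <- length(p)
  if (n < 8) stop_wm("grid too small")
  if (any(p < -1e-12)) stop_wm("density must be non-negative")
  p <- pmax(p, 0)
  h <- 2 * pi / n
  mass <- sum(p) * h
  if (mass <= 0) stop_wm("density has no mass")
  structure(list(p = p / mass, grid = (seq_len(n) - 1) * h, h = h,
                 time = time),
            class = "probability_field")
}

#' @param theta0 location of the unit point mass (assigned to the nearest
#'   grid bin).
#' @rdname probability_field
#' @export
delta_field <- function(theta0, grid_size = 128L) {
  h <- 2 * pi / grid_size
  p <- numeric(grid_size)
  i <- (round(wrap_0_2pi(theta0) / h) %% grid_size) + 1
  p[i] <- 1 / h
  probability_field(p)
}

## Bernoulli generating function B(x) = x / (exp(x) - 1), stable near 0.
bernoulli_fun <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2
  out[!small] <- x[!small] / expm1(x[!small])
  out
}

## Exponentially-fitted (Scharfetter-Gummel) finite-volume generator of the
## Fokker-Planck equation dp/dt = -d[v p]/dtheta + D d2p/dtheta2 on the
## periodic grid, v = beta*G, D = sigma^2/2. Acting on bin probabilities it
## is a continuous-time Markov generator: off-diagonal rates >= 0, columns
## sum to zero, so expm(L t) conserves mass and positivity exactly. In the
## limit D -> 0 the rates reduce to pure upwind advection.
fp_generator <- function(field, beta, sigma, grid_size = 128L) {
  n <- grid_size
  h <- 2 * pi / n
  mid <- (seq_len(n) - 0.5) * h   # interface between bin i and i+1
  v <- if (beta != 0) beta * evaluate_drift(field, mid) else numeric(n)
  D <- sigma^2 / 2
  if (D < 1e-12) {
    fwd <- pmax(v, 0) / h          # rate i -> i+1
    bwd <- pmax(-v, 0) / h         # rate i+1 -> i
  } else {
    w <- v * h / D
    fwd <- (D / h^2) * bernoulli_fun(-w)
    bwd <- (D / h^2) * bernoulli_fun(w)
  }
  L <- matrix(0, n, n)
  ip <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n)) {
    j <- ip[i]
    L[j, i] <- L[j, i] + fwd[i]
    L[i, i] <- L[i, i] - fwd[i]
    L[i, j] <- L[i, j] + bwd[i]
    L[j, j] <- L[j, j] - bwd[i]
  }
  L
}

## Transition matrix over bin probabilities for a finite duration.
## Column j is the propagated distribution of a point mass in bin j, so a
## single call yields the response kernel for every possible start color.
propagate_kernel <- function(field, beta, sigma, duration_s,
                             grid_size = 128L) {
  if (duration_s < 0) stop_wm("duration must be >= 0")
  n <- grid_size
  if (duration_s == 0 || (beta == 0 && sigma == 0)) return(diag(n))
  L <- fp_generator(field, beta, sigma, n)
  M <- as.matrix(Matrix::expm(Matrix::Matrix(L * duration_s, sparse = FALSE)))
  M[M < 0] <- 0           # expm round-off, O(1e-16)
  sweep(M, 2, colSums(M), "/")
}

#' Propagate a memory density through drift and diffusion
#'
#' Solves the Fokker-Planck equation
#' `dp/dt = -d[beta G(theta) p]/dtheta + (sigma^2/2) d2p/dtheta2`
#' on the periodic grid for `duration_s` seconds, via an exponentially
#' fitted finite-volume generator and its matrix exponential. The scheme is
#' unconditionally stable, conserves probability mass to machine precision,
#' preserves non-negativity, and is exact in time (the semigroup property
#' holds up to round-off), so no time-step or CFL control is needed.
#'
#' @param p0 a [probability_field()].
#' @param field a [drift_field()].
#' @param beta drift gain for this phase/load.
#' @param sigma diffusion for this phase/load.
#' @param duration_s integration time (seconds).
#' @return the propagated [probability_field()].
#' @export
propagate <- function(p0, field, beta, sigma, duration_s) {
  stopifnot(inherits(p0, "probability_field"))
  M <- propagate_kernel(field, beta, sigma, duration_s, length(p0$p))
  q <- as.numeric(M %*% (p0$p * p0$h))
  probability_field(q / p0$h, time = p0$time + duration_s)
}

## Periodic linear interpolation of a gridded density at arbitrary angles.
density_at <- function(pf, theta) {
  n <- length(pf$p)
  x <- wrap_0_2pi(theta) / pf$h
  i <- floor(x) %% n
  fr <- x - floor(x)
  pf$p[i + 1] * (1 - fr) + pf$p[(i + 1) %% n + 1] * fr
}

#' Predicted response distribution for one trial condition
#'
#' A point mass at the target color is propagated through the 1-s encoding
#' phase (encoding gain/noise of the trial's load) and then through the
#' memory delay (memory gain/noise). On load-2 trials the non-target is
#' propagated through the same pipeline, and the final response density is
#' the mixture `(1 - p_swap - p_guess) target + p_swap nontarget +
#' p_guess / (2*pi)`.
#'
#' @param load 1 or 2.
#' @param delay_s memory delay in seconds.
#' @param target target color angle (radians).
#' @param nontarget non-target color angle, required iff `load == 2`.
#' @param params a [ddm_params()].
#' @param grid_size grid resolution.
#' @return a [probability_field()] over response color angles.
#' @export
predict_response_distribution <- function(load, delay_s, target,
                                          nontarget = NULL, params,
                                          grid_size = 128L) {
  stopifnot(inherits(params, "ddm_params"))
  if (load == 2 && is.null(nontarget))
    stop_wm("load-2 prediction needs a nontarget angle")
  if (load == 1 && !is.null(nontarget))
    stop_wm("load-1 prediction must not have a nontarget")
  p_swap <- if (load == 2) params$p_swap else 0
  p_guess <- params$p_guess[load]
  if (p_swap + p_guess > 1) stop_wm("invalid mixture weights")
  chain <- function(theta0) {
    pf <- delta_field(theta0, grid_size)
    pf <- propagate(pf, params$drift, params$beta_encode[load],
                    params$sigma_encode[load], params$encode_duration_s)
    propagate(pf, params$drift, params$beta_memory[load],
              params$sigma_memory[load], delay_s)
  }
  pt <- chain(target)
  p <- (1 - p_swap - p_guess) * pt$p
  if (load == 2 && p_swap > 0) p <- p + p_swap * chain(nontarget)$p
  p <- p + p_guess / (2 * pi)
  probability_field(p, time = params$encode_duration_s + delay_s)
}
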