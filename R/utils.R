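# Internal numerical helpers shared across modules.

#' Wrap angles to a canonical interval
#'
#' `wrap_0_2pi()` maps angles to `[0, 2*pi)`; `wrap_pi()` maps angular
#' differences to `(-pi, pi]`.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of the same length.
#' @keywords internal
wrap_0_2pi <- function(theta) theta %% (2 * pi)

#' @rdname wrap_0_2pi
#' @keywords internal
wrap_pi <- function(theta) {
  x <- theta %% (2 * pi)
  ifelse(x > pi, x - 2 * pi, x)
}

## Mean resultant length of a sample of angles.
circ_resultant <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  s <- sum(w)
  if (s <= 0) return(0)
  sqrt(sum(w * cos(theta))^2 + sum(w * sin(theta))^2) / s
}

## Circular mean in (-pi, pi].
circ_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  wrap_pi(atan2(sum(w * sin(theta)), sum(w * cos(theta))))
}

## Circular standard deviation sqrt(-2 log Rbar).
circ_sd <- function(theta) {
  r <- circ_resultant(theta)
  r <- min(max(r, .Machine$double.xmin), 1)
  sqrt(-2 * log(r))
}

## Bessel-function ratio A1(kappa) = I1(kappa)/I0(kappa), overflow-safe.
bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

## Invert A1: find kappa with I1(kappa)/I0(kappa) = r.
## Standard piecewise starting approximations (Fisher 1993) refined by Newton;
## d A1/d kappa = 1 - A1/kappa - A1^2.
bessel_ratio_inv <- function(r, kappa_max = 1e4) {
  if (r <= 0) return(0)
  if (r >= 1) return(kappa_max)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  k <- min(max(k, 1e-8), kappa_max)
  for (i in 1:25) {
    a <- bessel_ratio(k)
    d <- 1 - a / k - a^2
    if (abs(d) < 1e-14) break
    step <- (a - r) / d
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    k_new <- min(k_new, kappa_max)
    if (abs(k_new - k) < 1e-12 * (1 + k)) { k <- k_new; break }
    k <- k_new
  }
  k
}

## von Mises log-density with mean 0.
dvonmises_log <- function(theta, kappa) {
  kappa * (cos(theta) - 1) - log(2 * pi) -
    log(besselI(kappa, 0, expon.scaled = TRUE))
}

dvonmises <- function(theta, kappa) exp(dvonmises_log(theta, kappa))

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

## Derive a named substream seed from a master seed (kept below 2^31).
substream_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) + offs * 10007L) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wm <- function(...) stop(..., call. = FALSE)
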