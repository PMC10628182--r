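# Drift-field basis: von Mises derivatives on the circle.

## Concentration for a von Mises bump whose circular SD equals the basis
## spacing: Rbar = exp(-s^2/2), kappa = A1^{-1}(Rbar).
basis_kappa <- function(spacing) {
  bessel_ratio_inv(exp(-spacing^2 / 2))
}

## Unnormalized derivative-of-von-Mises bump centered at 0.
vm_deriv_raw <- function(x, kappa) {
  -kappa * sin(x) * exp(kappa * (cos(x) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

## Peak height of the raw bump, used to normalize each basis column to
## unit maximum amplitude.
vm_deriv_peak <- function(kappa) {
  xs <- seq(0, pi, length.out = 4096)
  max(abs(vm_deriv_raw(xs, kappa)))
}

#' Von Mises-derivative basis for the drift landscape
#'
#' The drift function G over the circular color space is expanded on
#' derivative-of-von-Mises bumps with centers spaced `spacing` apart on
#' `[0, 2*pi)`. The bump concentration is chosen so that the circular
#' standard deviation of the underlying von Mises equals the spacing
#' ("separated by one standard deviation"); the default spacing `2*pi/12`
#' yields 12 basis functions. Each column is normalized to unit maximum
#' amplitude, and, being the derivative of a periodic function, sums to zero
#' over any uniform periodic grid.
#'
#' @param spacing center spacing in radians; must divide `2*pi`.
#' @param grid_size number of evaluation points on `[0, 2*pi)`.
#' @return a `grid_size x n_basis` matrix with attributes `grid` (angles),
#'   `centers`, `kappa` and `spacing`.
#' @export
build_basis <- function(spacing = 2 * pi / 12, grid_size = 128L) {
  n_basis <- 2 * pi / spacing
  if (abs(n_basis - round(n_basis)) > 1e-9)
    stop_wm("basis spacing must divide 2*pi")
  n_basis <- as.integer(round(n_basis))
  kappa <- basis_kappa(spacing)
  peak <- vm_deriv_peak(kappa)
  grid <- seq(0, 2 * pi, length.out = grid_size + 1L)[seq_len(grid_size)]
  centers <- (seq_len(n_basis) - 1L) * spacing
  B <- vapply(centers, function(mu) vm_deriv_raw(grid - mu, kappa) / peak,
              numeric(grid_size))
  structure(B, grid = grid, centers = centers, kappa = kappa,
            spacing = spacing)
}

#' Drift landscape on the circle
#'
#' A drift field is a weighted combination of the von Mises-derivative basis
#' of [build_basis()]. `evaluate_drift()` evaluates it analytically at
#' arbitrary angles (exactly periodic). With `normalize = TRUE` the weights
#' are rescaled so that `max |G| = 1`, the convention used during model
#' fitting so the load-specific gains carry all the magnitude.
#'
#' @param weights numeric vector of basis coefficients (length
#'   `2*pi/spacing`).
#' @param spacing basis spacing in radians.
#' @param normalize logical; rescale to unit maximum amplitude.
#' @return an object of class `drift_field`.
#' @export
drift_field <- function(weights, spacing = 2 * pi / 12, normalize = FALSE) {
  n_basis <- round(2 * pi / spacing)
  if (abs(2 * pi / spacing - n_basis) > 1e-9)
    stop_wm("basis spacing must divide 2*pi")
  if (length(weights) != n_basis)
    stop_wm("expected ", n_basis, " weights, got ", length(weights))
  kappa <- basis_kappa(spacing)
  f <- structure(
    list(weights = as.numeric(weights),
         spacing = spacing,
         centers = (seq_len(n_basis) - 1) * spacing,
         kappa = kappa,
         peak = vm_deriv_peak(kappa)),
    class = "drift_field")
  if (normalize) {
    m <- max(abs(evaluate_drift(f, seq(0, 2 * pi, length.out = 4097))))
    if (m > 0) f$weights <- f$weights / m
  }
  f
}

#' @export
print.drift_field <- function(x, ...) {
  cat("Drift field:", length(x$weights), "von Mises-derivative bumps,",
      "spacing", format(x$spacing, digits = 4), "rad\n")
  invisible(x)
}

#' @param field a [drift_field()].
#' @param theta angles in radians (any finite values).
#' @rdname drift_field
#' @export
evaluate_drift <- function(field, theta) {
  stopifnot(inherits(field, "drift_field"))
  out <- numeric(length(theta))
  for (k in seq_along(field$weights)) {
    w <- field$weights[k]
    if (w != 0)
      out <- out + w * vm_deriv_raw(theta - field$centers[k], field$kappa) /
        field$peak
  }
  out
}

## Fast evaluation via a dense lookup table with linear interpolation;
## used inside the Euler-Maruyama simulator where G is evaluated millions
## of times. Resolution 4096 keeps the interpolation error ~1e-6.
drift_lookup <- function(field, resolution = 4096L) {
  grid <- seq(0, 2 * pi, length.out = resolution + 1L)
  vals <- evaluate_drift(field, grid)
  list(grid = grid, vals = vals, h = 2 * pi / resolution)
}

drift_lookup_eval <- function(lut, theta) {
  x <- wrap_0_2pi(theta) / lut$h
  i <- pmin(floor(x), length(lut$vals) - 2)
  fr <- x - i
  lut$vals[i + 1] * (1 - fr) + lut$vals[i + 2] * fr
}

## Least-squares projection of an arbitrary periodic function onto the
## basis (used to construct generative fields with prescribed shapes).
## The equally spaced bumps nearly sum to zero (their parents tile the
## circle almost uniformly), so the minimum-norm solution via SVD is used.
project_drift <- function(fun, spacing = 2 * pi / 12, grid_size = 1024L) {
  B <- build_basis(spacing, grid_size)
  g <- attr(B, "grid")
  s <- svd(B)
  d_inv <- ifelse(s$d > max(s$d) * 1e-8, 1 / s$d, 0)
  w <- s$v %*% (d_inv * crossprod(s$u, fun(g)))
  drift_field(as.numeric(w), spacing = spacing)
}

#' Attractors and repellers of a drift field
#'
#' Discrete attractors are stable fixed points of the memory dynamics:
#' zero crossings of the effective drift `beta * G` with negative slope
#' (converging flow). Positive-slope crossings are repellers (basin
#' boundaries). Roots are located by a dense sign-change scan followed by
#' linear-interpolation refinement.
#'
#' @param field a [drift_field()].
#' @param beta drift gain; `beta = 0` returns an empty set.
#' @param resolution scan resolution.
#' @return object of class `attractor_set` with `attractors`, `repellers`
#'   (angles in radians, sorted) and `n_attractors`.
#' @export
find_attractors <- function(field, beta = 1, resolution = 4096L) {
  if (beta < 0) stop_wm("beta must be non-negative")
  empty <- structure(list(attractors = numeric(0), repellers = numeric(0),
                          n_attractors = 0L), class = "attractor_set")
  if (beta == 0) return(empty)
  grid <- seq(0, 2 * pi, length.out = resolution + 1L)[seq_len(resolution)]
  g <- beta * evaluate_drift(field, grid)
  g_next <- c(g[-1], g[1])
  grid_next <- c(grid[-1], 2 * pi)
  att <- numeric(0); rep_ <- numeric(0)
  cross <- which(g * g_next < 0 | (g == 0 & g_next != 0))
  for (i in cross) {
    if (g[i] == 0) {
      root <- grid[i]
    } else {
      root <- grid[i] - g[i] * (grid_next[i] - grid[i]) / (g_next[i] - g[i])
    }
    root <- wrap_0_2pi(root)
    if (g_next[i] < g[i]) att <- c(att, root) else rep_ <- c(rep_, root)
  }
  structure(list(attractors = sort(att), repellers = sort(rep_),
                 n_attractors = length(att)),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("Attractor set:", x$n_attractors, "attractor(s)\n")
  if (x$n_attractors)
    cat("  attractors (rad):",
        paste(format(x$attractors, digits = 4), collapse = ", "), "\n")
  if (length(x$repellers))
    cat("  repellers  (rad):",
        paste(format(x$repellers, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
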