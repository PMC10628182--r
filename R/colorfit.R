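# Per-target-color response histograms and four-parameter Gaussian
# characterization of the tuning around each target color.

#' Re-centered per-color response histogram
#'
#' For one target color: within each session, the fraction of responses to
#' each of the wheel's colors (bins sum to 1 per session), averaged across
#' sessions, then circularly shifted so the target sits at the central
#' position (33 for a 64-color wheel).
#'
#' @param trials trial table with responses.
#' @param target_idx the target color (1-based).
#' @param wheel a [color_wheel()].
#' @return numeric vector of length `n_colors` summing to 1, target
#'   centered.
#' @export
per_color_histogram <- function(trials, target_idx, wheel = color_wheel()) {
  n <- wheel$n_colors
  center <- n %/% 2 + 1L
  t2 <- trials[trials$target_idx == target_idx & !is.na(trials$response_idx),
               , drop = FALSE]
  if (!nrow(t2)) stop_wm("no trials with target color ", target_idx)
  per_session <- lapply(split(t2$response_idx, t2$session_id), function(r) {
    tabulate(r, n) / length(r)
  })
  avg <- Reduce(`+`, per_session) / length(per_session)
  # shift so the target lands on `center`
  shift <- (center - target_idx) %% n
  c(utils::tail(avg, shift), utils::head(avg, n - shift))
}

#' Gaussian characterization of a per-color response histogram
#'
#' Fits `y = a * exp(-((x - b)/c)^2) + d` to the 64-bin re-centered
#' histogram by nonlinear least squares, from the starting values
#' `a = 1`, `b = center` (the re-centered target position, 33 for 64
#' colors), `c = 1`, and `d =` the mean response fraction over the 30
#' colors farthest from the target. Amplitude and intercept are constrained
#' non-negative to exclude sign-flipped solutions, the center is kept on
#' the histogram support, and the width is bounded below by half a color
#' step (a peak narrower than one histogram bin, or centered outside the
#' support, is unidentifiable and would otherwise form a degenerate spike
#' ridge). The adjusted
#' R-squared (n bins, 4 parameters) measures goodness of fit.
#'
#' @param histogram vector from [per_color_histogram()].
#' @return object of class `color_tuning_fit`: `a` (amplitude, response
#'   fraction), `b` (center, color-index units), `b_offset_deg` (signed
#'   shift from the target in degrees), `c` (width, index units), `d`
#'   (intercept), `adj_r2`, `converged`.
#' @export
fit_color_tuning <- function(histogram) {
  n <- length(histogram)
  if (n < 16) stop_wm("histogram too short")
  center <- n %/% 2 + 1L
  x <- seq_len(n)
  far <- c(seq_len(floor(15 * n / 64)), seq(ceiling(50 * n / 64), n))
  start <- c(a = 1, b = center, c = 1, d = mean(histogram[far]))
  gauss <- function(p) p[["a"]] * exp(-((x - p[["b"]]) / p[["c"]])^2) +
    p[["d"]]
  fit <- minpack.lm::nls.lm(
    par = start, fn = function(p) histogram - gauss(p),
    lower = c(0, 1, 0.5, 0), upper = c(1.5, n, 2 * n, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- fit$par
  converged <- fit$info %in% 1:4
  pred <- gauss(co)
  ss_res <- sum((histogram - pred)^2)
  ss_tot <- sum((histogram - mean(histogram))^2)
  adj_r2 <- if (ss_tot > 0)
    1 - (ss_res / (n - 4)) / (ss_tot / (n - 1)) else NA_real_
  structure(list(a = unname(co[["a"]]), b = unname(co[["b"]]),
                 b_offset_deg = (unname(co[["b"]]) - center) * 360 / n,
                 c = unname(co[["c"]]), d = unname(co[["d"]]),
                 adj_r2 = adj_r2, converged = converged),
            class = "color_tuning_fit")
}

#' @export
print.color_tuning_fit <- function(x, ...) {
  cat("Gaussian tuning fit: a =", format(x$a, digits = 3),
      "b =", format(x$b, digits = 4),
      "c =", format(x$c, digits = 3), "d =", format(x$d, digits = 3),
      "adj R2 =", format(x$adj_r2, digits = 3),
      if (!x$converged) "[not converged]", "\n")
  invisible(x)
}

#' Gaussian tuning coefficients for every target color
#'
#' Runs [per_color_histogram()] and [fit_color_tuning()] for each color of
#' the wheel.
#'
#' @param trials trial table with responses.
#' @param wheel a [color_wheel()].
#' @return data.frame with one row per color: `color`, `a`, `b`,
#'   `b_offset_deg`, `c`, `d`, `adj_r2`, `converged`.
#' @export
fit_all_colors <- function(trials, wheel = color_wheel()) {
  rows <- lapply(seq_len(wheel$n_colors), function(ci) {
    f <- fit_color_tuning(per_color_histogram(trials, ci, wheel))
    data.frame(color = ci, a = f$a, b = f$b, b_offset_deg = f$b_offset_deg,
               c = f$c, d = f$d, adj_r2 = f$adj_r2, converged = f$converged)
  })
  do.call(rbind, rows)
}
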