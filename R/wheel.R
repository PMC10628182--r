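#' Color-wheel specification
#'
#' The choice stimulus is a wheel of `n_colors` uniformly spaced hues
#' (64 by default). Color indices are 1-based; index 1 sits at angle 0 and
#' consecutive indices advance counterclockwise by `2*pi/n_colors`. On each
#' trial the wheel is shown at a random rotation, recorded per trial in the
#' trial table, so all analyses work in the unrotated color frame.
#'
#' @param n_colors number of hues on the wheel (>= 4).
#' @return an object of class `color_wheel` with fields `n_colors` and
#'   `step` (the angular width of one wedge, radians).
#' @examples
#' w <- color_wheel()
#' index_to_angle(33, w)  # antipode of index 1
#' @export
color_wheel <- function(n_colors = 64L) {
  n_colors <- as.integer(n_colors)
  if (is.na(n_colors) || n_colors < 4L)
    stop_wm("a color wheel needs at least 4 colors")
  structure(list(n_colors = n_colors, step = 2 * pi / n_colors),
            class = "color_wheel")
}

#' @export
print.color_wheel <- function(x, ...) {
  cat("Color wheel:", x$n_colors, "hues,",
      format(x$step, digits = 4), "rad per wedge\n")
  invisible(x)
}

#' Convert color indices to angles and back
#'
#' `index_to_angle()` returns the wedge-center angle `(idx - 1) * 2*pi/n`;
#' `angle_to_index()` assigns an angle to the nearest wedge center, with an
#' angle exactly on a wedge boundary assigned to the lower index
#' (deterministic tie-break). The two functions round-trip exactly for any
#' angle within half a wedge of a center.
#'
#' @param idx integer color index in `1..n_colors` (vectorized).
#' @param theta angle in radians (vectorized; any finite value, wrapped).
#' @param wheel a [color_wheel()].
#' @return angles in `[0, 2*pi)`, or integer indices.
#' @export
index_to_angle <- function(idx, wheel = color_wheel()) {
  idx <- as.integer(idx)
  bad <- !is.na(idx) & (idx < 1L | idx > wheel$n_colors)
  if (any(bad))
    stop_wm("color index out of range 1..", wheel$n_colors, ": ",
            paste(unique(idx[bad]), collapse = ", "))
  (idx - 1L) * wheel$step
}

#' @rdname index_to_angle
#' @export
angle_to_index <- function(theta, wheel = color_wheel()) {
  if (any(!is.finite(theta) & !is.na(theta)))
    stop_wm("angles must be finite")
  u <- wrap_0_2pi(theta) / wheel$step + 0.5
  k <- floor(u)
  # exact boundary -> lower index
  k <- ifelse(!is.na(u) & k == u, k - 1, k)
  as.integer(k %% wheel$n_colors) + 1L
}

#' Signed angular error of a report relative to its target
#'
#' Errors are expressed in `(-pi, pi]`; positive values are counterclockwise
#' displacements of the report relative to the target. The function is
#' antisymmetric, `signed_angular_error(a, b) == -signed_angular_error(b, a)`,
#' except at exactly `pi` where both signs map to `+pi`.
#'
#' @param reported,target angles in radians (vectorized, wrapped internally).
#' @return signed errors in `(-pi, pi]`.
#' @export
signed_angular_error <- function(reported, target) {
  if (any(!is.finite(reported) & !is.na(reported)) ||
      any(!is.finite(target) & !is.na(target)))
    stop_wm("angles must be finite")
  wrap_pi(reported - target)
}

#' Circular index error between reported and target color
#'
#' @param response_idx,target_idx 1-based color indices.
#' @param wheel a [color_wheel()].
#' @return signed integer error in `(-n/2, n/2]` wedges.
#' @export
index_error <- function(response_idx, target_idx, wheel = color_wheel()) {
  n <- wheel$n_colors
  d <- (as.integer(response_idx) - as.integer(target_idx)) %% n
  as.integer(ifelse(!is.na(d) & d > n / 2, d - n, d))
}

#' Graded reward for a response
#'
#' A peck on the exact target color earns 3 pellets, a response within the
#' inner range (+/- 1 color) earns 2, within the full range (+/- 3 colors)
#' 1 pellet, and anything farther earns nothing (error signal / time-out).
#'
#' @param error_in_indices signed wedge error (vectorized),
#'   `|error| <= n_colors/2`.
#' @param wheel a [color_wheel()].
#' @return integer pellet counts in `0..3`.
#' @export
reward_level <- function(error_in_indices, wheel = color_wheel()) {
  e <- abs(as.integer(error_in_indices))
  if (any(!is.na(e) & e > wheel$n_colors / 2))
    stop_wm("|error| exceeds half the wheel; use index_error() first")
  as.integer(ifelse(e == 0L, 3L, ifelse(e == 1L, 2L, ifelse(e <= 3L, 1L, 0L))))
}

#' Chance performance levels of the graded reward scheme
#'
#' Under uniform guessing the probability of landing within the full reward
#' range is 7/n, within the inner range 3/n, and on the exact color 1/n
#' (11%, 5% and 1.6% for the default 64-color wheel).
#'
#' @param wheel a [color_wheel()].
#' @return named numeric vector of proportions `c(full, inner, exact)`.
#' @export
chance_levels <- function(wheel = color_wheel()) {
  c(full = 7 / wheel$n_colors,
    inner = 3 / wheel$n_colors,
    exact = 1 / wheel$n_colors)
}

#' The nine trial types of the task
#'
#' Three load conditions (load 1; load 2 with a simultaneous cue; load 2 with
#' a retro cue) crossed with three delay classes ('simultaneous' 0.45 s,
#' short 1.2 s, long 3.2 s).
#'
#' @param delay_map named numeric vector mapping delay class to seconds.
#' @return data.frame with columns `type`, `load`, `cue`, `delay_class`,
#'   `delay_s` (9 rows).
#' @export
trial_types <- function(delay_map = c(simultaneous = 0.45, short = 1.2,
                                      long = 3.2)) {
  stopifnot(all(c("simultaneous", "short", "long") %in% names(delay_map)))
  g <- expand.grid(
    delay_class = c("simultaneous", "short", "long"),
    load_cue = c("1.none", "2.simultaneous", "2.retro"),
    stringsAsFactors = FALSE
  )
  load <- as.integer(substr(g$load_cue, 1, 1))
  cue <- sub("^[12]\\.", "", g$load_cue)
  data.frame(
    type = seq_len(nrow(g)),
    load = load,
    cue = cue,
    delay_class = g$delay_class,
    delay_s = unname(delay_map[g$delay_class]),
    stringsAsFactors = FALSE
  )
}
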