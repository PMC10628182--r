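# Model-free behavioral measures.

load_condition_levels <- function() c("load1", "load2_sim", "load2_retro")

load_condition <- function(trials) {
  ifelse(trials$load == 1L, "load1",
         ifelse(trials$cue == "simultaneous", "load2_sim", "load2_retro"))
}

#' Performance matrices by load condition and delay
#'
#' Proportion of trials whose absolute wedge error falls within each
#' accuracy level: full reward range (+/- 3 colors), inner range (+/- 1),
#' exact target. Cells are the 3 load conditions (load 1, load 2 with
#' simultaneous cue, load 2 with retro cue) crossed with the 3 delay
#' classes. Also returns the "diagonal" of increasing memory demand:
#' load 1 / simultaneous delay, load 2 simultaneous cue / short delay,
#' load 2 retro cue / long delay. Cells with no trials are `NA` (missing,
#' not zero).
#'
#' @param trials trial table with responses.
#' @param wheel a [color_wheel()].
#' @return object of class `performance_matrix`: a list with 3x3 proportion
#'   matrices per level (`full`, `inner`, `exact`), trial `counts`, and a
#'   `diagonal` data.frame.
#' @export
performance_by_condition <- function(trials, wheel = color_wheel()) {
  trials <- trial_errors(trials, wheel)
  lc <- factor(load_condition(trials), levels = load_condition_levels())
  dc <- factor(trials$delay_class,
               levels = c("simultaneous", "short", "long"))
  counts <- table(lc, dc)
  abs_err <- abs(trials$error_idx)
  prop <- function(window) {
    hits <- tapply(abs_err <= window, list(lc, dc), mean)
    hits
  }
  mats <- list(full = prop(3L), inner = prop(1L), exact = prop(0L))
  diag_cells <- data.frame(
    load_condition = load_condition_levels(),
    delay_class = c("simultaneous", "short", "long"),
    stringsAsFactors = FALSE)
  diag_cells$full <- mapply(function(l, d) mats$full[l, d],
                            diag_cells$load_condition, diag_cells$delay_class)
  diag_cells$inner <- mapply(function(l, d) mats$inner[l, d],
                             diag_cells$load_condition, diag_cells$delay_class)
  diag_cells$exact <- mapply(function(l, d) mats$exact[l, d],
                             diag_cells$load_condition, diag_cells$delay_class)
  structure(c(mats, list(counts = counts, diagonal = diag_cells)),
            class = "performance_matrix")
}

#' @export
print.performance_matrix <- function(x, ...) {
  for (lv in c("full", "inner", "exact")) {
    cat(lv, "reward range:\n")
    print(round(x[[lv]], 3))
  }
  invisible(x)
}

#' Per-session performance table for factorial analysis
#'
#' One row per session x load condition x delay class, with the proportion
#' of responses within the requested accuracy window — the replication unit
#' for [variance_partitioning()].
#'
#' @param trials trial table with responses.
#' @param level `"full"` (+/-3), `"inner"` (+/-1) or `"exact"`.
#' @param wheel a [color_wheel()].
#' @return data.frame with columns `session_id`, `load`, `delay`, `value`.
#' @export
session_performance <- function(trials, level = "full",
                                wheel = color_wheel()) {
  window <- c(full = 3L, inner = 1L, exact = 0L)[[level]]
  trials <- trial_errors(trials, wheel)
  hit <- abs(trials$error_idx) <= window
  agg <- stats::aggregate(
    hit, by = list(session_id = trials$session_id,
                   load = load_condition(trials),
                   delay = trials$delay_class), FUN = mean)
  names(agg)[4] <- "value"
  agg
}

#' Circular bias and chance-corrected precision of response errors
#'
#' Bias is the absolute circular mean of the signed errors; precision is the
#' reciprocal of the circular standard deviation `sqrt(-2 log Rbar)`,
#' corrected for chance by subtracting the Monte-Carlo expectation of the
#' same statistic for uniform samples of matched size (fixed internal seed),
#' so that uniform guessing scores ~0. With a grouping vector (one entry
#' per error, typically the target color) both measures are computed per
#' group and then averaged across groups.
#'
#' @param errors signed angular errors in radians.
#' @param group optional grouping vector (default: pooled).
#' @param n_mc Monte-Carlo replicates for the chance correction.
#' @param mc_seed internal seed of the correction.
#' @param precision_cap reported precision for degenerate (all-identical)
#'   samples, where the circular SD is 0.
#' @return list with `bias`, `precision`, `per_group` (data.frame), and
#'   `degenerate` flag.
#' @export
bias_and_precision <- function(errors, group = NULL, n_mc = 200L,
                               mc_seed = 20260914L, precision_cap = 1e3) {
  if (length(errors) < 2) stop_wm("need at least 2 errors")
  if (is.null(group)) group <- rep(1L, length(errors))
  groups <- split(errors, group)
  chance_cache <- new.env(parent = emptyenv())
  chance_inv_sd <- function(n) {
    key <- as.character(n)
    hit <- chance_cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- with_seed(mc_seed, {
      mean(replicate(n_mc, {
        sd0 <- circ_sd(stats::runif(n, 0, 2 * pi))
        min(1 / sd0, precision_cap)
      }))
    })
    chance_cache[[key]] <- val
    val
  }
  rows <- lapply(names(groups), function(g) {
    e <- groups[[g]]
    r <- circ_resultant(e)
    degenerate <- r > 1 - 1e-12
    raw <- if (degenerate) precision_cap else min(1 / circ_sd(e), precision_cap)
    data.frame(group = g, n = length(e), bias = abs(circ_mean(e)),
               precision = raw - chance_inv_sd(length(e)),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, rows)
  list(bias = mean(per_group$bias), precision = mean(per_group$precision),
       per_group = per_group, degenerate = any(per_group$degenerate))
}

#' Normalized response frequency per color
#'
#' For each color, the number of times it was reported divided by the number
#' of times it served as target; values > 1 mark colors reported more often
#' than their incidence (candidate attractor colors), values < 1 less often.
#' The target-count-weighted sum of ratios equals the total response count
#' (mass conservation).
#'
#' @param trials trial table with responses.
#' @param wheel a [color_wheel()].
#' @return data.frame with columns `color`, `n_target`, `n_response`,
#'   `ratio`.
#' @export
normalized_response_frequency <- function(trials, wheel = color_wheel()) {
  n <- wheel$n_colors
  n_target <- tabulate(trials$target_idx, n)
  n_response <- tabulate(trials$response_idx, n)
  if (any(n_target == 0))
    stop_wm("color(s) never used as target: ",
            paste(which(n_target == 0), collapse = ", "))
  data.frame(color = seq_len(n), n_target = n_target,
             n_response = n_response, ratio = n_response / n_target)
}

#' Serial-dependence curve: response bias vs. previous-target offset
#'
#' The signed response error is related to the circular difference between
#' the previous and the current target color (`delta`, radians, positive
#' when the previous target lies counterclockwise). The mean error is
#' smoothed over a grid of `delta` with a von Mises kernel; an attraction
#' toward the previous target shows as a positive peak at positive `delta`.
#' The reported peak is taken from the antisymmetrized (odd) curve, which
#' removes any delta-independent bias component.
#'
#' @param trials trial table with responses and `prev_target_idx` (first
#'   trial of each session excluded automatically).
#' @param kernel_kappa von Mises smoothing concentration; the default 12
#'   gives a half-width of roughly 20 degrees.
#' @param grid_n number of grid points over `(-pi, pi]`.
#' @param min_trials minimum number of usable trials.
#' @param wheel a [color_wheel()].
#' @return object of class `serial_bias_curve`: data.frame `curve`
#'   (`delta`, `mean_error`, `odd_error`), `peak_magnitude` (radians),
#'   `peak_location_deg`, and `n`.
#' @export
serial_dependence_curve <- function(trials, kernel_kappa = 12,
                                    grid_n = 180L, min_trials = 50L,
                                    wheel = color_wheel()) {
  use <- !is.na(trials$prev_target_idx) & !is.na(trials$response_angle)
  if (sum(use) < min_trials)
    stop_wm("only ", sum(use), " usable trials (< ", min_trials, ")")
  t2 <- trial_errors(trials[use, , drop = FALSE], wheel)
  delta <- signed_angular_error(index_to_angle(t2$prev_target_idx, wheel),
                                index_to_angle(t2$target_idx, wheel))
  err <- t2$error_rad
  grid <- seq(-pi, pi, length.out = grid_n + 1L)[-1L]
  sm <- vapply(grid, function(d) {
    w <- exp(kernel_kappa * (cos(delta - d) - 1))
    sum(w * err) / sum(w)
  }, numeric(1))
  # odd (antisymmetric) component: flip the grid
  sm_neg <- vapply(grid, function(d) {
    w <- exp(kernel_kappa * (cos(delta + d) - 1))
    sum(w * err) / sum(w)
  }, numeric(1))
  odd <- (sm - sm_neg) / 2
  pos <- grid > 0
  i_pk <- which(pos)[which.max(abs(odd[pos]))]
  structure(list(
    curve = data.frame(delta = grid, mean_error = sm, odd_error = odd),
    peak_magnitude = odd[i_pk],
    peak_location_deg = grid[i_pk] * 180 / pi,
    n = sum(use), kernel_kappa = kernel_kappa),
    class = "serial_bias_curve")
}

#' @export
print.serial_bias_curve <- function(x, ...) {
  cat("Serial-dependence curve (n =", x$n, "):\n")
  cat("  peak", format(x$peak_magnitude, digits = 3), "rad (",
      format(x$peak_magnitude * 180 / pi, digits = 3), "deg ) at delta =",
      format(x$peak_location_deg, digits = 3), "deg\n")
  invisible(x)
}
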