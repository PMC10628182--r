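# Trial-table input/output and validation.

trial_columns <- function() {
  c("bird_id", "session_id", "trial_index", "load", "cue", "delay_class",
    "delay_s", "target_idx", "nontarget_idx", "wheel_rotation",
    "response_angle", "response_idx", "prev_target_idx", "reward_pellets")
}

default_delay_map <- function() c(simultaneous = 0.45, short = 1.2, long = 3.2)

#' Validate a trial table
#'
#' Enforces the per-trial invariants: loads in {1, 2}; load-1 trials have no
#' non-target and no cue; load-2 trials carry a simultaneous or retro cue and
#' a non-target index; `delay_class` maps to the configured delay in seconds
#' (`delay_s` is filled in when absent); color indices lie in
#' `1..n_colors`; when responses are present, `response_idx` equals the
#' nearest wheel wedge to `response_angle` after removing `wheel_rotation`.
#'
#' @param trials data.frame of trials (see [read_trials()] for columns).
#' @param wheel a [color_wheel()].
#' @param delay_map named map from delay class to seconds.
#' @return the validated (possibly completed) data.frame, invisibly classed.
#'   Violations abort with row-level diagnostics.
#' @export
validate_trials <- function(trials, wheel = color_wheel(),
                            delay_map = default_delay_map()) {
  if (!is.data.frame(trials)) stop_wm("trials must be a data.frame")
  mandatory <- c("load", "cue", "delay_class", "target_idx", "wheel_rotation")
  missing_cols <- setdiff(mandatory, names(trials))
  if (length(missing_cols))
    stop_wm("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(trial_columns(), names(trials))) trials[[col]] <- NA
  n <- nrow(trials)
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop_wm("invalid trial table: ", what, " (rows ",
              paste(utils::head(rows, 10), collapse = ", "),
              if (length(rows) > 10) ", ..." else "", ")")
  }
  bad(!trials$load %in% c(1L, 2L), "load must be 1 or 2")
  bad(!trials$cue %in% c("none", "simultaneous", "retro"), "unknown cue")
  bad(trials$load == 1L & trials$cue != "none",
      "load-1 trials must have cue = none")
  bad(trials$load == 2L & !trials$cue %in% c("simultaneous", "retro"),
      "load-2 trials need a simultaneous or retro cue")
  bad(trials$load == 1L & !is.na(trials$nontarget_idx),
      "load-1 trials must not carry a non-target")
  bad(trials$load == 2L & is.na(trials$nontarget_idx),
      "load-2 trials need a non-target index")
  bad(!trials$delay_class %in% names(delay_map), "unknown delay_class")
  expected_delay <- unname(delay_map[trials$delay_class])
  if (all(is.na(trials$delay_s))) {
    trials$delay_s <- expected_delay
  } else {
    bad(!is.na(trials$delay_s) & abs(trials$delay_s - expected_delay) > 1e-9,
        "delay_s inconsistent with delay_class")
    trials$delay_s[is.na(trials$delay_s)] <-
      expected_delay[is.na(trials$delay_s)]
  }
  idx_ok <- function(x) is.na(x) | (x >= 1 & x <= wheel$n_colors & x == round(x))
  bad(!idx_ok(trials$target_idx), "target_idx out of range")
  bad(!idx_ok(trials$nontarget_idx), "nontarget_idx out of range")
  bad(!idx_ok(trials$prev_target_idx), "prev_target_idx out of range")
  bad(!is.na(trials$wheel_rotation) & !is.finite(trials$wheel_rotation),
      "wheel_rotation must be finite")
  has_resp <- !is.na(trials$response_angle)
  if (any(has_resp)) {
    bad(has_resp & (trials$response_angle < 0 |
                      trials$response_angle >= 2 * pi),
        "response_angle must lie in [0, 2*pi)")
    derived <- rep(NA_integer_, n)
    derived[has_resp] <- angle_to_index(
      trials$response_angle[has_resp] - trials$wheel_rotation[has_resp], wheel)
    if (all(is.na(trials$response_idx))) {
      trials$response_idx <- derived
    } else {
      bad(has_resp & !is.na(trials$response_idx) &
            trials$response_idx != derived,
          "response_idx does not match response_angle minus wheel_rotation")
    }
  }
  trials
}

#' Read and write trial tables
#'
#' Trial tables are UTF-8 tab-separated files with a header row, one row per
#' completed trial. Mandatory columns: `load`, `cue`, `delay_class`,
#' `target_idx`, `wheel_rotation`; the full column set also includes
#' `bird_id`, `session_id`, `trial_index`, `delay_s`, `nontarget_idx`,
#' `response_angle`, `response_idx`, `prev_target_idx`, `reward_pellets`.
#' Unknown columns are preserved. Angles are radians. All invariants of
#' [validate_trials()] are enforced on load, with row numbers reported on
#' violation; `write_trials()` then `read_trials()` round-trips losslessly.
#'
#' @param path file path.
#' @param wheel a [color_wheel()].
#' @param delay_map named map from delay class to seconds.
#' @param trials a trial data.frame.
#' @return `read_trials()` returns the validated data.frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path, wheel = color_wheel(),
                        delay_map = default_delay_map()) {
  if (!file.exists(path)) stop_wm("no such trial table: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_trials(df, wheel = wheel, delay_map = delay_map)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Derived error columns for a trial table
#'
#' Adds the color-frame response angle (`response_color_angle`, rotation
#' removed), the signed angular error relative to the target
#' (`error_rad`, counterclockwise positive), the signed wedge error
#' (`error_idx`), and, for load-2 trials, the signed error relative to the
#' non-target (`nontarget_error_rad`).
#'
#' @param trials a validated trial table with responses.
#' @param wheel a [color_wheel()].
#' @return the table with the derived columns appended.
#' @export
trial_errors <- function(trials, wheel = color_wheel()) {
  if (any(is.na(trials$response_angle)))
    stop_wm("trial table has trials without responses")
  col_angle <- wrap_0_2pi(trials$response_angle - trials$wheel_rotation)
  target_angle <- index_to_angle(trials$target_idx, wheel)
  trials$response_color_angle <- col_angle
  trials$error_rad <- signed_angular_error(col_angle, target_angle)
  trials$error_idx <- index_error(trials$response_idx, trials$target_idx, wheel)
  nt <- rep(NA_real_, nrow(trials))
  has_nt <- !is.na(trials$nontarget_idx)
  if (any(has_nt))
    nt[has_nt] <- signed_angular_error(
      col_angle[has_nt], index_to_angle(trials$nontarget_idx[has_nt], wheel))
  trials$nontarget_error_rad <- nt
  trials
}
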