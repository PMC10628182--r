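# Pipeline orchestration: simulate -> analyze -> fit -> compare -> report
# from a single config, with explicit seeds and file-based stage outputs.

#' Demonstration drift field with a prescribed number of attractors
#'
#' Least-squares projection of `-sin(k * theta)` onto the von Mises
#' derivative basis, normalized to `max |G| = 1`: a drift landscape with
#' `k` evenly spaced attractors (and `k` repellers between them). Used as
#' ground truth by the synthetic test bed.
#'
#' @param n_attractors number of attractors (must be below the basis
#'   resolution; the default basis supports up to 6).
#' @param spacing basis spacing.
#' @return a [drift_field()].
#' @export
demo_drift_field <- function(n_attractors = 6L, spacing = 2 * pi / 12) {
  f <- project_drift(function(th) -sin(n_attractors * th), spacing = spacing)
  drift_field(f$weights, spacing = spacing, normalize = TRUE)
}

#' Resolve a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Top-level fields: exactly one
#' of `input` (trial TSV path) or `generator` (a block with `n_trials`,
#' `seed`, `n_sessions`, `serial_bias_gain`, `trial_type_weights`, and a
#' `model` block with `drift_weights` or `n_attractors`, `beta_encode`,
#' `sigma_encode`, `beta_memory`, `sigma_memory`, `p_swap`, `p_guess`);
#' `wheel` (`n_colors`); `stages` (subset of `behavior`, `mixture`,
#' `colorfit`, `ddm`); `ddm` settings (`grid_size`, `folds`, `restarts`,
#' `subsample`, `maxit`, `variants`); and a global `seed` from which all
#' unset stage seeds are derived as named substreams.
#'
#' @param config list or YAML path.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_wm("config must be a list or a YAML path")
  has_input <- !is.null(config$input)
  has_gen <- !is.null(config$generator)
  if (has_input == has_gen)
    stop_wm("config needs exactly one of 'input' or 'generator'")
  config$seed <- as.integer(config$seed %||% 1L)
  config$wheel <- config$wheel %||% list()
  config$wheel$n_colors <- as.integer(config$wheel$n_colors %||% 64L)
  config$stages <- config$stages %||% c("behavior")
  bad <- setdiff(config$stages, c("behavior", "mixture", "colorfit", "ddm"))
  if (length(bad)) stop_wm("unknown stage(s): ", paste(bad, collapse = ", "))
  if (has_gen) {
    g <- config$generator
    g$seed <- as.integer(g$seed %||% substream_seed(config$seed, "generator"))
    g$n_trials <- as.integer(g$n_trials %||% 1000L)
    g$n_sessions <- as.integer(g$n_sessions %||% 1L)
    g$serial_bias_gain <- g$serial_bias_gain %||% 0
    g$trial_type_weights <- unlist(g$trial_type_weights %||% rep(1, 9))
    config$generator <- g
  }
  d <- config$ddm %||% list()
  d$grid_size <- as.integer(d$grid_size %||% 128L)
  d$folds <- as.integer(d$folds %||% 4L)
  d$restarts <- as.integer(d$restarts %||% 5L)
  d$subsample <- as.integer(d$subsample %||% 3000L)
  d$maxit <- as.integer(d$maxit %||% 150L)
  d$variants <- unlist(d$variants %||% c("full", "no_memory_drift"))
  d$seed <- as.integer(d$seed %||% substream_seed(config$seed, "ddm"))
  config$ddm <- d
  structure(config, class = c("pipeline_config", "list"))
}

pipeline_model <- function(block, spacing = 2 * pi / 12) {
  drift <- if (!is.null(block$drift_weights)) {
    drift_field(unlist(block$drift_weights), spacing = spacing)
  } else {
    demo_drift_field(as.integer(block$n_attractors %||% 6L), spacing)
  }
  generative_model(
    drift,
    beta_encode = unlist(block$beta_encode %||% c(0, 0)),
    sigma_encode = unlist(block$sigma_encode %||% c(0.15, 0.25)),
    beta_memory = unlist(block$beta_memory %||% c(0, 0)),
    sigma_memory = unlist(block$sigma_memory %||% c(0.25, 0.35)),
    p_swap = block$p_swap %||% 0,
    p_guess = unlist(block$p_guess %||% c(0, 0)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order: obtain trials
#' (generate from the generator block, or read the input TSV), then the
#' requested analyses (behavioral statistics, mixture model, per-color
#' tuning fits, drift-diffusion fitting and cross-validation). Every stage
#' writes tidy TSV/JSON files into `output_dir`, and a `manifest.json`
#' records the resolved config, all seeds, stage status and the config
#' hash, so an identical config reproduces identical outputs. A failing
#' stage aborts downstream stages; partial outputs are kept and the
#' manifest records the failure.
#'
#' @param config a [pipeline_config()] (or list/YAML path coercible to one).
#' @param output_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir) {
  config <- pipeline_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wheel <- color_wheel(config$wheel$n_colors)
  cfg_path <- file.path(output_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed, stages = list())
  results <- list()
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop_wm("stage '", stage, "' failed: ", conditionMessage(e))
  }
  # --- trials ---
  trials <- tryCatch({
    if (!is.null(config$input)) {
      read_trials(config$input, wheel)
    } else {
      g <- config$generator
      sc <- session_config(g$n_trials, g$trial_type_weights,
                           config$wheel$n_colors, g$seed,
                           g$serial_bias_gain, g$n_sessions)
      tr <- generate_sessions(sc)
      model <- pipeline_model(g$model %||% list())
      generate_responses(tr, model,
                         seed = substream_seed(g$seed, "responses"),
                         serial_bias_gain = g$serial_bias_gain,
                         wheel = wheel)
    }
  }, error = function(e) fail("trials", e))
  write_trials(trials, file.path(output_dir, "trials.tsv"))
  manifest$stages$trials <- list(status = "ok", n_trials = nrow(trials))
  results$trials <- trials
  # --- behavior ---
  if ("behavior" %in% config$stages) {
    res <- tryCatch({
      perf <- performance_by_condition(trials, wheel)
      freq <- normalized_response_frequency(trials, wheel)
      te <- trial_errors(trials, wheel)
      bp <- bias_and_precision(te$error_rad, group = te$target_idx)
      write_tsv(perf$diagonal, file.path(output_dir, "performance_diagonal.tsv"))
      write_tsv(freq, file.path(output_dir, "response_frequency.tsv"))
      write_tsv(bp$per_group, file.path(output_dir, "bias_precision.tsv"))
      sb <- tryCatch(serial_dependence_curve(trials, wheel = wheel),
                     error = function(e) NULL)
      if (!is.null(sb))
        write_tsv(sb$curve, file.path(output_dir, "serial_bias_curve.tsv"))
      list(performance = perf, frequency = freq, bias_precision = bp,
           serial = sb)
    }, error = function(e) fail("behavior", e))
    manifest$stages$behavior <- list(status = "ok")
    results$behavior <- res
  }
  # --- mixture ---
  if ("mixture" %in% config$stages) {
    res <- tryCatch({
      te <- trial_errors(trials, wheel)
      diag_sets <- list(
        load1_sim = te[te$load == 1 & te$delay_class == "simultaneous", ],
        load2sim_short = te[te$cue == "simultaneous" &
                              te$delay_class == "short", ],
        load2retro_long = te[te$cue == "retro" & te$delay_class == "long", ])
      fits <- lapply(diag_sets, function(d) {
        if (nrow(d) < 10) return(NULL)
        f <- fit_mixture(d$error_rad, d$nontarget_error_rad,
                         seed = substream_seed(config$seed, "mixture"))
        list(kappa = f$kappa, p_t = f$p_t, p_n = f$p_n, p_u = f$p_u,
             loglik = f$loglik, n = f$n, converged = f$converged)
      })
      jsonlite::write_json(fits, file.path(output_dir, "mixture_fits.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      fits
    }, error = function(e) fail("mixture", e))
    manifest$stages$mixture <- list(status = "ok")
    results$mixture <- res
  }
  # --- colorfit ---
  if ("colorfit" %in% config$stages) {
    res <- tryCatch({
      cf <- fit_all_colors(trials, wheel)
      write_tsv(cf, file.path(output_dir, "color_tuning.tsv"))
      cf
    }, error = function(e) fail("colorfit", e))
    manifest$stages$colorfit <- list(status = "ok")
    results$colorfit <- res
  }
  # --- ddm ---
  if ("ddm" %in% config$stages) {
    res <- tryCatch({
      d <- config$ddm
      cfg <- ddm_config(d$grid_size, d$subsample, d$restarts, d$maxit, d$seed)
      fit <- fit_model(trials, "full", cfg, wheel)
      att <- find_attractors(fit$params$drift, max(fit$params$beta_memory))
      grid <- seq(0, 2 * pi, length.out = 257)[1:256]
      write_tsv(data.frame(angle = grid,
                           drift = max(fit$params$beta_memory) *
                             evaluate_drift(fit$params$drift, grid)),
                file.path(output_dir, "drift_curve.tsv"))
      if (att$n_attractors)
        write_tsv(data.frame(angle = att$attractors,
                             color = angle_to_index(att$attractors, wheel)),
                  file.path(output_dir, "attractors.tsv"))
      cv <- cross_validate(trials, d$variants, d$folds, cfg, wheel)
      cv_df <- data.frame(fold = rep(seq_len(nrow(cv$nll)), ncol(cv$nll)),
                          variant = rep(colnames(cv$nll),
                                        each = nrow(cv$nll)),
                          held_out_nll = as.vector(cv$nll),
                          relative_nll = as.vector(cv$relative_nll))
      write_tsv(cv_df, file.path(output_dir, "model_comparison.tsv"))
      jsonlite::write_json(
        list(variant = fit$variant, nll = fit$nll,
             converged = fit$converged, seed = fit$seed,
             beta_encode = fit$params$beta_encode,
             beta_memory = fit$params$beta_memory,
             sigma_encode = fit$params$sigma_encode,
             sigma_memory = fit$params$sigma_memory,
             p_swap = fit$params$p_swap, p_guess = fit$params$p_guess,
             drift_weights = fit$params$drift$weights,
             attractors = att$attractors),
        file.path(output_dir, "ddm_fit.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      list(fit = fit, attractors = att, comparison = cv)
    }, error = function(e) fail("ddm", e))
    manifest$stages$ddm <- list(status = "ok")
    results$ddm <- res
  }
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Generate the bundled demonstration datasets
#'
#' Three small synthetic datasets with documented generating parameters:
#' `attractor6` (6-attractor drift acting during encoding and memory),
#' `purediffusion` (no drift), and `swapheavy` (strong swap rate). Each is
#' written as a trial TSV next to a JSON manifest of the generating
#' parameters; regeneration from the same seed is byte-identical.
#'
#' @param seed master seed.
#' @param dir output directory.
#' @param n_trials trials per dataset.
#' @return invisibly, the manifest list.
#' @export
make_fixtures <- function(seed = 1L, dir, n_trials = 4500L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    attractor6 = list(n_attractors = 6, beta_encode = c(0.15, 0.15),
                      sigma_encode = c(0.15, 0.25),
                      beta_memory = c(0.15, 0.15),
                      sigma_memory = c(0.25, 0.35),
                      p_swap = 0.15, p_guess = c(0.03, 0.08)),
    purediffusion = list(n_attractors = 6, beta_encode = c(0, 0),
                         sigma_encode = c(0.15, 0.25),
                         beta_memory = c(0, 0),
                         sigma_memory = c(0.25, 0.35),
                         p_swap = 0.15, p_guess = c(0.03, 0.08)),
    swapheavy = list(n_attractors = 6, beta_encode = c(0.15, 0.15),
                     sigma_encode = c(0.1, 0.15),
                     beta_memory = c(0.15, 0.15),
                     sigma_memory = c(0.15, 0.2),
                     p_swap = 0.35, p_guess = c(0.02, 0.02)))
  manifest <- list(seed = seed, n_trials = n_trials, datasets = specs)
  for (nm in names(specs)) {
    s <- specs[[nm]]
    model <- generative_model(demo_drift_field(s$n_attractors),
                              s$beta_encode, s$sigma_encode, s$beta_memory,
                              s$sigma_memory, s$p_swap, s$p_guess)
    sc <- session_config(n_trials, seed = substream_seed(seed, nm),
                         n_sessions = 4L)
    tr <- generate_responses(generate_sessions(sc), model,
                             seed = substream_seed(seed, paste0(nm, "_r")))
    write_trials(tr, file.path(dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(manifest, file.path(dir, "fixtures_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
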