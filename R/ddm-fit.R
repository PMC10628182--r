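# Maximum-likelihood fitting of the attractor drift-diffusion model and
# cross-validated comparison of its variants.

#' Drift-diffusion model parameters
#'
#' Bundles the shared drift landscape with phase- (encoding vs. memory) and
#' load-specific gains and noise, plus swap and guess weights. Gains are
#' non-negative; any sign structure lives in the drift weights. By
#' convention a fitted drift is normalized to `max |G| = 1` so the gains
#' carry all the magnitude.
#'
#' @param drift a [drift_field()].
#' @param beta_encode,beta_memory length-2 gains (per load).
#' @param sigma_encode,sigma_memory length-2 noise levels (per load).
#' @param p_swap swap probability (load 2).
#' @param p_guess length-2 guess probability (per load).
#' @param encode_duration_s encoding duration, 1 s by default.
#' @return object of class `ddm_params`.
#' @export
ddm_params <- function(drift, beta_encode, sigma_encode, beta_memory,
                       sigma_memory, p_swap = 0, p_guess = c(0, 0),
                       encode_duration_s = 1) {
  stopifnot(inherits(drift, "drift_field"))
  rep2 <- function(x) if (length(x) == 1) rep(x, 2) else x
  out <- structure(list(drift = drift, beta_encode = rep2(beta_encode),
                        sigma_encode = rep2(sigma_encode),
                        beta_memory = rep2(beta_memory),
                        sigma_memory = rep2(sigma_memory),
                        p_swap = p_swap, p_guess = rep2(p_guess),
                        encode_duration_s = encode_duration_s),
                   class = "ddm_params")
  if (any(c(out$sigma_encode, out$sigma_memory) < 0))
    stop_wm("sigma must be >= 0")
  if (any(c(out$beta_encode, out$beta_memory) < 0))
    stop_wm("beta must be >= 0")
  if (p_swap < 0 || any(out$p_guess < 0) ||
      any(p_swap + out$p_guess > 1))
    stop_wm("invalid mixture weights")
  out
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Drift-diffusion parameters (loads 1, 2):\n")
  cat("  beta  encode:", format(x$beta_encode, digits = 4),
      " memory:", format(x$beta_memory, digits = 4), "\n")
  cat("  sigma encode:", format(x$sigma_encode, digits = 4),
      " memory:", format(x$sigma_memory, digits = 4), "\n")
  cat("  p_swap:", format(x$p_swap, digits = 4),
      " p_guess:", format(x$p_guess, digits = 4), "\n")
  invisible(x)
}

#' Restrict a trial table to the conditions the model is fitted on
#'
#' Load-1 and load-2 retro-cue trials at the two true memory delays.
#' Simultaneous-cue trials are excluded because their load is ambiguous;
#' 'simultaneous'-delay (0.45 s) trials are excluded by default but can be
#' kept (then modeled with their nominal 0.45-s delay).
#'
#' @param trials trial table with responses.
#' @param include_simultaneous_delay keep 0.45-s trials?
#' @return the filtered table.
#' @export
modeled_trials <- function(trials, include_simultaneous_delay = FALSE) {
  keep <- trials$cue %in% c("none", "retro")
  if (!include_simultaneous_delay)
    keep <- keep & trials$delay_class != "simultaneous"
  trials[keep, , drop = FALSE]
}

## Preprocess trials into per-(load, delay) groups of grid bins and
## response angles for fast likelihood evaluation.
nll_prepare <- function(trials, grid_size, wheel = color_wheel()) {
  if (any(is.na(trials$response_angle)))
    stop_wm("trials must carry responses")
  h <- 2 * pi / grid_size
  resp <- wrap_0_2pi(trials$response_angle - trials$wheel_rotation)
  tbin <- (round(index_to_angle(trials$target_idx, wheel) / h) %% grid_size) + 1
  nbin <- rep(NA_integer_, nrow(trials))
  has_nt <- !is.na(trials$nontarget_idx)
  nbin[has_nt] <- (round(index_to_angle(trials$nontarget_idx[has_nt], wheel) /
                           h) %% grid_size) + 1
  key <- paste(trials$load, trials$delay_s)
  groups <- lapply(split(seq_len(nrow(trials)), key), function(i) {
    x <- resp[i] / h
    i0 <- floor(x)
    list(load = trials$load[i[1]], delay_s = trials$delay_s[i[1]],
         n = length(i),
         row_lo = (i0 %% grid_size) + 1, row_hi = ((i0 + 1) %% grid_size) + 1,
         frac = x - i0, tbin = tbin[i], nbin = nbin[i])
  })
  list(groups = groups, grid_size = grid_size, h = h,
       n = nrow(trials), loads = sort(unique(trials$load)))
}

## Likelihood engine with a kernel cache: the propagation kernel of each
## (phase, load, delay) depends only on its own (beta, sigma) and the shared
## drift weights, so finite-difference perturbations of the remaining
## parameters reuse cached kernels.
nll_engine <- function(prep) {
  cache <- new.env(parent = emptyenv())
  kernel <- function(field, beta, sigma, duration) {
    key <- paste(format(c(beta, sigma, duration, field$weights), digits = 15),
                 collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    if (length(ls(cache)) > 256) rm(list = ls(cache), envir = cache)
    M <- propagate_kernel(field, beta, sigma, duration, prep$grid_size)
    cache[[key]] <- M
    M
  }
  function(params) {
    total <- 0
    for (g in prep$groups) {
      ld <- g$load
      K <- kernel(params$drift, params$beta_memory[ld],
                  params$sigma_memory[ld], g$delay_s) %*%
        kernel(params$drift, params$beta_encode[ld],
               params$sigma_encode[ld], params$encode_duration_s)
      ft <- (K[cbind(g$row_lo, g$tbin)] * (1 - g$frac) +
               K[cbind(g$row_hi, g$tbin)] * g$frac) / prep$h
      p_guess <- params$p_guess[ld]
      p_swap <- if (ld == 2) params$p_swap else 0
      dens <- (1 - p_swap - p_guess) * ft + p_guess / (2 * pi)
      if (ld == 2 && p_swap > 0) {
        fn <- (K[cbind(g$row_lo, g$nbin)] * (1 - g$frac) +
                 K[cbind(g$row_hi, g$nbin)] * g$frac) / prep$h
        dens <- dens + p_swap * fn
      }
      total <- total - sum(log(pmax(dens, 1e-12)))
    }
    total
  }
}

#' Joint negative log-likelihood of the drift-diffusion model
#'
#' Sums `-log p(response | trial)` over trials, with the predicted response
#' density of each (load, delay, target) obtained by Fokker-Planck
#' propagation and evaluated at the response angle by periodic linear
#' interpolation. One propagation kernel is computed per (phase, load,
#' delay) and shared by all trials and target colors of that condition.
#' Zero-density responses are floored at 1e-12.
#'
#' @param params a [ddm_params()].
#' @param trials modeled trials (see [modeled_trials()]).
#' @param grid_size Fokker-Planck grid resolution.
#' @param wheel a [color_wheel()].
#' @return scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, trials, grid_size = 128L,
                                    wheel = color_wheel()) {
  stopifnot(inherits(params, "ddm_params"))
  prep <- nll_prepare(trials, grid_size, wheel)
  nll_engine(prep)(params)
}

#' Fitting configuration for the drift-diffusion model
#'
#' @param grid_size Fokker-Planck grid resolution.
#' @param subsample maximum trials per (load, delay) condition used for
#'   fitting (randomly subsampled, seeded).
#' @param restarts number of seeded optimizer restarts.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param seed master seed; subsampling, starting points and fold
#'   assignment derive named substreams from it.
#' @param include_simultaneous_delay model the 0.45-s trials as well?
#' @return a list of class `ddm_config`.
#' @export
ddm_config <- function(grid_size = 128L, subsample = 3000L, restarts = 5L,
                       maxit = 150L, seed = 1L,
                       include_simultaneous_delay = FALSE) {
  structure(list(grid_size = as.integer(grid_size),
                 subsample = as.integer(subsample),
                 restarts = as.integer(restarts), maxit = as.integer(maxit),
                 seed = as.integer(seed),
                 include_simultaneous_delay = include_simultaneous_delay),
            class = "ddm_config")
}

ddm_variants <- function() {
  c("full", "no_encoding_drift", "no_memory_drift", "pure_diffusion")
}

## Pack/unpack the free parameter vector of a variant. sigma is optimized
## on the log scale; beta >= 0 and the mixture weights are box-bounded.
ddm_parameterization <- function(variant, has_load2, n_basis = 12L) {
  stopifnot(variant %in% ddm_variants())
  par <- list(); lower <- list(); upper <- list()
  add <- function(name, n, lo, hi) {
    par[[name]] <<- n; lower[[name]] <<- rep(lo, n); upper[[name]] <<- rep(hi, n)
  }
  if (variant != "pure_diffusion") add("weights", n_basis, -8, 8)
  if (!variant %in% c("no_encoding_drift", "pure_diffusion"))
    add("beta_encode", 2L, 0, 10)
  if (!variant %in% c("no_memory_drift", "pure_diffusion"))
    add("beta_memory", 2L, 0, 10)
  add("log_sigma_encode", 2L, log(0.02), log(3))
  add("log_sigma_memory", 2L, log(0.02), log(3))
  # jointly feasible: p_swap + p_guess <= 0.9 < 1 everywhere in the box
  add("p_guess", 2L, 1e-4, 0.45)
  if (has_load2) add("p_swap", 1L, 1e-4, 0.45)
  list(blocks = par, lower = unlist(lower), upper = unlist(upper))
}

ddm_unpack <- function(x, blocks, spacing = 2 * pi / 12) {
  out <- list(); i <- 1L
  for (nm in names(blocks)) {
    out[[nm]] <- x[i:(i + blocks[[nm]] - 1L)]
    i <- i + blocks[[nm]]
  }
  drift <- drift_field(out$weights %||% rep(0, round(2 * pi / spacing)),
                       spacing = spacing)
  ddm_params(drift,
             beta_encode = out$beta_encode %||% c(0, 0),
             sigma_encode = exp(out$log_sigma_encode),
             beta_memory = out$beta_memory %||% c(0, 0),
             sigma_memory = exp(out$log_sigma_memory),
             p_swap = if (is.null(out$p_swap)) 0 else out$p_swap,
             p_guess = out$p_guess)
}

ddm_start <- function(blocks, restart, seed) {
  with_seed(substream_seed(seed, paste0("restart", restart)), {
    x <- numeric(0)
    for (nm in names(blocks)) {
      v <- switch(nm,
        weights = stats::rnorm(blocks[[nm]], 0, if (restart == 1) 0.3 else 0.8),
        beta_encode = stats::runif(2, 0.2, if (restart == 1) 0.8 else 2),
        beta_memory = stats::runif(2, 0.2, if (restart == 1) 0.8 else 2),
        log_sigma_encode = log(stats::runif(2, 0.1, 0.5)),
        log_sigma_memory = log(stats::runif(2, 0.15, 0.7)),
        p_guess = rep(0.05, 2),
        p_swap = 0.08)
      x <- c(x, v)
    }
    x
  })
}

## Forward-difference gradient reusing the memoized objective value; the
## kernel cache inside the engine makes single-coordinate perturbations
## cheap (only the affected propagation kernels are recomputed).
fd_grad <- function(fn, eps = 1e-5) {
  function(x, f0 = NULL) {
    if (is.null(f0)) f0 <- fn(x)
    vapply(seq_along(x), function(j) {
      xj <- x; xj[j] <- xj[j] + eps
      (fn(xj) - f0) / eps
    }, numeric(1))
  }
}

#' Fit a drift-diffusion model variant by maximum likelihood
#'
#' Minimizes the joint negative log-likelihood over the basis weights of the
#' drift landscape, load- and phase-specific gains and noise, and swap/guess
#' weights, by L-BFGS-B with forward-difference gradients. Noise is
#' optimized on the log scale, gains are constrained non-negative, and
#' variants zero the corresponding gains and remove them from the search:
#' `no_encoding_drift` (no drift during encoding), `no_memory_drift` (none
#' during the delay), `pure_diffusion` (no drift at all). Up to
#' `config$subsample` trials per (load, delay) condition are used (seeded
#' subsample), with seeded random restarts. The fitted drift is normalized
#' to `max |G| = 1`, the gains absorbing the scale.
#'
#' @param trials trial table with responses (filtered via
#'   [modeled_trials()] internally).
#' @param variant one of `"full"`, `"no_encoding_drift"`,
#'   `"no_memory_drift"`, `"pure_diffusion"`.
#' @param config a [ddm_config()].
#' @param wheel a [color_wheel()].
#' @return object of class `ddm_fit`: `params` ([ddm_params()]), `nll`,
#'   `converged`, per-restart diagnostics, seeds, and the trial count used.
#' @export
fit_model <- function(trials, variant = "full", config = ddm_config(),
                      wheel = color_wheel()) {
  trials <- modeled_trials(trials, config$include_simultaneous_delay)
  if (nrow(trials) < 100)
    stop_wm("need at least 100 modeled trials")
  # seeded subsample per (load, delay) condition
  key <- paste(trials$load, trials$delay_s)
  keep <- with_seed(substream_seed(config$seed, "subsample"), {
    unlist(lapply(split(seq_len(nrow(trials)), key), function(i) {
      if (length(i) > config$subsample) sample(i, config$subsample) else i
    }), use.names = FALSE)
  })
  trials <- trials[sort(keep), , drop = FALSE]
  prep <- nll_prepare(trials, config$grid_size, wheel)
  engine <- nll_engine(prep)
  par_spec <- ddm_parameterization(variant, has_load2 = any(trials$load == 2))
  fn <- function(x) engine(ddm_unpack(x, par_spec$blocks))
  gr <- fd_grad(fn)
  best <- NULL
  restarts <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    x0 <- ddm_start(par_spec$blocks, r, config$seed)
    res <- tryCatch(
      stats::optim(x0, fn, gr, method = "L-BFGS-B",
                   lower = par_spec$lower, upper = par_spec$upper,
                   control = list(maxit = config$maxit, factr = 1e9)),
      error = function(e) {
        warning("restart ", r, " failed: ", conditionMessage(e),
                call. = FALSE)
        list(par = x0, value = fn(x0), convergence = 99L,
             message = conditionMessage(e))
      })
    restarts[[r]] <- list(value = res$value, convergence = res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  params <- ddm_unpack(best$par, par_spec$blocks)
  # fix the gain/weight scale degeneracy: max |G| = 1, beta carries gain
  if (variant != "pure_diffusion") {
    m <- max(abs(evaluate_drift(params$drift,
                                seq(0, 2 * pi, length.out = 4097))))
    if (m > 0) {
      params$drift$weights <- params$drift$weights / m
      params$beta_encode <- params$beta_encode * m
      params$beta_memory <- params$beta_memory * m
    }
  }
  structure(list(variant = variant, params = params, nll = best$value,
                 converged = identical(best$convergence, 0L),
                 convergence_code = best$convergence,
                 restarts = restarts, n_trials = nrow(trials),
                 seed = config$seed, config = config),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("DDM fit (", x$variant, "): NLL = ", format(x$nll, digits = 8),
      " on ", x$n_trials, " trials",
      if (!x$converged) " [not converged]", "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Cross-validated comparison of drift-diffusion model variants
#'
#' Trials are partitioned into `k_folds` folds, stratified by (load, delay)
#' condition. Each variant is trained on k-1 folds and scored by its
#' negative log-likelihood on the held-out fold. Reported are the per-fold
#' held-out NLL, the per-fold NLL relative to the best variant of that fold
#' (the best variant sits at 0), and the fold average.
#'
#' @param trials trial table with responses.
#' @param variants character vector of variants to compare.
#' @param k_folds number of folds (default 4).
#' @param config a [ddm_config()]; its seed also drives fold assignment.
#' @param wheel a [color_wheel()].
#' @return object of class `model_comparison`: matrices `nll` and
#'   `relative_nll` (folds x variants), `mean_relative_nll`, `folds`
#'   (assignment vector) and `seed`.
#' @export
cross_validate <- function(trials, variants = c("full", "no_memory_drift"),
                           k_folds = 4L, config = ddm_config(),
                           wheel = color_wheel()) {
  if (k_folds < 2) stop_wm("need at least 2 folds")
  stopifnot(all(variants %in% ddm_variants()))
  trials <- modeled_trials(trials, config$include_simultaneous_delay)
  key <- paste(trials$load, trials$delay_s)
  fold <- integer(nrow(trials))
  with_seed(substream_seed(config$seed, "folds"), {
    for (i in split(seq_len(nrow(trials)), key))
      fold[i] <- sample(rep_len(seq_len(k_folds), length(i)))
  })
  if (any(table(fold) == 0)) stop_wm("a fold received no trials")
  nll <- matrix(NA_real_, k_folds, length(variants),
                dimnames = list(paste0("fold", seq_len(k_folds)), variants))
  for (f in seq_len(k_folds)) {
    train <- trials[fold != f, , drop = FALSE]
    test <- trials[fold == f, , drop = FALSE]
    miss <- setdiff(unique(paste(trials$load, trials$delay_s)),
                    unique(paste(train$load, train$delay_s)))
    if (length(miss)) stop_wm("fold ", f, " leaves condition(s) unrepresented")
    cfg <- config
    cfg$seed <- substream_seed(config$seed, paste0("fold", f))
    for (v in variants) {
      fit <- fit_model(train, v, cfg, wheel)
      nll[f, v] <- negative_log_likelihood(fit$params, test,
                                           cfg$grid_size, wheel)
    }
  }
  rel <- nll - apply(nll, 1, min)
  structure(list(nll = nll, relative_nll = rel,
                 mean_relative_nll = colMeans(rel),
                 mean_nll = colMeans(nll), folds = fold,
                 seed = config$seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Cross-validated model comparison (held-out NLL):\n")
  print(round(x$nll, 2))
  cat("mean relative NLL (best variant = 0):\n")
  print(round(x$mean_relative_nll, 3))
  invisible(x)
}
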