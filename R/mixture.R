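# Three-component circular mixture model of response errors
# (target von Mises, non-target von Mises, uniform), fitted by EM.

#' Fit the three-component circular mixture model
#'
#' Response errors are modeled as
#' `pT * VM(e; 0, kappa) + pN * mean_j VM(e - delta_j; 0, kappa) + pU / (2*pi)`,
#' where `delta_j` are the trial's non-target offsets (the non-target color
#' relative to the target) and a single concentration `kappa` is shared by
#' the target and non-target components. Fitting is by
#' expectation-maximization: closed-form component weights, `kappa` by
#' numerical inversion of the Bessel ratio `A(kappa) = I1/I0` on the
#' responsibility-weighted resultant. Several seeded restarts from
#' stratified starting weights are run and the best log-likelihood is kept.
#' Without non-target offsets (load-1 data) `pN` is fixed at 0.
#'
#' @param errors signed response errors in radians, `n >= 10`.
#' @param nontarget_errors optional numeric vector aligned with `errors`:
#'   the signed error of each response relative to its trial's non-target
#'   color, `NA` where no non-target was shown; `NULL` for load-1 data.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param restarts number of seeded restarts.
#' @param seed seed for the restarts.
#' @param kappa_cap upper cap for `kappa` (degenerate point-mass data).
#' @return object of class `mixture_fit` with `kappa`, `p_t`, `p_n`, `p_u`,
#'   `loglik`, `n_iter`, `converged`, the log-likelihood `trace`, and
#'   `collapsed_uniform`. As `kappa -> 0` the von Mises components become
#'   uniform and the component weights are unidentifiable (a flat
#'   likelihood ridge); when the best fit fails to beat the pure-uniform
#'   model by the 95% chi-squared margin, the parsimonious uniform
#'   representative (`p_u = 1`, `kappa = 0`) is returned with
#'   `collapsed_uniform = TRUE`.
#' @export
fit_mixture <- function(errors, nontarget_errors = NULL, max_iter = 500L,
                        tol = 1e-8, restarts = 5L, seed = 1L,
                        kappa_cap = 1e4) {
  n <- length(errors)
  if (n < 10) stop_wm("need at least 10 errors")
  has_nt <- !is.null(nontarget_errors) && any(!is.na(nontarget_errors))
  if (has_nt && length(nontarget_errors) != n)
    stop_wm("nontarget_errors must align with errors")
  starts <- mixture_starts(restarts, has_nt, seed)
  best <- NULL
  for (s in starts) {
    fit <- mixture_em(errors, nontarget_errors, has_nt, s, max_iter, tol,
                      kappa_cap)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # Identifiability guard: as kappa -> 0 the von Mises components become
  # uniform and the weights lie on a flat likelihood ridge. When the fit
  # does not improve on the pure-uniform model beyond the 95% chi-squared
  # margin for the two extra effective parameters, report the parsimonious
  # uniform representative of that ridge.
  ll_unif <- -n * log(2 * pi)
  if (best$loglik - ll_unif < stats::qchisq(0.95, 2) / 2) {
    best$kappa <- 0
    best$p_t <- 0; best$p_n <- 0; best$p_u <- 1
    best$loglik <- ll_unif
    best$trace <- ll_unif
    best$collapsed_uniform <- TRUE
  } else {
    best$collapsed_uniform <- FALSE
  }
  best
}

mixture_starts <- function(restarts, has_nt, seed) {
  base <- list(c(p_t = 0.7, p_n = if (has_nt) 0.1 else 0, p_u = NA,
                 kappa = 8))
  with_seed(substream_seed(seed, "mixture"), {
    extra <- lapply(seq_len(max(restarts - 1, 0)), function(i) {
      p_t <- stats::runif(1, 0.2, 0.9)
      p_n <- if (has_nt) stats::runif(1, 0, (1 - p_t) * 0.8) else 0
      c(p_t = p_t, p_n = p_n, p_u = NA, kappa = stats::runif(1, 2, 30))
    })
    c(base, extra)
  })
}

mixture_em <- function(errors, nontarget_errors, has_nt, start, max_iter,
                       tol, kappa_cap) {
  n <- length(errors)
  p_t <- start[["p_t"]]; p_n <- start[["p_n"]]
  p_u <- 1 - p_t - p_n
  kappa <- start[["kappa"]]
  nt_ok <- if (has_nt) !is.na(nontarget_errors) else rep(FALSE, n)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ft <- dvonmises(errors, kappa)
    fn <- numeric(n)
    if (any(nt_ok)) fn[nt_ok] <- dvonmises(nontarget_errors[nt_ok], kappa)
    wt <- p_t * ft; wn <- p_n * fn; wu <- rep(p_u / (2 * pi), n)
    tot <- pmax(wt + wn + wu, 1e-300)
    rt <- wt / tot; rn <- wn / tot
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll < ll_old - 1e-9)
      stop_wm("EM log-likelihood decreased; internal error")
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    # M-step
    p_t <- mean(rt)
    p_n <- if (has_nt) mean(rn) else 0
    p_u <- max(1 - p_t - p_n, 0)
    w <- c(rt, rn[nt_ok])
    ang <- c(errors, nontarget_errors[nt_ok])
    sw <- sum(w)
    if (sw > 0) {
      # component means are fixed at 0, so the sufficient statistic is the
      # cosine moment (not the resultant length, which would re-estimate
      # the mean and can decrease the likelihood)
      cbar <- sum(w * cos(ang)) / sw
      kappa <- if (cbar <= 0) 0 else
        min(bessel_ratio_inv(min(cbar, 1 - 1e-12)), kappa_cap)
    }
  }
  structure(list(kappa = kappa, p_t = p_t, p_n = p_n, p_u = p_u,
                 loglik = trace[length(trace)], n_iter = iter,
                 converged = converged, trace = trace, n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Circular mixture fit (n = ", x$n, "): kappa = ",
      format(x$kappa, digits = 4), ", pT = ", format(x$p_t, digits = 3),
      ", pN = ", format(x$p_n, digits = 3), ", pU = ",
      format(x$p_u, digits = 3), ", logLik = ",
      format(x$loglik, digits = 8),
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' Log-likelihood of the circular mixture model
#'
#' Pure evaluation of the objective maximized by [fit_mixture()].
#'
#' @param fit a [fit_mixture()] result (or any list with `kappa`, `p_t`,
#'   `p_n`, `p_u`).
#' @param errors signed response errors.
#' @param nontarget_errors optional aligned non-target errors (`NA` where
#'   absent).
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(fit, errors, nontarget_errors = NULL) {
  n <- length(errors)
  nt_ok <- if (!is.null(nontarget_errors)) !is.na(nontarget_errors)
           else rep(FALSE, n)
  ft <- dvonmises(errors, fit$kappa)
  fn <- numeric(n)
  if (any(nt_ok)) fn[nt_ok] <- dvonmises(nontarget_errors[nt_ok], fit$kappa)
  sum(log(pmax(fit$p_t * ft + fit$p_n * fn + fit$p_u / (2 * pi), 1e-300)))
}

#' Swap-error rate of load-2 trials
#'
#' Quantifies how often the non-cued color was reported instead of the
#' target, in two ways: the mixture weight `p_n` of the non-target
#' component, and the posterior-responsibility count (fraction of trials
#' whose non-target responsibility exceeds both the target and the uniform
#' responsibility at the fitted parameters).
#'
#' @param trials load-2 trial table with responses.
#' @param fit optional precomputed [fit_mixture()]; fitted here otherwise.
#' @param wheel a [color_wheel()].
#' @param ... passed to [fit_mixture()].
#' @return list with `p_n`, `responsibility_rate`, `fit`, `n`.
#' @export
swap_error_rate <- function(trials, fit = NULL, wheel = color_wheel(), ...) {
  trials <- trials[trials$load == 2L, , drop = FALSE]
  if (!nrow(trials)) stop_wm("no load-2 trials")
  te <- trial_errors(trials, wheel)
  if (is.null(fit))
    fit <- fit_mixture(te$error_rad, te$nontarget_error_rad, ...)
  ft <- fit$p_t * dvonmises(te$error_rad, fit$kappa)
  fn <- fit$p_n * dvonmises(te$nontarget_error_rad, fit$kappa)
  fu <- rep(fit$p_u / (2 * pi), nrow(te))
  list(p_n = fit$p_n,
       responsibility_rate = mean(fn > ft & fn > fu),
       fit = fit, n = nrow(te))
}
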