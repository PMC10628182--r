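# Significance tests used by the behavioral analyses.

#' Hodges-Ajne test for non-uniformity of circular data
#'
#' The statistic `m` is the minimum number of observations in any closed
#' half-circle; small `m` indicates clustering. For `m < n/3` the exact
#' p-value `(n - 2m) * choose(n, m) / 2^(n-1)` is used; otherwise (weakly
#' clustered samples, where the exact formula is invalid) a seeded
#' Monte-Carlo null of uniform samples is used.
#'
#' @param angles numeric vector of angles in radians, `n >= 4`.
#' @param n_mc Monte-Carlo replicates for the fallback branch.
#' @param mc_seed internal seed for the fallback (fixed for
#'   reproducibility).
#' @return list with `m`, `p_value`, `n`, `method`.
#' @export
hodges_ajne_test <- function(angles, n_mc = 10000L, mc_seed = 20260928L) {
  n <- length(angles)
  if (n < 4) stop_wm("need at least 4 angles")
  m <- hodges_ajne_m(angles)
  if (m < n / 3) {
    p <- min(1, (n - 2 * m) * exp(lchoose(n, m) - (n - 1) * log(2)))
    method <- "exact"
  } else {
    p <- with_seed(mc_seed, {
      stat <- replicate(n_mc, hodges_ajne_m(stats::runif(n, 0, 2 * pi)))
      (sum(stat <= m) + 1) / (n_mc + 1)
    })
    method <- "monte-carlo"
  }
  list(m = m, p_value = p, n = n, method = method)
}

## Minimum half-circle count. As the half-circle boundary rotates, the
## count changes only when it passes a data point or an antipode, so the
## minimum is attained for a half-circle [a_i, a_i + pi) starting at a data
## point, or its complement. Counts for all starts come from one sorted
## scan (O(n log n)).
hodges_ajne_m <- function(angles) {
  a <- sort(wrap_0_2pi(angles))
  n <- length(a)
  ext <- c(a, a + 2 * pi)
  # points in [a_i, a_i + pi): all ext values in that window
  hi <- findInterval(a + pi - 1e-9, ext)
  count <- hi - (seq_len(n) - 1L)
  as.integer(min(pmin(count, n - count)))
}

#' Cochran's Q test for equality of proportions in matched binary data
#'
#' @param x binary matrix, blocks (rows) x groups (columns).
#' @return list with `Q`, `df`, `p_value`, and `degenerate` (TRUE when all
#'   rows are constant and Q is undefined).
#' @export
cochrans_q_test <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 2) stop_wm("need >= 2 groups and >= 2 blocks")
  if (!all(x %in% c(0, 1))) stop_wm("Cochran's Q needs binary input")
  k <- ncol(x)
  Gj <- colSums(x)
  Li <- rowSums(x)
  N <- sum(x)
  denom <- k * sum(Li) - sum(Li^2)
  if (denom == 0) {
    # every block is constant across groups: no within-block information.
    # The group totals are then necessarily equal, so no evidence against
    # the null is available; reported as Q = 0, p = 1 with a flag.
    return(list(Q = 0, df = k - 1L, p_value = 1, degenerate = TRUE))
  }
  Q <- k * (k - 1) * sum((Gj - N / k)^2) / denom
  list(Q = Q, df = k - 1L,
       p_value = stats::pchisq(Q, k - 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' One-sided exact binomial test against a chance level
#'
#' `P(X >= k)` under `Binomial(n, p0)`; used to test whether performance
#' exceeds the chance level of the graded reward scheme (11% for the full
#' reward range on a 64-color wheel).
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p0 chance probability, in (0, 1).
#' @return one-sided p-value.
#' @export
binomial_chance_test <- function(k, n, p0) {
  if (k < 0 || k > n) stop_wm("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop_wm("p0 must be in (0, 1)")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Friedman rank test with Kendall's W effect size
#'
#' Rank-based test for condition differences across matched blocks
#' (average-rank tie correction, via [stats::friedman.test()]), plus
#' Kendall's coefficient of concordance `W = chi^2 / (n (k - 1))`.
#'
#' @param x numeric matrix, blocks (rows) x conditions (columns).
#' @return list with `chisq`, `df`, `p_value`, `kendall_w`.
#' @export
friedman_test <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 2)
    stop_wm("need >= 2 conditions and >= 2 blocks")
  n <- nrow(x); k <- ncol(x)
  if (all(apply(x, 1, function(r) length(unique(r)) == 1))) {
    return(list(chisq = 0, df = k - 1L, p_value = 1, kendall_w = 0))
  }
  ft <- stats::friedman.test(x)
  chisq <- unname(ft$statistic)
  list(chisq = chisq, df = unname(ft$parameter),
       p_value = ft$p.value, kendall_w = chisq / (n * (k - 1)))
}

#' Two-way ANOVA with partial omega-squared effect sizes
#'
#' Fixed-effects two-way ANOVA of a performance measure on load, delay and
#' their interaction (cells replicated across sessions), with partial
#' omega-squared per term,
#' `(SS_t - df_t * MS_err) / (SS_t + (N - df_t) * MS_err)`, interpreted as
#' the percentage of explained variance. Negative estimates are preserved
#' (they arise under the null) and also reported clipped at zero.
#'
#' @param data data.frame with columns `value`, `load`, `delay` and one row
#'   per session x cell; the design must be balanced.
#' @return object of class `effect_size_report`: data.frame with columns
#'   `term`, `df`, `F`, `p_value`, `omega_sq_partial`, `omega_sq_clipped`.
#' @export
variance_partitioning <- function(data) {
  stopifnot(all(c("value", "load", "delay") %in% names(data)))
  data$load <- factor(data$load)
  data$delay <- factor(data$delay)
  counts <- table(data$load, data$delay)
  if (any(counts == 0)) stop_wm("empty design cell; balanced design required")
  if (length(unique(as.vector(counts))) != 1)
    stop_wm("unbalanced design; equal sessions per cell required")
  if (any(counts < 2)) stop_wm("need >= 2 sessions per cell")
  fit <- stats::aov(value ~ load * delay, data = data)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  err <- terms == "Residuals"
  ms_err <- tab[err, "Mean Sq"]
  N <- nrow(data)
  out <- do.call(rbind, lapply(which(!err), function(i) {
    ss <- tab[i, "Sum Sq"]; df <- tab[i, "Df"]
    om <- (ss - df * ms_err) / (ss + (N - df) * ms_err)
    data.frame(term = terms[i], df = df, F = tab[i, "F value"],
               p_value = tab[i, "Pr(>F)"], omega_sq_partial = om,
               omega_sq_clipped = max(om, 0), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("effect_size_report", "data.frame")
  out
}
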