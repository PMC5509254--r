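#' Fold-change resolvability: one-tailed two-sample t-test p-value
#'
#' The probability of failing to resolve a true fold-change given the
#' assay's measurement CV and replicate count. Parameterization: group means
#' 1 and `fold_change` on a unit scale, common standard deviation `cv`,
#' `n_replicates` per group, pooled variance, `df = 2n - 2`; the upper
#' one-tailed p is returned. At the assay's operating point (5.8% intraday
#' CV, duplicates) a 1.14-fold change gives p ~ 0.069.
#'
#' @param fold_change true ratio between the two groups, `>= 1`.
#' @param cv measurement coefficient of variation, in (0, 1).
#' @param n_replicates measurements per group, `>= 2`.
#' @return One-tailed p-value. Degenerate `cv = 0` returns 0 for
#'   `fold_change > 1` and 0.5 for `fold_change = 1`.
#' @examples
#' resolvability_pvalue(1.14, 0.058, 2)   # ~0.069
#' @export
resolvability_pvalue <- function(fold_change, cv, n_replicates) {
  if (any(fold_change < 1)) stop("resolvability: fold_change must be >= 1")
  if (any(cv < 0) || any(cv >= 1)) stop("resolvability: cv must be in [0, 1)")
  if (any(n_replicates < 2)) stop("resolvability: n_replicates must be >= 2")
  if (any(cv == 0)) {
    return(ifelse(fold_change > 1, 0, 0.5))
  }
  t_stat <- (fold_change - 1) / (cv * sqrt(2 / n_replicates))
  stats::pt(t_stat, df = 2 * n_replicates - 2, lower.tail = FALSE)
}

#' Fold-change resolvability certainty
#'
#' `100 x (1 - p)` from [resolvability_pvalue()]: the probability, in
#' percent, that a change of the given magnitude is correctly resolved.
#' This is the complement of the one-tailed p (the assay's reported usage),
#' not statistical power at a fixed alpha; see [resolvability_power()] for
#' the latter.
#'
#' @inheritParams resolvability_pvalue
#' @return Certainty in percent.
#' @examples
#' resolvability_certainty(1.14, 0.058, 2)  # ~93
#' resolvability_certainty(1.5, 0.058, 2)   # > 99
#' @export
resolvability_certainty <- function(fold_change, cv, n_replicates) {
  100 * (1 - resolvability_pvalue(fold_change, cv, n_replicates))
}

#' Power of the one-tailed two-sample t-test at a fixed level
#'
#' Classical power under the same parameterization as
#' [resolvability_pvalue()], using the noncentral t distribution.
#'
#' @inheritParams resolvability_pvalue
#' @param alpha test level.
#' @return Power in `[0, 1]`.
#' @export
resolvability_power <- function(fold_change, cv, n_replicates, alpha = 0.05) {
  df <- 2 * n_replicates - 2
  ncp <- (fold_change - 1) / (cv * sqrt(2 / n_replicates))
  crit <- stats::qt(alpha, df, lower.tail = FALSE)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
}

#' Per-miRNA coefficient-of-variation summary over replicates
#'
#' `intraday` grouping computes each species' CV (sd/mean) across all
#' replicate measurements; `interday` first averages within each day/gel
#' (`gel_id`) and computes the CV across those day means. Species with zero
#' mean are flagged and excluded from the mean CV.
#'
#' @param table an [intensity_table()] of replicate measurements (or a list
#'   of tables, concatenated).
#' @param grouping `"intraday"` or `"interday"`.
#' @return List with `per_mirna` (data.frame `mirna_id`, `cv`, `n`,
#'   `flags`) and `mean_cv` (fraction).
#' @export
cv_summary <- function(table, grouping = c("intraday", "interday")) {
  grouping <- match.arg(grouping)
  if (is.list(table) && !is.data.frame(table)) table <- do.call(rbind, table)
  ids <- unique(table$mirna_id)
  recs <- lapply(ids, function(id) {
    v <- table$intensity[table$mirna_id == id]
    g <- table$gel_id[table$mirna_id == id]
    if (grouping == "interday") {
      v <- tapply(v, g, mean)
    }
    if (length(v) < 2L) {
      stop("cv_summary: need >= 2 replicates per group for ", id)
    }
    m <- mean(v)
    if (m == 0) {
      data.frame(mirna_id = id, cv = NA_real_, n = length(v),
                 flags = "zero_mean", stringsAsFactors = FALSE)
    } else {
      data.frame(mirna_id = id, cv = stats::sd(v) / m, n = length(v),
                 flags = ".", stringsAsFactors = FALSE)
    }
  })
  per <- do.call(rbind, recs)
  list(per_mirna = per, mean_cv = mean(per$cv, na.rm = TRUE))
}

#' Mean absolute percent deviation from expected ratios
#'
#' `mean(|measured/expected - 1|) x 100` over paired ratios; pairs with a
#' zero expected value are excluded and counted in `n_excluded`.
#'
#' @param measured,expected paired numeric vectors.
#' @return List with `mean_deviation_pct`, `per_pair` percent deviations,
#'   and `n_excluded`.
#' @export
deviation_from_expected <- function(measured, expected) {
  if (length(measured) != length(expected)) {
    stop("deviation_from_expected: inputs must be paired")
  }
  bad <- is.na(expected) | expected == 0 | is.na(measured)
  dev <- abs(measured[!bad] / expected[!bad] - 1) * 100
  list(mean_deviation_pct = mean(dev), per_pair = dev,
       n_excluded = sum(bad))
}

#' Benchmarking regression between two differential-ratio sets
#'
#' Ordinary least squares of `y` on `x` with fitted intercept, as used to
#' compare differential-expression ratios between measurement platforms.
#'
#' @param x,y paired finite differential ratios, `n >= 3`.
#' @return Object of class `regression_summary`: list with `gradient`,
#'   `gradient_se`, `intercept`, `r_squared`, `n`.
#' @export
benchmark_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("benchmark_regression: need n >= 3 finite pairs")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  se <- sqrt(sum(res^2) / (length(x) - 2)) / sqrt(sum((x - mean(x))^2))
  structure(list(gradient = unname(stats::coef(fit)[2]),
                 gradient_se = se,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = .r_squared(fit, y),
                 n = length(x)),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("regression_summary: gradient = %.2f +/- %.2f, r2 = %.2f (n = %d)\n",
              x$gradient, x$gradient_se, x$r_squared, x$n))
  invisible(x)
}

#' Monte-Carlo copy-number error interval
#'
#' Propagates independent multiplicative error stages through a simulated
#' copy-number estimate: `estimate = prod(f_k)` with each `f_k` drawn with
#' mean 1 and SD equal to its stage CV (normal by default, matching CV
#' arithmetic; lognormal optional). Returns the requested percentile of the
#' absolute relative error in percent. Two 12%-CV stages give a 99th
#' percentile near `2.576 x sqrt(2) x 12% ~ 44%`, i.e. within the assay's
#' "99% of copy numbers within 50%" budget.
#'
#' @param stage_cvs numeric vector of per-stage CVs in (0, 1); empty gives 0.
#' @param percentile percentile of |relative error| to report (default 99).
#' @param n_sim simulated estimates, `>= 10000`.
#' @param seed integer RNG seed.
#' @param distribution `"normal"` or `"lognormal"` stage factors.
#' @return Percentile of `|estimate - 1| x 100`.
#' @export
copy_error_interval <- function(stage_cvs, percentile = 99, n_sim = 1e5,
                                seed = 1L, distribution = c("normal",
                                                            "lognormal")) {
  distribution <- match.arg(distribution)
  if (length(stage_cvs) == 0L) return(0)
  if (any(stage_cvs <= 0) || any(stage_cvs >= 1)) {
    stop("copy_error_interval: each cv must be in (0, 1)")
  }
  if (n_sim < 1e4) stop("copy_error_interval: n_sim must be >= 10,000")
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  est <- rep(1, n_sim)
  for (cv in stage_cvs) {
    f <- switch(distribution,
                normal = stats::rnorm(n_sim, 1, cv),
                lognormal = rlnorm_cv(n_sim, cv))
    est <- est * f
  }
  unname(stats::quantile(abs(est - 1) * 100, percentile / 100))
}

#' Convert a qPCR cycle-threshold difference to a fold-change
#'
#' `fold = 2^delta_ct`, the standard conversion for comparing Ct-scale
#' variability with ratio-scale variability.
#'
#' @param delta_ct cycle-threshold difference.
#' @return Fold-change.
#' @export
ct_to_fold <- function(delta_ct) 2^delta_ct
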