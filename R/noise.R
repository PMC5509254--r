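#' Stochastic model of the assay's signal chain
#'
#' Collects the parameters governing expected signal and its variability:
#' capture-ligation efficiency and per-miRNA capture bias, the number of
#' linear-amplification coding cycles, multiplicative intraday noise on raw
#' and reference-normalized band intensities, interday variability, per-gel
#' scanner drift, and an optional saturation level for the soft plateau seen
#' at the top of the dynamic range.
#'
#' Defaults are the assay's characterized operating point: 86% capture
#' efficiency with 10% capture-bias CV, 50 coding cycles, 7.9% raw / 5.8%
#' normalized intraday CV, and 22% interday CV. `scanner_drift_sd` defaults
#' to 0.20 so that intraday noise plus drift compose to the observed
#' interday CV (sqrt(0.079^2 + 0.20^2) ~ 0.215). `saturation_level = Inf`
#' disables the plateau; pass a finite fluorescence level to emulate it.
#'
#' All noise sources are multiplicative lognormal with mean 1, parameterized
#' by their CV.
#'
#' @param capture_efficiency fraction in (0, 1].
#' @param capture_bias_cv fraction in `[0, 1)`: CV of the fixed per-miRNA
#'   capture factor.
#' @param n_cycles integer >= 1, coding-ligation thermal cycles.
#' @param cv_intraday_raw,cv_intraday_norm,cv_interday fractions in `[0, 1)`.
#' @param scanner_drift_sd fraction: SD of the per-gel multiplicative drift.
#' @param saturation_level fluorescence units; `Inf` disables saturation.
#' @param seed integer recorded in all simulator outputs.
#' @return An object of class `noise_model` (a list of the above).
#' @export
noise_model <- function(capture_efficiency = 0.86,
                        capture_bias_cv = 0.10,
                        n_cycles = 50L,
                        cv_intraday_raw = 0.079,
                        cv_intraday_norm = 0.058,
                        cv_interday = 0.22,
                        scanner_drift_sd = 0.20,
                        saturation_level = Inf,
                        seed = 1L) {
  cvs <- c(capture_bias_cv, cv_intraday_raw, cv_intraday_norm, cv_interday)
  if (any(cvs < 0 | cvs >= 1)) {
    stop("noise_model: all CVs must lie in [0, 1)")
  }
  if (capture_efficiency <= 0 || capture_efficiency > 1) {
    stop("noise_model: capture_efficiency must be in (0, 1]")
  }
  if (n_cycles < 1) stop("noise_model: n_cycles must be >= 1")
  if (scanner_drift_sd < 0) stop("noise_model: scanner_drift_sd must be >= 0")
  if (saturation_level <= 0) stop("noise_model: saturation_level must be > 0")
  structure(list(
    capture_efficiency = capture_efficiency,
    capture_bias_cv = capture_bias_cv,
    n_cycles = as.integer(n_cycles),
    cv_intraday_raw = cv_intraday_raw,
    cv_intraday_norm = cv_intraday_norm,
    cv_interday = cv_interday,
    scanner_drift_sd = scanner_drift_sd,
    saturation_level = saturation_level,
    seed = as.integer(seed)
  ), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("noise_model:\n")
  cat(sprintf("  capture: efficiency %.2f, bias CV %.1f%%; %d coding cycles\n",
              x$capture_efficiency, 100 * x$capture_bias_cv, x$n_cycles))
  cat(sprintf("  CV: intraday raw %.1f%%, normalized %.1f%%, interday %.1f%%\n",
              100 * x$cv_intraday_raw, 100 * x$cv_intraday_norm,
              100 * x$cv_interday))
  cat(sprintf("  scanner drift SD %.2f; saturation %s; seed %d\n",
              x$scanner_drift_sd,
              if (is.finite(x$saturation_level))
                format(x$saturation_level) else "disabled",
              x$seed))
  invisible(x)
}

# coefficient of determination without summary.lm's degenerate-fit warnings
.r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / ss_tot))
}

# mean-1 multiplicative lognormal draws at a given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
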