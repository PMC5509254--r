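#' Ligation-inhibition reference curve
#'
#' Background total RNA above ~100 ng inhibits coding-ligation efficiency.
#' The curve is 1 below a threshold mass and decays logistically in log mass
#' above it (rescaled for continuity at the threshold); the floor, midpoint
#' and steepness may differ per miRNA, but every curve is deterministic and
#' repeatable. Per-miRNA parameters are derived from a hash of the miRNA
#' name so the same species always gets the same curve.
#'
#' @param mirna_id species name; `NULL` gives the panel-average curve.
#' @param threshold_ng mass below which efficiency is 1 (default 100).
#' @param midpoint_ng,hill,floor optional explicit curve parameters; when
#'   `NULL` they are derived from `mirna_id`.
#' @return Object of class `inhibition_curve` with an `efficiency(mass)`
#'   evaluator via [simulate_inhibition_curve()].
#' @export
inhibition_curve <- function(mirna_id = NULL, threshold_ng = 100,
                             midpoint_ng = NULL, hill = NULL, floor = NULL) {
  h <- if (is.null(mirna_id)) 0.5 else .name_hash01(mirna_id)
  if (is.null(midpoint_ng)) midpoint_ng <- 300 + 200 * h
  if (is.null(hill)) hill <- 2.5 + h
  if (is.null(floor)) floor <- 0.05 + 0.10 * h
  stopifnot(threshold_ng >= 0, midpoint_ng > 0, hill > 0,
            floor >= 0, floor < 1)
  structure(list(mirna_id = mirna_id, threshold_ng = threshold_ng,
                 midpoint_ng = midpoint_ng, hill = hill, floor = floor),
            class = "inhibition_curve")
}

# deterministic [0,1) hash of a species name (repeatable, seed-free)
.name_hash01 <- function(id) {
  codes <- utf8ToInt(as.character(id)[1])
  (sum(codes * seq_along(codes) * 2654435761) %% 10000L) / 10000
}

# fixed per-species lognormal capture-bias factors (mean 1, CV from the
# noise model); a property of the probe chemistry, so reproducible across
# simulate calls sharing a noise model seed
capture_bias_factors <- function(ids, noise) {
  if (noise$capture_bias_cv == 0) {
    return(stats::setNames(rep(1, length(ids)), ids))
  }
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  sdlog <- sqrt(log(1 + noise$capture_bias_cv^2))
  out <- vapply(ids, function(id) {
    set.seed((as.integer(noise$seed) * 7919L +
                as.integer(.name_hash01(id) * 1e4)) %% .Machine$integer.max)
    stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  }, numeric(1))
  stats::setNames(out, ids)
}

#' Coding-ligation efficiency at a given background RNA mass
#'
#' Evaluates an [inhibition_curve()]: efficiency is exactly 1 at 0 ng and up
#' to the threshold mass, then decreases monotonically.
#'
#' @param total_rna_ng background total RNA mass (ng), `>= 0`.
#' @param curve an [inhibition_curve()], or a miRNA name (a curve is derived).
#' @return Efficiency fraction in (0, 1].
#' @examples
#' simulate_inhibition_curve(0, "miR-21-5p")    # 1
#' simulate_inhibition_curve(500, "miR-21-5p") <
#'   simulate_inhibition_curve(100, "miR-21-5p")
#' @export
simulate_inhibition_curve <- function(total_rna_ng, curve = NULL) {
  if (any(total_rna_ng < 0)) stop("domain error: total_rna_ng must be >= 0")
  if (!inherits(curve, "inhibition_curve")) curve <- inhibition_curve(curve)
  L <- function(m) {
    curve$floor + (1 - curve$floor) / (1 + (m / curve$midpoint_ng)^curve$hill)
  }
  eff <- rep(1, length(total_rna_ng))
  above <- total_rna_ng > curve$threshold_ng
  if (any(above)) {
    eff[above] <- pmin(1, L(total_rna_ng[above]) / L(curve$threshold_ng))
  }
  eff
}

#' Lane layout and sample metadata
#'
#' One row per gel lane: which sample is loaded, what kind of input it is
#' (synthetic attomoles, counted cells, total or small RNA mass), the amount,
#' and replicate/gel identifiers.
#'
#' @param sample_id character vector of sample names.
#' @param input_type one of `synthetic_amol`, `cells`, `total_rna_ng`,
#'   `small_rna_ng` (recycled).
#' @param input_amount positive input amount per lane (recycled).
#' @param replicate_id,gel_id,lane identifiers (defaulted sensibly).
#' @return Object of class `sample_sheet` (a data.frame).
#' @export
sample_sheet <- function(sample_id,
                         input_type = "synthetic_amol",
                         input_amount = 1,
                         replicate_id = 1L,
                         gel_id = "gel1",
                         lane = seq_along(sample_id)) {
  types <- c("synthetic_amol", "cells", "total_rna_ng", "small_rna_ng")
  df <- data.frame(sample_id = as.character(sample_id),
                   input_type = rep_len(input_type, length(sample_id)),
                   input_amount = rep_len(input_amount, length(sample_id)),
                   replicate_id = rep_len(replicate_id, length(sample_id)),
                   gel_id = rep_len(as.character(gel_id), length(sample_id)),
                   lane = rep_len(as.integer(lane), length(sample_id)),
                   stringsAsFactors = FALSE)
  if (!all(df$input_type %in% types)) {
    stop("sample_sheet: input_type must be one of ",
         paste(types, collapse = ", "))
  }
  if (any(df$input_amount <= 0)) stop("sample_sheet: input_amount must be > 0")
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' Band-intensity table constructor
#'
#' The pipeline's central exchange format: background-subtracted band
#' fluorescence per (sample, miRNA), with gel/lane provenance and QC flags
#' (semicolon-separated; `"."` means none).
#'
#' @param gel_id,lane,sample_id,mirna_id,intensity,flags column vectors.
#' @return Object of class `intensity_table` (a data.frame).
#' @export
intensity_table <- function(gel_id, lane, sample_id, mirna_id, intensity,
                            flags = ".") {
  n <- length(intensity)
  if (any(intensity < 0)) stop("intensity_table: intensities must be >= 0")
  structure(data.frame(gel_id = rep_len(as.character(gel_id), n),
                       lane = rep_len(as.integer(lane), n),
                       sample_id = rep_len(as.character(sample_id), n),
                       mirna_id = rep_len(as.character(mirna_id), n),
                       intensity = as.numeric(intensity),
                       flags = rep_len(as.character(flags), n),
                       stringsAsFactors = FALSE),
            class = c("intensity_table", "data.frame"))
}

#' Deterministic expected band intensity
#'
#' The noise-free expectation of the signal chain for one species:
#' amount x capture efficiency x capture-bias factor x coding cycles x
#' ligation efficiency x response factor x gel drift, soft-clipped at the
#' saturation level (`I_sat = sat * I0 / (sat + I0)`).
#'
#' @param amount attomoles.
#' @param response_factor per-species fluorescence yield.
#' @param noise a [noise_model()].
#' @param bias fixed per-species capture-bias factor (default 1).
#' @param efficiency ligation efficiency from background inhibition.
#' @param drift per-gel multiplicative drift factor.
#' @param capture apply the capture stage (FALSE for mastermix spike-ins,
#'   which enter after capture).
#' @return Expected fluorescence (arbitrary units).
#' @export
expected_intensity <- function(amount, response_factor, noise,
                               bias = 1, efficiency = 1, drift = 1,
                               capture = TRUE) {
  i0 <- amount * noise$n_cycles * efficiency * response_factor * drift
  if (capture) i0 <- i0 * noise$capture_efficiency * bias
  soft_clip(i0, noise$saturation_level)
}

# smooth saturation: exact at 0, asymptote sat; identity when sat = Inf
soft_clip <- function(x, sat) {
  if (!is.finite(sat)) return(x)
  sat * x / (sat + x)
}

#' Simulate band intensities for a set of samples
#'
#' Runs the full stochastic signal chain for every (sample, species) pair:
#' optional cross-talk leakage on true amounts, capture ligation (efficiency
#' and a fixed per-species lognormal bias factor, skipped for mastermix
#' spike-ins), 50-cycle linear coding amplification, background-RNA ligation
#' inhibition (from the sheet's total-RNA input mass), per-species response
#' factor, per-gel multiplicative scanner drift, multiplicative intraday
#' noise, and soft saturation. Zero input gives exactly zero intensity.
#' Output is reproducible from the seed.
#'
#' @param true_amounts named numeric vector (single sample) or matrix
#'   (species x samples) of attomoles. Spike-in species absent from the rows
#'   are added at `spike_amol`.
#' @param panel a [panel_design()].
#' @param noise a [noise_model()].
#' @param sheet a [sample_sheet()]; defaulted from the column names.
#' @param crosstalk optional plex x plex leakage matrix over panel species
#'   (fractions; rows = input species, columns = probes; identity = none).
#' @param gel_drift optional named vector of per-gel drift factors; when
#'   `NULL`, drawn lognormal with SD `noise$scanner_drift_sd`.
#' @param spike_amol known amount at which spike-in species are added
#'   (default 1000).
#' @param seed integer; defaults to `noise$seed`.
#' @return An [intensity_table()] with attributes `seed`, `gel_drift`,
#'   `capture_bias` and `true_amounts`.
#' @export
simulate_intensities <- function(true_amounts, panel, noise = noise_model(),
                                 sheet = NULL, crosstalk = NULL,
                                 gel_drift = NULL, spike_amol = 1000,
                                 seed = noise$seed) {
  stopifnot(inherits(panel, "panel_design"), inherits(noise, "noise_model"))
  if (is.null(dim(true_amounts))) {
    true_amounts <- matrix(true_amounts, ncol = 1,
                           dimnames = list(names(true_amounts), "sample1"))
  }
  if (is.null(rownames(true_amounts))) {
    stop("panel-mismatch error: true_amounts must be named by mirna_id")
  }
  unknown <- setdiff(rownames(true_amounts), panel$mirna_id)
  if (length(unknown) > 0L) {
    stop("panel-mismatch error: species not in panel: ",
         paste(unknown, collapse = ", "))
  }
  if (any(true_amounts < 0)) stop("domain error: amounts must be >= 0")

  # spike-ins enter every reaction at known amounts
  spikes <- panel_targets(panel, c("spike_in_pellet", "spike_in_mastermix"))
  add <- setdiff(spikes, rownames(true_amounts))
  if (length(add) > 0L) {
    true_amounts <- rbind(true_amounts,
                          matrix(spike_amol, nrow = length(add),
                                 ncol = ncol(true_amounts),
                                 dimnames = list(add, colnames(true_amounts))))
  }
  ids <- rownames(true_amounts)

  if (is.null(sheet)) {
    sheet <- sample_sheet(colnames(true_amounts))
  }
  if (nrow(sheet) != ncol(true_amounts)) {
    stop("layout error: sheet rows must match amount columns")
  }

  if (!is.null(crosstalk)) {
    ct <- crosstalk[ids, ids, drop = FALSE]
    true_amounts <- t(ct) %*% true_amounts   # input i leaks into probe j
  }

  prow <- match(ids, panel$mirna_id)
  rf <- panel$response_factor[prow]
  is_mm <- panel$role[prow] == "spike_in_mastermix"
  # capture bias is a fixed property of each probe:miRNA pair: derived from
  # the species name and the noise model's seed, identical across calls
  bias <- capture_bias_factors(ids, noise)

  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))

  gels <- unique(sheet$gel_id)
  if (is.null(gel_drift)) {
    gel_drift <- stats::setNames(rlnorm_cv(length(gels),
                                           noise$scanner_drift_sd), gels)
  } else {
    if (!all(gels %in% names(gel_drift))) {
      stop("layout error: gel_drift must name every gel in the sheet")
    }
  }

  rows <- vector("list", nrow(sheet))
  for (s in seq_len(nrow(sheet))) {
    bg <- if (sheet$input_type[s] == "total_rna_ng") sheet$input_amount[s] else 0
    eff <- vapply(ids, function(id)
      simulate_inhibition_curve(bg, inhibition_curve(id)), numeric(1))
    mu <- expected_intensity(true_amounts[, s], rf, noise,
                             bias = ifelse(is_mm, 1, bias),
                             efficiency = eff,
                             drift = gel_drift[[sheet$gel_id[s]]],
                             capture = TRUE)
    mu[is_mm] <- expected_intensity(true_amounts[is_mm, s], rf[is_mm], noise,
                                    efficiency = eff[is_mm],
                                    drift = gel_drift[[sheet$gel_id[s]]],
                                    capture = FALSE)
    inten <- mu * rlnorm_cv(length(ids), noise$cv_intraday_raw)
    inten[true_amounts[, s] == 0] <- 0
    rows[[s]] <- intensity_table(sheet$gel_id[s], sheet$lane[s],
                                 sheet$sample_id[s], ids, inten)
  }
  out <- do.call(rbind, rows)
  out <- structure(out, class = c("intensity_table", "data.frame"))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "gel_drift") <- gel_drift
  attr(out, "capture_bias") <- bias
  attr(out, "true_amounts") <- true_amounts
  out
}

#' Cross-talk leakage preset mimicking a let-7 family panel
#'
#' An 8-plex leakage matrix over the let-7 family in which exactly five
#' probe:miRNA combinations exceed 5% cross-talk (let-7f:let-7a,
#' let-7c:let-7b, let-7a:let-7c, let-7a:let-7d, let-7a:let-7e — mismatches
#' distant from the ligation site), plus a handful of sub-5% entries.
#' Rows are the input miRNA, columns the responding probe; diagonal is 1.
#'
#' @return 8 x 8 numeric matrix of leakage fractions.
#' @export
crosstalk_preset_let7 <- function() {
  ids <- paste0("let-7", c("a", "b", "c", "d", "e", "f", "g", "i"))
  m <- diag(1, 8)
  dimnames(m) <- list(input = ids, probe = ids)
  # probe:miRNA pairs above the 5% threshold
  m["let-7a", "let-7f"] <- 0.18
  m["let-7b", "let-7c"] <- 0.12
  m["let-7c", "let-7a"] <- 0.09
  m["let-7d", "let-7a"] <- 0.08
  m["let-7e", "let-7a"] <- 0.11
  # limited (<5%) cross-talk in additional combinations
  m["let-7a", "let-7g"] <- 0.03
  m["let-7b", "let-7a"] <- 0.02
  m["let-7f", "let-7a"] <- 0.04
  m["let-7g", "let-7a"] <- 0.02
  m["let-7c", "let-7b"] <- 0.03
  m["let-7i", "let-7g"] <- 0.01
  m["let-7e", "let-7d"] <- 0.02
  m
}
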