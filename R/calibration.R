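#' Spike-in control set
#'
#' Technical controls of known amount added either to the cell pellet
#' (traversing the full assay, capture included) or to the reaction
#' mastermix (entering after capture), with the reference intensity each is
#' expected to produce on an undrifted gel.
#'
#' @param mirna_id spike-in species names.
#' @param stage `"cell_pellet"` or `"mastermix"` (recycled).
#' @param known_amol known input amounts (attomoles, > 0).
#' @param reference_intensity expected intensity at reference conditions.
#' @return Object of class `spike_in_set` (a data.frame).
#' @export
spike_in_set <- function(mirna_id, stage, known_amol, reference_intensity) {
  stages <- c("cell_pellet", "mastermix")
  df <- data.frame(mirna_id = as.character(mirna_id),
                   stage = rep_len(stage, length(mirna_id)),
                   known_amol = rep_len(known_amol, length(mirna_id)),
                   reference_intensity = rep_len(reference_intensity,
                                                 length(mirna_id)),
                   stringsAsFactors = FALSE)
  if (!all(df$stage %in% stages)) {
    stop("spike_in_set: stage must be one of ", paste(stages, collapse = ", "))
  }
  if (any(df$known_amol <= 0)) stop("spike_in_set: known_amol must be > 0")
  if (any(df$reference_intensity <= 0)) {
    stop("spike_in_set: reference_intensity must be > 0")
  }
  structure(df, class = c("spike_in_set", "data.frame"))
}

#' Correct per-gel scanner drift using spike-in controls
#'
#' For each gel, the drift factor is the geometric mean over its spike-ins
#' of measured / reference intensity; all intensities on the gel are divided
#' by it. Spike-ins measured exactly at reference give factor 1 and leave
#' the table unchanged. With `by_stage = TRUE` the mastermix spikes estimate
#' the scan/coding drift and the pellet spikes the full-chain factor (which
#' includes capture recovery); the correction then uses the pellet
#' (full-chain) factor for targets, with both stage factors reported.
#'
#' @param table an [intensity_table()] containing the spike-in bands.
#' @param spikes a [spike_in_set()].
#' @param by_stage combine pellet and mastermix factors per stage.
#' @return The corrected table, with per-gel factors as attribute
#'   `drift_factors` (and `stage_factors` when `by_stage`).
#' @export
drift_correction <- function(table, spikes, by_stage = FALSE) {
  stopifnot(inherits(spikes, "spike_in_set"))
  gels <- unique(table$gel_id)
  factors <- stats::setNames(numeric(length(gels)), gels)
  stage_factors <- list()
  for (g in gels) {
    sub <- table[table$gel_id == g & table$mirna_id %in% spikes$mirna_id, ]
    if (nrow(sub) == 0L) {
      stop("calibration error: gel ", g, " has no spike-in measurements")
    }
    ratio <- sub$intensity /
      spikes$reference_intensity[match(sub$mirna_id, spikes$mirna_id)]
    if (any(ratio <= 0)) {
      stop("calibration error: non-positive spike-in intensity on gel ", g)
    }
    if (by_stage) {
      st <- spikes$stage[match(sub$mirna_id, spikes$mirna_id)]
      geo <- function(x) exp(mean(log(x)))
      f_mm <- if (any(st == "mastermix")) geo(ratio[st == "mastermix"]) else 1
      f_full <- if (any(st == "cell_pellet")) geo(ratio[st == "cell_pellet"]) else f_mm
      stage_factors[[g]] <- c(mastermix = f_mm, capture = f_full / f_mm)
      factors[g] <- f_full
    } else {
      factors[g] <- exp(mean(log(ratio)))
    }
  }
  table$intensity <- table$intensity / factors[table$gel_id]
  attr(table, "drift_factors") <- factors
  if (by_stage) attr(table, "stage_factors") <- stage_factors
  table
}

#' Fit a per-miRNA standard curve
#'
#' Least-squares fit of log10(intensity) on log10(amount), the assay's
#' 4-point absolute-quantification standard. Saturated points are refused:
#' a curve fit through the compressed top of the response would bias every
#' inverted amount.
#'
#' @param amounts known input amounts (attomoles, > 0).
#' @param intensities measured intensities (> 0).
#' @param mirna_id species the curve belongs to.
#' @param saturated optional logical vector flagging saturated points.
#' @return Object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `range` (valid amount range), `n_points`.
#' @examples
#' sc <- fit_standard_curve(c(15, 150, 1500, 15000),
#'                          43 * c(15, 150, 1500, 15000), "miR-21-5p")
#' sc$slope      # 1
#' @export
fit_standard_curve <- function(amounts, intensities, mirna_id = NA,
                               saturated = NULL) {
  if (!is.null(saturated) && any(saturated)) {
    stop("saturation error: refusing to fit through saturated standards")
  }
  if (length(amounts) < 2L || length(intensities) != length(amounts)) {
    stop("fit error: need >= 2 (amount, intensity) pairs")
  }
  if (any(amounts <= 0) || any(intensities <= 0)) {
    stop("fit error: amounts and intensities must be > 0")
  }
  x <- log10(amounts)
  y <- log10(intensities)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("fit error: standard curve slope must be positive")
  r2 <- .r_squared(fit, y)
  structure(list(mirna_id = mirna_id, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, range = range(amounts),
                 n_points = length(amounts)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve [%s]: log10(I) = %.3f + %.3f*log10(amol); r2 = %.4f; %d points, %g-%g amol\n",
    x$mirna_id, x$intercept, x$slope, x$r_squared, x$n_points,
    x$range[1], x$range[2]))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Invert a standard curve: intensity to absolute amount
#'
#' Inverts the log-log fit. Intensity 0 maps to amount 0 with a
#' `below_range` flag. Outside the curve's valid amount range the result is
#' flagged `extrapolated`; the extrapolated value is returned only when
#' `extrapolate = TRUE`, otherwise `NA`.
#'
#' @param intensity non-negative intensity value(s).
#' @param curve a [fit_standard_curve()] result.
#' @param extrapolate allow inversion outside the valid range.
#' @return data.frame with columns `amount` (attomoles) and `flags`.
#' @export
intensity_to_amount <- function(intensity, curve, extrapolate = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(intensity < 0)) stop("domain error: intensity must be >= 0")
  amount <- ifelse(intensity > 0,
                   10^((log10(pmax(intensity, .Machine$double.xmin)) -
                          curve$intercept) / curve$slope),
                   0)
  flags <- rep(".", length(intensity))
  flags[intensity == 0] <- "below_range"
  outside <- intensity > 0 &
    (amount < curve$range[1] | amount > curve$range[2])
  flags[outside] <- "extrapolated"
  if (!extrapolate) amount[outside] <- NA_real_
  data.frame(amount = amount, flags = flags, stringsAsFactors = FALSE)
}

#' Correct an amount for background-RNA ligation inhibition
#'
#' Divides the measured amount by the ligation efficiency at the sample's
#' background total-RNA mass, read from an inhibition reference curve.
#'
#' @param amount measured attomoles (`>= 0`).
#' @param sample_total_rna_ng background total RNA mass (ng).
#' @param curve an [inhibition_curve()] (or miRNA name).
#' @return Corrected amount in attomoles.
#' @export
correct_inhibition <- function(amount, sample_total_rna_ng, curve = NULL) {
  if (any(amount < 0, na.rm = TRUE)) stop("domain error: amount must be >= 0")
  eff <- simulate_inhibition_curve(sample_total_rna_ng, curve)
  if (any(eff <= 0)) stop("domain error: efficiency must be > 0")
  amount / eff
}

#' Attomoles to molecule copies
#'
#' `copies = amol x 1e-18 x N_A` with Avogadro's number
#' `N_A = 6.02214076e23`; 1 amol is about 602,214 copies.
#'
#' @param amount attomoles (`>= 0`).
#' @return Molecule count (real-valued; rounding is presentation-only).
#' @export
amol_to_copies <- function(amount) {
  if (any(amount < 0, na.rm = TRUE)) stop("domain error: amount must be >= 0")
  amount * 1e-18 * 6.02214076e23
}

#' Cell equivalents of an assay input
#'
#' Counted-cell inputs pass through unchanged; total-RNA inputs are
#' converted at an assumed RNA content per cell (default 15 pg), so 500 ng
#' of total RNA corresponds to 33,333 cell equivalents.
#'
#' @param input_type `"cells"` or `"total_rna_ng"`.
#' @param input_amount positive input amount.
#' @param pg_total_rna_per_cell assumed pg of total RNA per cell.
#' @return Cell-equivalent count.
#' @export
cell_equivalents <- function(input_type, input_amount,
                             pg_total_rna_per_cell = 15) {
  if (any(input_amount <= 0)) stop("domain error: input_amount must be > 0")
  switch(input_type,
         cells = input_amount,
         total_rna_ng = input_amount * 1000 / pg_total_rna_per_cell,
         stop("unknown input_type: ", input_type))
}

#' Absolute copy-number profile from an intensity table
#'
#' The full calibration pipeline: spike-in drift correction, standard-curve
#' inversion to attomoles, background-RNA inhibition correction, conversion
#' to molecule copies, and division by cell equivalents. When a sample has
#' replicate lanes, per-miRNA copy numbers are averaged and their CV across
#' replicates is reported.
#'
#' @param table an [intensity_table()].
#' @param spikes a [spike_in_set()] for drift correction.
#' @param curves named list of [fit_standard_curve()] objects covering every
#'   quantified species in the table.
#' @param sheet a [sample_sheet()] giving each sample's input type/amount.
#' @param inhibition apply inhibition correction for total-RNA inputs.
#' @param extrapolate passed to [intensity_to_amount()].
#' @param pg_total_rna_per_cell assumed pg of total RNA per cell.
#' @return Object of class `copy_number_profile`: data.frame with
#'   `sample_id`, `mirna_id`, `amol`, `copies_per_cell`, `copies_per_ng`,
#'   `cv`, `flags`.
#' @export
compute_copy_profile <- function(table, spikes, curves, sheet,
                                 inhibition = TRUE, extrapolate = TRUE,
                                 pg_total_rna_per_cell = 15) {
  stopifnot(inherits(spikes, "spike_in_set"))
  quantified <- setdiff(unique(table$mirna_id), spikes$mirna_id)
  missing_curves <- setdiff(quantified, names(curves))
  if (length(missing_curves) > 0L) {
    stop("calibration error: no standard curve for ",
         paste(missing_curves, collapse = ", "))
  }
  corrected <- drift_correction(table, spikes)

  recs <- list()
  for (s in unique(sheet$sample_id)) {
    lanes <- sheet[sheet$sample_id == s, ]
    bg <- if (lanes$input_type[1] == "total_rna_ng") lanes$input_amount[1] else 0
    cells <- if (lanes$input_type[1] %in% c("cells", "total_rna_ng")) {
      cell_equivalents(lanes$input_type[1], lanes$input_amount[1],
                       pg_total_rna_per_cell)
    } else NA_real_
    ng <- switch(lanes$input_type[1],
                 total_rna_ng = lanes$input_amount[1],
                 cells = lanes$input_amount[1] * pg_total_rna_per_cell / 1000,
                 NA_real_)
    sub <- corrected[corrected$sample_id == s &
                       corrected$mirna_id %in% quantified, ]
    for (id in unique(sub$mirna_id)) {
      rows <- sub[sub$mirna_id == id, ]
      inv <- intensity_to_amount(rows$intensity, curves[[id]], extrapolate)
      amolv <- inv$amount
      if (inhibition && bg > 0) {
        amolv <- correct_inhibition(amolv, bg, inhibition_curve(id))
      }
      copies <- amol_to_copies(amolv)
      cpc <- copies / cells
      m <- mean(copies, na.rm = TRUE)
      cv <- if (sum(!is.na(copies)) >= 2 && m > 0) {
        stats::sd(copies, na.rm = TRUE) / m
      } else NA_real_
      flags <- unique(c(setdiff(unlist(strsplit(rows$flags, ";")), "."),
                        setdiff(inv$flags, ".")))
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = s, mirna_id = id,
        amol = mean(amolv, na.rm = TRUE),
        copies_per_cell = mean(cpc, na.rm = TRUE),
        copies_per_ng = mean(copies / ng, na.rm = TRUE),
        cv = cv,
        flags = if (length(flags) == 0L) "." else paste(flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  structure(out, class = c("copy_number_profile", "data.frame"))
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat(sprintf("copy_number_profile: %d species x %d sample(s)\n",
              length(unique(x$mirna_id)), length(unique(x$sample_id))))
  ok <- is.finite(x$copies_per_cell)
  if (any(ok)) {
    cat(sprintf("  copies/cell range: %.3g-%.3g; mean replicate CV: %s\n",
                min(x$copies_per_cell[ok]), max(x$copies_per_cell[ok]),
                if (all(is.na(x$cv))) "n/a"
                else sprintf("%.1f%%", 100 * mean(x$cv, na.rm = TRUE))))
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
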