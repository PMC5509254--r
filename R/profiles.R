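#' Normalize a per-sample expression profile
#'
#' Supported schemes: `raw` (identity), `reference_gene` (divide every value
#' by the reference species, removing any per-sample multiplicative input
#' factor exactly), `fractional` (divide by the summed expression of the
#' panel's miRNA targets — snRNA references and spike-ins are excluded from
#' the denominator, so fractions sum to 1 over targets), and the
#' pass-through schemes `copies_per_cell` / `per_ng_total_rna` for values
#' already calibrated upstream.
#'
#' @param values named numeric vector of per-species values for one sample.
#' @param panel a [panel_design()] (supplies roles for `fractional`).
#' @param scheme normalization scheme.
#' @param ref_id reference species for `reference_gene` (e.g. `"RNU44"`).
#' @param sample_id optional sample label.
#' @return Object of class `normalized_profile`: data.frame with `mirna_id`,
#'   `value`, and attributes `scheme`, `ref_id`, `sample_id`.
#' @export
normalize_profile <- function(values, panel, scheme = "raw", ref_id = NULL,
                              sample_id = NA) {
  stopifnot(inherits(panel, "panel_design"))
  schemes <- c("raw", "reference_gene", "fractional", "copies_per_cell",
               "per_ng_total_rna")
  if (!scheme %in% schemes) {
    stop("normalization error: unknown scheme ", scheme)
  }
  if (is.null(names(values))) {
    stop("normalization error: values must be named by mirna_id")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("normalization error: values must be >= 0")
  }
  out <- values
  if (scheme == "reference_gene") {
    if (is.null(ref_id) || !ref_id %in% names(values)) {
      stop("normalization error: reference ", ref_id %||% "<missing>",
           " not present")
    }
    if (is.na(values[[ref_id]]) || values[[ref_id]] == 0) {
      stop("normalization error: reference ", ref_id, " is zero or missing")
    }
    out <- values / values[[ref_id]]
  } else if (scheme == "fractional") {
    targets <- intersect(panel_targets(panel, "target"), names(values))
    denom <- sum(values[targets], na.rm = TRUE)
    if (denom <= 0) stop("normalization error: total target expression is 0")
    out <- values / denom
  }
  structure(data.frame(mirna_id = names(values), value = unname(out),
                       stringsAsFactors = FALSE),
            class = c("normalized_profile", "data.frame"),
            scheme = scheme, ref_id = ref_id, sample_id = sample_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Differential expression between a sample and a baseline
#'
#' Per-species ratio sample/baseline under a common normalization scheme;
#' for the `fractional` scheme the absolute difference in expression
#' fraction is also returned (over the panel targets these differences sum
#' to zero). A zero baseline with nonzero sample signal is reported as an
#' undefined ratio (NA, flagged) rather than infinity, and excluded from
#' summary statistics downstream.
#'
#' @param profile,baseline_profile [normalize_profile()] results sharing a
#'   scheme and species set.
#' @return Object of class `differential_result`: data.frame with
#'   `mirna_id`, `ratio`, `abs_diff` (NA unless fractional), `flags`, and
#'   attributes `scheme`, `baseline_id`.
#' @export
differential <- function(profile, baseline_profile) {
  s1 <- attr(profile, "scheme")
  s0 <- attr(baseline_profile, "scheme")
  if (!identical(s1, s0)) {
    stop("scheme mismatch: ", s1, " vs ", s0)
  }
  if (!setequal(profile$mirna_id, baseline_profile$mirna_id)) {
    stop("differential: profiles cover different species")
  }
  b <- baseline_profile$value[match(profile$mirna_id,
                                    baseline_profile$mirna_id)]
  v <- profile$value
  ratio <- v / b
  flags <- rep(".", length(v))
  undef <- !is.na(b) & b == 0 & !is.na(v) & v > 0
  ratio[undef] <- NA_real_
  flags[undef] <- "undefined_ratio"
  ratio[!is.na(b) & b == 0 & !is.na(v) & v == 0] <- NA_real_
  abs_diff <- if (identical(s1, "fractional")) v - b else rep(NA_real_, length(v))
  structure(data.frame(mirna_id = profile$mirna_id, ratio = ratio,
                       abs_diff = abs_diff, flags = flags,
                       stringsAsFactors = FALSE),
            class = c("differential_result", "data.frame"),
            scheme = s1, baseline_id = attr(baseline_profile, "sample_id"))
}

#' Check the titration ordering response
#'
#' Averages replicates per (sample, species), then evaluates the strict
#' inequality chain given by `expect` (default S1 < S4 < S3 < S2, the
#' ordering implied by the convex titration mixtures when S1 < S2) on the
#' mean intensities of every measured species. Ties fail. When a panel is
#' supplied, spike-in species are excluded (they are constant by design).
#'
#' @param table an [intensity_table()] containing all four samples (or a
#'   list of tables, which are concatenated).
#' @param expect sample ids in expected ascending order.
#' @param panel optional [panel_design()] used to drop spike-in species.
#' @return List with `per_mirna` (data.frame `mirna_id`, `pass`) and
#'   `fraction_correct`.
#' @export
titration_order_check <- function(table, expect = c("S1", "S4", "S3", "S2"),
                                  panel = NULL) {
  if (is.list(table) && !is.data.frame(table)) {
    table <- do.call(rbind, table)
  }
  missing_samples <- setdiff(expect, unique(table$sample_id))
  if (length(missing_samples) > 0L) {
    stop("titration error: missing sample(s) ",
         paste(missing_samples, collapse = ", "))
  }
  ids <- unique(table$mirna_id)
  if (!is.null(panel)) {
    ids <- intersect(ids, panel_targets(panel, c("target", "reference")))
  }
  means <- sapply(expect, function(s) {
    vapply(ids, function(id) {
      mean(table$intensity[table$sample_id == s & table$mirna_id == id])
    }, numeric(1))
  })
  if (length(ids) == 1L) means <- matrix(means, nrow = 1,
                                         dimnames = list(ids, expect))
  pass <- apply(means, 1, function(x) all(diff(x) > 0))
  list(per_mirna = data.frame(mirna_id = ids, pass = unname(pass),
                              stringsAsFactors = FALSE),
       fraction_correct = mean(pass))
}

#' Cross-talk matrix from single-plex lanes
#'
#' Entry (i, j) is the intensity of probe j's band when only species i is
#' input, as a percent of species i's on-target intensity; the diagonal is
#' 100%. A zero on-target intensity makes the row undefined (NA, flagged).
#'
#' @param single_plex_tables named list, one [intensity_table()] (or named
#'   intensity vector) per single-plex input species.
#' @param panel a [panel_design()] giving the probe set.
#' @return plex x plex percentage matrix (rows = input species, columns =
#'   probes), with undefined input rows listed in attribute `flagged`.
#' @export
crosstalk_matrix <- function(single_plex_tables, panel) {
  stopifnot(inherits(panel, "panel_design"))
  ids <- panel$mirna_id
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(input = ids, probe = ids))
  flagged <- character(0)
  for (i in ids) {
    tab <- single_plex_tables[[i]]
    if (is.null(tab)) stop("crosstalk error: no single-plex table for ", i)
    v <- if (is.data.frame(tab)) {
      stats::setNames(tab$intensity, tab$mirna_id)
    } else tab
    on_target <- v[[i]]
    if (is.na(on_target) || on_target <= 0) {
      flagged <- c(flagged, i)
      next
    }
    m[i, names(v)] <- 100 * unname(v) / on_target
  }
  attr(m, "flagged") <- flagged
  m
}
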