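#' Titration design for differential-sensitivity testing
#'
#' Two base samples S1 and S2 are mixed to generate S3 and S4, creating small
#' known fold-changes at three expression levels. The default design places
#' miRNA at low (10 amol), medium (100 amol), and high (1000 amol) levels
#' with maximum fold-changes of 3, 3, and 2 respectively, and mixes
#' S3 = 0.25*S1 + 0.75*S2 and S4 = 0.75*S1 + 0.25*S2. The smallest pairwise
#' ratio this produces is S2/S3 = 1/(0.25/2 + 0.75) ~ 1.14 at the high level.
#'
#' @param levels data.frame with columns `name`, `base_amount` (attomoles;
#'   the S2 amount at that level), `max_fold` (S2/S1 at that level).
#' @param mixtures named list mapping derived-sample names to `c(w1, w2)`
#'   weights on (S1, S2); weights must be non-negative and sum to 1.
#' @return Object of class `titration_design`.
#' @export
titration_design <- function(
    levels = data.frame(name = c("low", "medium", "high"),
                        base_amount = c(10, 100, 1000),
                        max_fold = c(3, 3, 2)),
    mixtures = list(S3 = c(0.25, 0.75), S4 = c(0.75, 0.25))) {
  stopifnot(is.data.frame(levels),
            all(c("name", "base_amount", "max_fold") %in% names(levels)))
  if (any(levels$base_amount <= 0)) stop("titration_design: base_amount must be > 0")
  if (any(levels$max_fold < 1)) stop("titration_design: max_fold must be >= 1")
  for (nm in names(mixtures)) {
    w <- mixtures[[nm]]
    if (length(w) != 2L || any(w < 0) || abs(sum(w) - 1) > 1e-12) {
      stop("titration_design: mixture weights for ", nm,
           " must be non-negative and sum to 1")
    }
  }
  structure(list(levels = levels, mixtures = mixtures),
            class = "titration_design")
}

#' @export
print.titration_design <- function(x, ...) {
  cat("titration_design:\n")
  for (i in seq_len(nrow(x$levels))) {
    cat(sprintf("  %s: S2 = %g amol, max fold %g\n",
                x$levels$name[i], x$levels$base_amount[i], x$levels$max_fold[i]))
  }
  for (nm in names(x$mixtures)) {
    w <- x$mixtures[[nm]]
    cat(sprintf("  %s = %.2f*S1 + %.2f*S2\n", nm, w[1], w[2]))
  }
  invisible(x)
}

#' Mix base samples into the full titration sample set
#'
#' Given per-miRNA true amounts for the base samples S1 and S2, returns the
#' true amounts of every sample in the design. Derived samples are exact
#' convex combinations, so for any miRNA with S1 < S2 the ordering
#' S1 < S4 < S3 < S2 holds exactly in true amounts.
#'
#' @param design a [titration_design()].
#' @param s1_amounts,s2_amounts named numeric vectors of attomoles over the
#'   same miRNA set.
#' @return A matrix (miRNA x samples) of true amounts with columns
#'   `S1`, `S2`, and the design's derived samples.
#' @examples
#' d <- titration_design()
#' make_titration_samples(d, c(x = 500), c(x = 1000))  # S3 = 875, S4 = 625
#' @export
make_titration_samples <- function(design, s1_amounts, s2_amounts) {
  stopifnot(inherits(design, "titration_design"))
  if (is.null(names(s1_amounts)) || is.null(names(s2_amounts)) ||
      !setequal(names(s1_amounts), names(s2_amounts))) {
    stop("design error: S1 and S2 must cover the same named miRNA set")
  }
  if (any(s1_amounts < 0) || any(s2_amounts < 0)) {
    stop("design error: amounts must be >= 0")
  }
  ids <- names(s1_amounts)
  s2 <- s2_amounts[ids]
  out <- cbind(S1 = unname(s1_amounts), S2 = unname(s2))
  for (nm in names(design$mixtures)) {
    w <- design$mixtures[[nm]]
    out <- cbind(out, w[1] * out[, "S1"] + w[2] * out[, "S2"])
    colnames(out)[ncol(out)] <- nm
  }
  rownames(out) <- ids
  out
}

#' Assign panel targets to titration levels and build base amounts
#'
#' Distributes the panel's measured species (targets and references; spike-ins
#' excluded) cyclically across the design's levels. At each level the S2
#' amount is the level's base amount and the S1 amount is base/max_fold, so
#' each species realizes its level's maximum fold-change.
#'
#' @param panel a [panel_design()].
#' @param design a [titration_design()].
#' @return List with named vectors `s1`, `s2` and the level assignment.
#' @export
titration_truth <- function(panel, design = titration_design()) {
  stopifnot(inherits(panel, "panel_design"))
  ids <- panel_targets(panel, c("target", "reference"))
  if (length(ids) == 0L) stop("design error: panel has no measured species")
  lev <- design$levels[rep_len(seq_len(nrow(design$levels)), length(ids)), ]
  s2 <- stats::setNames(lev$base_amount, ids)
  s1 <- stats::setNames(lev$base_amount / lev$max_fold, ids)
  list(s1 = s1, s2 = s2,
       level = stats::setNames(lev$name, ids))
}
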