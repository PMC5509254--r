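#' Construct a length-coded probe panel
#'
#' A panel maps each miRNA (or control) to a unique single-stranded DNA
#' product length, so that band position on a denaturing PAGE gel identifies
#' the species. Panels carry per-target roles (`target`, `spike_in_pellet`,
#' `spike_in_mastermix`, `reference`, `ladder`) and per-target response
#' factors (dimensionless fluorescence yield relative to the panel mean).
#'
#' @param targets data.frame with columns `mirna_id`, `product_length`,
#'   `role`, `response_factor`.
#' @return An object of class `panel_design`: the validated data.frame with
#'   a `plex` attribute.
#' @export
panel_design <- function(targets) {
  stopifnot(is.data.frame(targets))
  required <- c("mirna_id", "product_length", "role", "response_factor")
  missing_cols <- setdiff(required, names(targets))
  if ("response_factor" %in% missing_cols) {
    targets$response_factor <- 1.0
    warning("response_factor missing; default 1.0 applied", call. = FALSE)
    missing_cols <- setdiff(missing_cols, "response_factor")
  }
  if (length(missing_cols) > 0L) {
    stop("invalid panel: missing fields ", paste(missing_cols, collapse = ", "))
  }
  targets$mirna_id <- as.character(targets$mirna_id)
  plex <- nrow(targets)
  if (plex < 1L || plex > 26L) {
    stop("invalid panel: plex must be in [1, 26], got ", plex)
  }
  if (anyDuplicated(targets$mirna_id)) {
    stop("invalid panel: duplicated mirna_id")
  }
  if (anyDuplicated(targets$product_length)) {
    stop("invalid panel: product lengths must be unique (length coding)")
  }
  if (any(targets$product_length <= 0)) {
    stop("invalid panel: product_length must be positive")
  }
  roles <- c("target", "spike_in_pellet", "spike_in_mastermix",
             "reference", "ladder")
  if (!all(targets$role %in% roles)) {
    stop("invalid panel: unknown role(s) ",
         paste(setdiff(unique(targets$role), roles), collapse = ", "))
  }
  if (any(targets$response_factor <= 0)) {
    stop("invalid panel: response_factor must be positive")
  }
  rownames(targets) <- NULL
  structure(targets, class = c("panel_design", "data.frame"), plex = plex)
}

#' Default multiplex panel
#'
#' Builds a panel in the assay's standard composition: up to 26 species with
#' unique, evenly spaced product lengths. For `plex >= 6` the panel follows
#' the canonical 26-plex layout (4 internal controls split between pellet and
#' mastermix spike-in stages, 2 snRNA references, the remainder miRNA
#' targets); for `plex >= 4` one reference and one spike-in of each stage are
#' included so copy-number calibration can be exercised. Response factors are
#' drawn uniformly on the log10 scale within a 10-fold band (the assay's
#' specified max/min response spread) and are fixed by `seed`.
#'
#' @param plex integer in `[1, 26]`, number of co-assayed species.
#' @param seed integer seed fixing the response-factor draw.
#' @return A [panel_design()].
#' @examples
#' p <- make_default_panel(26, seed = 1)
#' nrow(p)                       # 26
#' max(p$response_factor) / min(p$response_factor) <= 10
#' @export
make_default_panel <- function(plex, seed = 1L) {
  if (!is.numeric(plex) || length(plex) != 1L || is.na(plex) ||
      plex != round(plex) || plex < 1 || plex > 26) {
    stop("invalid panel: plex must be an integer in [1, 26]")
  }
  plex <- as.integer(plex)
  mirna_pool <- c(
    "miR-16-5p", "miR-21-5p", "miR-205-5p", "let-7a-5p", "miR-15a-5p",
    "miR-17-5p", "miR-106a-5p", "miR-155-5p", "miR-31-5p", "miR-200c-3p",
    "miR-141-3p", "miR-125b-5p", "miR-99a-5p", "miR-34a-5p", "miR-143-3p",
    "miR-145-5p", "miR-10b-5p", "miR-221-3p", "miR-222-3p", "miR-26a-5p"
  )
  ids <- character(plex)
  roles <- character(plex)
  if (plex >= 6L) {
    n_spike <- 4L
    n_ref <- 2L
    n_target <- plex - n_spike - n_ref
    ids <- c(paste0("Crc-", 1:4), "RNU44", "RNU6B", mirna_pool[seq_len(n_target)])
    roles <- c("spike_in_pellet", "spike_in_pellet",
               "spike_in_mastermix", "spike_in_mastermix",
               "reference", "reference", rep("target", n_target))
  } else if (plex >= 4L) {
    extra <- plex - 3L
    ids <- c("Crc-1", "Crc-3", "RNU44", mirna_pool[seq_len(extra)])
    roles <- c("spike_in_pellet", "spike_in_mastermix", "reference",
               rep("target", extra))
  } else {
    ids <- mirna_pool[seq_len(plex)]
    roles <- rep("target", plex)
  }
  # evenly spaced lengths, 4 nt apart, shortest 40 nt: resolvable on 15% PAGE
  lengths <- 40L + 4L * (seq_len(plex) - 1L)
  rf <- local({
    old <- .Random.seed_exists()
    on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
    10^stats::runif(plex, -0.5, 0.5)
  })
  panel_design(data.frame(
    mirna_id = ids,
    product_length = lengths,
    role = roles,
    response_factor = rf,
    stringsAsFactors = FALSE
  ))
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("panel_design: %d-plex length-coded panel\n", attr(x, "plex")))
  cat(sprintf("  lengths: %d-%d nt; roles: %s\n",
              min(x$product_length), max(x$product_length),
              paste(sprintf("%s (%d)", names(table(x$role)), table(x$role)),
                    collapse = ", ")))
  invisible(x)
}

#' Panel targets by role
#'
#' @param panel a [panel_design()].
#' @param role role string or vector of roles.
#' @return Character vector of `mirna_id`s with the requested role(s).
#' @export
panel_targets <- function(panel, role = "target") {
  stopifnot(inherits(panel, "panel_design"))
  panel$mirna_id[panel$role %in% role]
}

# Preserve and restore the caller's RNG state so that seeded draws inside
# constructors do not perturb the session-level random stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
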