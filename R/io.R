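#' Read and write panel designs as JSON
#'
#' The JSON roundtrip is exact: `write_panel()` then [read_panel()]
#' reproduces the panel. Panels violating the length-coding invariants
#' (duplicate lengths, unknown roles) are rejected on read; a missing
#' `response_factor` field defaults to 1.0 with a warning.
#'
#' @param panel a [panel_design()].
#' @param path file path.
#' @return `read_panel()` returns a [panel_design()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_design"))
  jsonlite::write_json(list(plex = attr(panel, "plex"),
                            targets = as.data.frame(panel)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$targets)) stop("schema error at $targets: missing")
  panel_design(as.data.frame(obj$targets))
}

#' Read and write noise models, sample sheets, titration designs as JSON
#'
#' @param x the object.
#' @param path file path.
#' @name json_io
#' @export
write_noise_model <- function(x, path) {
  stopifnot(inherits(x, "noise_model"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname json_io
#' @export
read_noise_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$saturation_level <- if (is.character(obj$saturation_level) ||
                              is.null(obj$saturation_level)) Inf
                          else obj$saturation_level
  do.call(noise_model, obj)
}

#' @rdname json_io
#' @export
write_sample_sheet <- function(x, path) {
  stopifnot(inherits(x, "sample_sheet"))
  jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname json_io
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  do.call(sample_sheet, as.list(df))
}

#' Read and write intensity tables as TSV
#'
#' Plain UTF-8 TSV with one header line and `#`-prefixed provenance
#' comments; columns `gel_id`, `lane`, `sample_id`, `mirna_id`,
#' `intensity`, `flags` (semicolon-separated tokens, `"."` = none).
#'
#' @param table an [intensity_table()].
#' @param path file path.
#' @param provenance optional named character vector written as `# key: value`.
#' @return `read_intensity_table()` returns an [intensity_table()].
#' @export
write_intensity_table <- function(table, path, provenance = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  seed <- attr(table, "seed")
  if (!is.null(seed) && !"seed" %in% names(provenance)) {
    provenance <- c(provenance, seed = as.character(seed))
  }
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  }
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_table
#' @export
read_intensity_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  body <- lines[!is_comment]
  if (length(body) == 0L) stop("parse error: no header line")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  required <- c("gel_id", "lane", "sample_id", "mirna_id", "intensity",
                "flags")
  if (!identical(header, required)) {
    stop("parse error: header must be ", paste(required, collapse = ", "))
  }
  if (length(body) == 1L) {
    return(intensity_table(character(0), integer(0), character(0),
                           character(0), numeric(0), character(0)))
  }
  body_line_no <- which(!is_comment)
  df <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "character", "numeric", "character"))
  bad <- which(is.na(df$intensity) | df$intensity < 0)
  if (length(bad) > 0L) {
    stop("parse error: invalid intensity at line ",
         body_line_no[bad[1] + 1L], ", column intensity")
  }
  out <- intensity_table(df$gel_id, df$lane, df$sample_id, df$mirna_id,
                         df$intensity, df$flags)
  out
}

#' Read and write gel images as grayscale TIFF
#'
#' 16-bit (or 8-bit) single-channel grayscale TIFF; counts are stored
#' losslessly as `value / (2^bit_depth - 1)` samples.
#'
#' @param image a [gel_image()].
#' @param path file path.
#' @return `read_gel_tiff()` returns a `gel_image`.
#' @export
write_gel_tiff <- function(image, path) {
  bit <- attr(image, "bit_depth") %||% 16L
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m / (2^bit - 1), path, bits.per.sample = bit)
  invisible(path)
}

#' @rdname write_gel_tiff
#' @export
read_gel_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  bit <- attr(img, "bits.per.sample") %||% 16L
  structure(round(img), class = "gel_image", bit_depth = as.integer(bit))
}

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed, recorded in every output.
#' @param stages stages to run, a subset of
#'   `c("simulate", "render", "quantify", "calibrate", "profile", "stats")`,
#'   executed in that order.
#' @param plex panel size for synthetic runs.
#' @param noise a [noise_model()] (or path to its JSON).
#' @param table_path existing intensity-table TSV for table-only runs
#'   (skips simulation).
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "render", "quantify",
                                  "calibrate", "profile", "stats"),
                       plex = 26L, noise = noise_model(), table_path = NULL) {
  all_stages <- c("simulate", "render", "quantify", "calibrate", "profile",
                  "stats")
  if (!all(stages %in% all_stages)) {
    stop("validation error: unknown stage(s) ",
         paste(setdiff(stages, all_stages), collapse = ", "))
  }
  if (is.character(noise)) {
    if (!file.exists(noise)) stop("validation error: noise config not found: ",
                                  noise)
    noise <- read_noise_model(noise)
  }
  if (!is.null(table_path) && !file.exists(table_path)) {
    stop("validation error: table_path not found: ", table_path)
  }
  if (!"simulate" %in% stages && is.null(table_path) &&
      any(c("calibrate", "profile", "stats") %in% stages)) {
    stop("validation error: downstream stages need either 'simulate' or table_path")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = intersect(all_stages, stages), plex = as.integer(plex),
                 noise = noise, table_path = table_path),
            class = "run_config")
}

# hash of the scientific configuration (output location excluded)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  x <- unclass(config)
  x$out_dir <- NULL
  writeLines(utils::capture.output(utils::str(x)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the requested stages in order on a synthetic titration study:
#' simulate a panel and duplicate S1-S4 titration intensities, render a gel
#' image, quantify it back to a table, calibrate to absolute copies,
#' compute normalized/differential profiles and the titration-order check,
#' and summarize statistics (CVs, resolvability, error budget). Every
#' output carries the seed and a config hash; all randomness derives from
#' `config$seed`, so two invocations are bit-identical. A failing stage
#' aborts with the stage named; files written by the failing stage keep a
#' `.partial` suffix.
#'
#' @param config a [run_config()].
#' @return Invisible list of the principal in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  prov <- c(seed = as.character(config$seed), config_hash = hash,
            package = paste0("ligomir ",
                             as.character(utils::packageVersion("ligomir"))))
  out <- list(seed = config$seed, config_hash = hash)
  path_of <- function(name) file.path(config$out_dir, name)

  stage <- function(name, body) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    pending <- character(0)
    commit <- function(final) {
      pending <<- c(pending, final)
      paste0(final, ".partial")
    }
    ok <- FALSE
    tryCatch({
      body(commit)
      ok <- TRUE
    }, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    }, finally = {
      if (ok) {
        for (f in pending) file.rename(paste0(f, ".partial"), f)
      }
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }

  panel <- make_default_panel(config$plex, seed = config$seed)
  design <- titration_design()
  noise <- config$noise

  stage("simulate", function(commit) {
    truth <- titration_truth(panel, design)
    amounts <- make_titration_samples(design, truth$s1, truth$s2)
    amounts <- amounts[, c("S1", "S2", "S3", "S4"), drop = FALSE]
    amounts <- amounts[, rep(1:4, each = 2)]
    colnames(amounts) <- paste0(rep(c("S1", "S2", "S3", "S4"), each = 2))
    sheet <- sample_sheet(colnames(amounts),
                          replicate_id = rep(1:2, times = 4))
    tab <- simulate_intensities(amounts, panel, noise, sheet,
                                seed = config$seed)
    out$panel <<- panel
    out$sheet <<- sheet
    out$table <<- tab
    write_panel(panel, commit(path_of("panel.json")))
    write_sample_sheet(sheet, commit(path_of("sheet.json")))
    write_noise_model(noise, commit(path_of("noise.json")))
    write_intensity_table(tab, commit(path_of("table.tsv")), prov)
  })

  if (!is.null(config$table_path) && !"simulate" %in% config$stages) {
    out$table <- read_intensity_table(config$table_path)
  }

  stage("render", function(commit) {
    img <- render_gel(out$table, panel, seed = config$seed)
    out$image <<- img
    write_gel_tiff(img, commit(path_of("gel.tif")))
  })

  stage("quantify", function(commit) {
    tab <- quantify_gel(out$image, out$sheet, panel)
    out$quantified <<- tab
    write_intensity_table(tab, commit(path_of("quantified.tsv")), prov)
  })

  stage("calibrate", function(commit) {
    spike_ids <- panel_targets(panel, c("spike_in_pellet",
                                        "spike_in_mastermix"))
    if (length(spike_ids) == 0L) {
      stop("pre-flight: panel has no spike-ins for copy-number mode")
    }
    bias <- attr(out$table, "capture_bias")
    ref_int <- vapply(spike_ids, function(id) {
      row <- panel[panel$mirna_id == id, ]
      expected_intensity(1000, row$response_factor, noise,
                         bias = if (row$role == "spike_in_pellet")
                           bias[[id]] else 1,
                         capture = row$role == "spike_in_pellet")
    }, numeric(1))
    spikes <- spike_in_set(spike_ids,
                           ifelse(grepl("pellet",
                                        panel$role[match(spike_ids,
                                                         panel$mirna_id)]),
                                  "cell_pellet", "mastermix"),
                           1000, ref_int)
    std_amounts <- c(15, 150, 1500, 15000)
    curves <- lapply(panel_targets(panel, c("target", "reference")),
                     function(id) {
      std <- simulate_intensities(
        matrix(std_amounts, nrow = 1, dimnames = list(id, NULL),
               ncol = 4), panel,
        noise_model(cv_intraday_raw = noise$cv_intraday_norm,
                    scanner_drift_sd = 0, capture_bias_cv = 0),
        sample_sheet(paste0("std", 1:4)),
        seed = config$seed + match(id, panel$mirna_id))
      fit_standard_curve(std_amounts, std$intensity[std$mirna_id == id], id)
    })
    names(curves) <- panel_targets(panel, c("target", "reference"))
    sheet_cells <- sample_sheet(unique(out$table$sample_id),
                                input_type = "cells", input_amount = 10000)
    profile <- compute_copy_profile(out$table, spikes, curves, sheet_cells)
    out$curves <<- curves
    out$copy_profile <<- profile
    utils::write.table(as.data.frame(profile),
                       commit(path_of("copy_profile.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("profile", function(commit) {
    tab <- out$table
    per_sample <- function(s) {
      sub <- tab[tab$sample_id == s, ]
      tapply(sub$intensity, sub$mirna_id, mean)
    }
    ref <- intersect("RNU44", panel$mirna_id)
    v1 <- per_sample("S1")
    v2 <- per_sample("S2")
    scheme <- if (length(ref) == 1L) "reference_gene" else "raw"
    p1 <- normalize_profile(v1, panel, scheme, ref_id = ref, sample_id = "S1")
    p2 <- normalize_profile(v2, panel, scheme, ref_id = ref, sample_id = "S2")
    diffres <- differential(p2, p1)
    order_check <- titration_order_check(tab, panel = panel)
    out$differential <<- diffres
    out$titration <<- order_check
    utils::write.table(as.data.frame(diffres),
                       commit(path_of("differential.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("stats", function(commit) {
    tab <- out$table
    cvres <- cv_summary(tab[tab$sample_id == unique(tab$sample_id)[1], ])
    stats_out <- list(
      seed = config$seed, config_hash = hash,
      mean_intraday_cv = cvres$mean_cv,
      resolvability_p_114 = resolvability_pvalue(1.14, 0.058, 2),
      certainty_114 = resolvability_certainty(1.14, 0.058, 2),
      copy_error_p99 = copy_error_interval(c(0.12, 0.12), 99, 1e5,
                                           seed = config$seed),
      titration_fraction_correct = out$titration$fraction_correct %||% NA)
    out$stats <<- stats_out
    jsonlite::write_json(stats_out, commit(path_of("stats.json")),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(out)
}
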