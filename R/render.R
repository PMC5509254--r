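#' Gel rendering configuration
#'
#' Forward-model parameters for drawing a synthetic PAGE image from an
#' intensity table. Coordinates follow gel convention: row 1 is the well
#' edge, migration increases with row index, lanes are column bands. Band
#' centers follow the standard denaturing-PAGE migration model, linear in
#' log10 of product length with a strictly negative slope (longer products
#' migrate less and sit nearer the wells).
#'
#' @param height,width image size in pixels (width defaulted from lanes).
#' @param n_lanes total physical lanes including the ladder lane.
#' @param bit_depth 8 or 16.
#' @param band_sigma Gaussian band SD along the migration axis (pixels).
#' @param lane_width,lane_gap lane geometry (pixels).
#' @param baseline_level,baseline_slope additive background model
#'   (counts; level + slope * row).
#' @param migration_intercept,migration_slope band center row =
#'   intercept + slope * log10(length); slope must be negative. When `NULL`
#'   they are fitted so `length_range` spans rows 0.1 to 0.9 of the height.
#' @param length_range numeric `c(min, max)` product lengths (nt) the image
#'   must accommodate.
#' @param ladder_lane physical lane index holding the sizing ladder
#'   (default: last lane).
#' @param ladder_lengths known ladder product lengths (nt).
#' @param ladder_volume integrated counts per ladder band.
#' @param counts_per_unit image counts per intensity unit (default 1).
#' @param shot_factor,read_noise_sd pixel noise model: SD =
#'   sqrt(shot_factor * signal + read_noise_sd^2).
#' @return Object of class `gel_render_config`.
#' @export
gel_render_config <- function(height = 700, width = NULL, n_lanes = 11,
                              bit_depth = 16, band_sigma = 1.5,
                              lane_width = 12, lane_gap = 8,
                              baseline_level = 50, baseline_slope = 0.02,
                              migration_intercept = NULL,
                              migration_slope = NULL,
                              length_range = c(40, 140),
                              ladder_lane = n_lanes,
                              ladder_lengths = NULL,
                              ladder_volume = 5e4,
                              counts_per_unit = 1,
                              shot_factor = 0.5, read_noise_sd = 2) {
  if (!bit_depth %in% c(8, 16)) stop("gel_render_config: bit_depth must be 8 or 16")
  if (band_sigma <= 0) stop("gel_render_config: band_sigma must be > 0")
  if (is.null(width)) width <- n_lanes * (lane_width + lane_gap) + lane_gap
  if (is.null(migration_slope) || is.null(migration_intercept)) {
    lr <- log10(range(length_range))
    migration_slope <- (0.1 * height - 0.9 * height) / (lr[2] - lr[1])
    migration_intercept <- 0.9 * height - migration_slope * lr[1]
  }
  if (migration_slope >= 0) {
    stop("gel_render_config: migration mapping must be strictly decreasing in length")
  }
  if (is.null(ladder_lengths)) {
    ladder_lengths <- round(10^seq(log10(length_range[1]),
                                   log10(length_range[2]), length.out = 8))
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_lanes = as.integer(n_lanes), bit_depth = as.integer(bit_depth),
                 band_sigma = band_sigma, lane_width = as.integer(lane_width),
                 lane_gap = as.integer(lane_gap),
                 baseline_level = baseline_level,
                 baseline_slope = baseline_slope,
                 migration_intercept = migration_intercept,
                 migration_slope = migration_slope,
                 length_range = length_range,
                 ladder_lane = as.integer(ladder_lane),
                 ladder_lengths = ladder_lengths,
                 ladder_volume = ladder_volume,
                 counts_per_unit = counts_per_unit,
                 shot_factor = shot_factor,
                 read_noise_sd = read_noise_sd),
            class = "gel_render_config")
}

# half-open [start, stop) column interval of a physical lane
lane_columns <- function(cfg, k) {
  start <- cfg$lane_gap + (k - 1L) * (cfg$lane_width + cfg$lane_gap) + 1L
  seq.int(start, start + cfg$lane_width - 1L)
}

# band center row for a product length
migration_row <- function(cfg, length_nt) {
  cfg$migration_intercept + cfg$migration_slope * log10(length_nt)
}

#' Render an intensity table as a synthetic gel image
#'
#' Each band is drawn as a Gaussian profile along the migration axis at the
#' row given by the migration model, spread uniformly across its lane's
#' columns, with integrated volume `intensity * counts_per_unit`. An
#' additive sloped baseline and shot-like pixel noise are applied, and the
#' image is clipped to the bit depth. The ladder lane is rendered from the
#' config's known lengths.
#'
#' @param table an [intensity_table()] whose `lane` column gives physical
#'   lane indices (must not collide with the ladder lane).
#' @param panel a [panel_design()] supplying product lengths.
#' @param cfg a [gel_render_config()].
#' @param seed integer seed for pixel noise.
#' @return Object of class `gel_image`: an integer matrix (rows = migration
#'   axis) with attributes `bit_depth`, `config`, `seed`.
#' @export
render_gel <- function(table, panel, cfg = NULL, seed = 1L) {
  stopifnot(inherits(panel, "panel_design"))
  if (is.null(cfg)) {
    n_sample_lanes <- if (nrow(table) > 0) max(table$lane) else 0L
    cfg <- gel_render_config(
      n_lanes = n_sample_lanes + 1L,
      length_range = range(panel$product_length) + c(-2, 2),
      ladder_lengths = panel$product_length)
  }
  unknown <- setdiff(unique(table$mirna_id), panel$mirna_id)
  if (length(unknown) > 0L) {
    stop("render error: species without panel lengths: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(table) > 0 && any(table$lane == cfg$ladder_lane)) {
    stop("render error: sample lane collides with ladder lane ",
         cfg$ladder_lane)
  }
  if (nrow(table) > 0 && max(table$lane) > cfg$n_lanes) {
    stop("render error: lane index exceeds configured lane count")
  }

  lens <- c(panel$product_length[match(table$mirna_id, panel$mirna_id)],
            cfg$ladder_lengths)
  rows_c <- migration_row(cfg, lens)
  bad <- lens[rows_c < 1 | rows_c > cfg$height]
  if (length(bad) > 0L) {
    stop("render error: band positions outside image for lengths ",
         paste(unique(bad), collapse = ", "))
  }

  img <- matrix(cfg$baseline_level + cfg$baseline_slope * seq_len(cfg$height),
                nrow = cfg$height, ncol = cfg$width)
  r <- seq_len(cfg$height)
  add_band <- function(img, lane, row_c, volume) {
    profile <- volume / cfg$lane_width * stats::dnorm(r, row_c, cfg$band_sigma)
    img[, lane_columns(cfg, lane)] <-
      img[, lane_columns(cfg, lane)] + profile
    img
  }
  if (nrow(table) > 0) {
    for (i in seq_len(nrow(table))) {
      img <- add_band(img, table$lane[i], rows_c[i],
                      table$intensity[i] * cfg$counts_per_unit)
    }
  }
  for (len in cfg$ladder_lengths) {
    img <- add_band(img, cfg$ladder_lane, migration_row(cfg, len),
                    cfg$ladder_volume)
  }

  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  sd_pix <- sqrt(cfg$shot_factor * pmax(img, 0) + cfg$read_noise_sd^2)
  img <- img + stats::rnorm(length(img), 0, sd_pix)
  ceiling_val <- 2^cfg$bit_depth - 1
  img <- round(pmin(pmax(img, 0), ceiling_val))
  structure(img, class = "gel_image", bit_depth = cfg$bit_depth,
            config = cfg, seed = as.integer(seed))
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("gel_image: %d x %d px, %d-bit, range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "bit_depth"),
              min(x), max(x)))
  invisible(x)
}
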