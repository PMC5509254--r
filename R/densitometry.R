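#' Segment gel lanes from the column-intensity profile
#'
#' Lanes are located from the image's summed column profile. Occupied lanes
#' appear as runs of columns above a threshold between the inter-lane
#' baseline and the lane level. Without `n_expected` only those occupied
#' runs are returned. With `n_expected`, the column axis is split at the
#' valleys between lane centers into exactly `n_expected` segments; when
#' fewer occupied runs are found than expected (blank lanes), lane centers
#' are inferred on the regular lane pitch fitted from the detected runs.
#'
#' @param image a [gel_image()] or numeric matrix (rows = migration axis).
#' @param n_expected optional expected lane count.
#' @return Object of class `lane_segmentation`: data.frame with `lane`,
#'   `start`, `stop` (half-open pixel column intervals, ordered left to
#'   right), with the column profile as attribute `profile`.
#' @export
detect_lanes <- function(image, n_expected = NULL) {
  if (length(image) == 0L) stop("detect_lanes: empty image")
  p <- colSums(image)
  width <- length(p)
  sp <- running_mean(p, 5L)
  noise <- stats::mad(diff(p)) / sqrt(2)   # per-column profile noise
  # elevation above the inter-lane baseline; the rolling-min window must
  # exceed the lane pitch so it reaches a gap from inside any lane
  w_base <- max(9L, if (is.null(n_expected)) width %/% 4L
                else min(width, 3L * width %/% (2L * n_expected)))
  elev <- sp - running_mean(running_min(sp, w_base), w_base)
  thr <- 4 * max(noise, .Machine$double.eps)
  blank <- max(elev) < thr

  as_seg <- function(starts, stops) {
    structure(data.frame(lane = seq_along(starts),
                         start = as.integer(starts),
                         stop = as.integer(stops)),
              class = c("lane_segmentation", "data.frame"), profile = p)
  }

  runs_df <- function() {
    runs <- rle(elev > thr)
    stops_all <- cumsum(runs$lengths)
    starts_all <- stops_all - runs$lengths + 1L
    keep <- runs$values & runs$lengths >= 3L
    data.frame(start = starts_all[keep], stop = stops_all[keep] + 1L,
               center = vapply(which(keep), function(k) {
                 cols <- (stops_all[k] - runs$lengths[k] + 1L):stops_all[k]
                 sum(cols * elev[cols]) / sum(elev[cols])
               }, numeric(1)),
               strength = vapply(which(keep), function(k)
                 max(elev[(stops_all[k] - runs$lengths[k] + 1L):stops_all[k]]),
                 numeric(1)))
  }

  if (is.null(n_expected)) {
    if (blank) return(as_seg(integer(0), integer(0)))
    r <- runs_df()
    return(as_seg(r$start, r$stop))
  }

  n_expected <- as.integer(n_expected)
  if (n_expected < 1L) stop("detect_lanes: n_expected must be >= 1")
  if (n_expected == 1L) return(as_seg(1L, width + 1L))
  if (blank) {
    stop("segmentation error: no lane structure detected (profile attached)")
  }
  r <- runs_df()
  centers <- r$center
  if (nrow(r) > n_expected) {
    centers <- sort(r$center[order(-r$strength)][seq_len(n_expected)])
  } else if (nrow(r) < n_expected) {
    if (nrow(r) < 2L) {
      stop(sprintf(
        "segmentation error: found %d lane run(s), need %d (profile attached)",
        nrow(r), n_expected))
    }
    # infer missing (blank) lanes on the regular lane pitch
    pitch <- min(diff(centers))
    idx <- round((centers - centers[1]) / pitch)
    if (max(idx) > 0) pitch <- (centers[length(centers)] - centers[1]) / max(idx)
    offset <- mean(centers - idx * pitch)
    kmin <- ceiling((1 - offset) / pitch)
    kmax <- floor((width - offset) / pitch)
    if (kmax - kmin + 1L < n_expected) {
      stop("segmentation error: lane pitch does not admit ", n_expected,
           " lanes (profile attached)")
    }
    # window of n_expected grid slots covering the observed lanes
    lo <- min(max(kmin, max(idx) - n_expected + 1L), 0L)
    lo <- max(lo, kmax - n_expected + 1L - (kmax - max(idx)))
    lo <- max(kmin, min(lo, 0L))
    while (lo + n_expected - 1L > kmax) lo <- lo - 1L
    if (lo < kmin) {
      stop("segmentation error: cannot place ", n_expected,
           " lanes on the fitted pitch (profile attached)")
    }
    centers <- offset + (lo:(lo + n_expected - 1L)) * pitch
  }
  cuts <- round((centers[-1] + centers[-length(centers)]) / 2)
  as_seg(c(1L, cuts + 1L), c(cuts + 1L, width + 1L))
}

# centered running mean / minimum with edge truncation
running_mean <- function(x, w) {
  h <- w %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) mean(x[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}

running_min <- function(x, w) {
  h <- w %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) min(x[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}

#' Extract a lane's migration profile
#'
#' @param image matrix (rows = migration axis).
#' @param seg a `lane_segmentation`.
#' @param lane lane index.
#' @return Numeric vector: summed intensity per row over the lane's columns.
#' @export
lane_profile <- function(image, seg, lane) {
  row <- seg[seg$lane == lane, ]
  if (nrow(row) != 1L) stop("lane_profile: unknown lane ", lane)
  rowSums(image[, row$start:(row$stop - 1L), drop = FALSE])
}

#' Rolling-minimum background subtraction
#'
#' Estimates the baseline of a 1-D lane profile as a rolling minimum
#' followed by rolling-mean smoothing. Because a rolling minimum of a noisy
#' profile sits systematically below the true baseline (by roughly the
#' expected minimum of the noise over the window), the estimate is then
#' re-centered by the median residual over the profile, which is dominated
#' by band-free pixels. The corrected profile is clamped at zero. The
#' window must be wider than the bands so band signal is not absorbed into
#' the baseline.
#'
#' @param profile numeric migration profile.
#' @param window odd window width in pixels, `>= 3`.
#' @return Corrected profile (same length, all values `>= 0`) with the
#'   estimated baseline as attribute `baseline`.
#' @export
subtract_background <- function(profile, window = 25L) {
  window <- as.integer(window)
  if (window < 3L) stop("parameter error: window must be >= 3 pixels")
  if (window > length(profile)) {
    stop("parameter error: window larger than profile")
  }
  baseline <- running_mean(running_min(profile, window), window)
  baseline <- baseline + stats::median(profile - baseline)
  out <- pmax(profile - baseline, 0)
  attr(out, "baseline") <- baseline
  out
}

#' Detect bands in a background-subtracted lane profile
#'
#' Finds local maxima whose topographic prominence exceeds `min_snr` times a
#' robust noise estimate (MAD of the profile's first differences). Band
#' windows extend to the surrounding saddle minima; peak centers are refined
#' to sub-pixel precision by parabolic interpolation.
#'
#' @param profile background-subtracted profile.
#' @param min_snr prominence threshold as a multiple of the noise level.
#'   The default of 5 rejects pure-noise excursions, whose peak-to-saddle
#'   prominence reaches about 4 noise SDs over a gel-length profile.
#' @param saturation_ceiling optional counts level at or above which a peak
#'   is flagged saturated (per-pixel ceiling times the number of columns
#'   summed, if the profile is a column sum).
#' @return data.frame with `center`, `start`, `stop` (half-open window),
#'   `height`, `prominence`, `saturated`. Empty result is valid.
#' @export
detect_bands <- function(profile, min_snr = 5, saturation_ceiling = Inf) {
  n <- length(profile)
  empty <- data.frame(center = numeric(0), start = integer(0),
                      stop = integer(0), height = numeric(0),
                      prominence = numeric(0), saturated = logical(0))
  if (n < 3L) return(empty)
  # robust noise level; zero-clamped stretches (flat after background
  # subtraction) are excluded so they cannot deflate the estimate
  d <- diff(profile)
  noise <- stats::mad(d) / sqrt(2)
  if (noise == 0 && any(d != 0)) noise <- stats::mad(d[d != 0]) / sqrt(2)
  noise <- max(noise, .Machine$double.eps)
  i <- 2:(n - 1L)
  peaks <- i[profile[i] > profile[i - 1L] & profile[i] >= profile[i + 1L]]
  if (length(peaks) == 0L) return(empty)

  res <- lapply(peaks, function(pk) {
    h <- profile[pk]
    # walk outward to nearest higher ground; saddle = min along the way
    left <- pk
    lmin <- h
    while (left > 1L && profile[left] <= h) {
      left <- left - 1L
      lmin <- min(lmin, profile[left])
    }
    right <- pk
    rmin <- h
    while (right < n && profile[right] <= h) {
      right <- right + 1L
      rmin <- min(rmin, profile[right])
    }
    prom <- h - max(lmin, rmin)
    # window: nearest flanking local minima, stopping once the profile has
    # decayed to the noise floor (so flat stretches are not swept in)
    floor_val <- noise
    ws <- pk
    while (ws > 1L && profile[ws - 1L] <= profile[ws] &&
           profile[ws] > floor_val) ws <- ws - 1L
    we <- pk
    while (we < n && profile[we + 1L] <= profile[we] &&
           profile[we] > floor_val) we <- we + 1L
    # sub-pixel center by parabolic interpolation
    denom <- profile[pk - 1L] - 2 * profile[pk] + profile[pk + 1L]
    center <- if (denom < 0) {
      pk + 0.5 * (profile[pk - 1L] - profile[pk + 1L]) / denom
    } else pk
    # width at half prominence: single-pixel noise spikes are not bands
    half <- h - prom / 2
    wl <- pk
    while (wl > 1L && profile[wl - 1L] > half) wl <- wl - 1L
    wr <- pk
    while (wr < n && profile[wr + 1L] > half) wr <- wr + 1L
    c(center = center, start = ws, stop = we + 1L, height = h,
      prominence = prom, fwhm = wr - wl + 1L)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$start <- as.integer(out$start)
  out$stop <- as.integer(out$stop)
  out <- out[out$prominence >= min_snr * noise & out$fwhm >= 2, ,
             drop = FALSE]
  # second pass: re-estimate the noise from band-free pixels. Zero-clamped
  # profiles leave only the positive half of the noise, whose SD is
  # sqrt(1 - 2/pi) of the underlying sigma.
  if (nrow(out) > 0L) {
    mask <- rep(TRUE, n)
    for (b in seq_len(nrow(out))) mask[out$start[b]:(out$stop[b] - 1L)] <- FALSE
    resid <- profile[mask]
    rnz <- resid[resid > 0]
    if (length(rnz) >= 30L && mean(resid == 0) > 0.2) {
      noise <- max(noise, stats::sd(rnz) / sqrt(1 - 2 / pi))
      out <- out[out$prominence >= min_snr * noise, , drop = FALSE]
    }
  }
  out$fwhm <- NULL
  out$saturated <- out$height >= saturation_ceiling
  rownames(out) <- NULL
  out
}

#' Fit the ladder migration calibration
#'
#' Least-squares fit of band position against log10 of product length for
#' the sizing-ladder lane. The fitted slope must be strictly negative
#' (longer products migrate less); the fit is order-free in its inputs and
#' invertible within the ladder's length range.
#'
#' @param positions band center positions (pixels along the migration axis).
#' @param lengths known ladder product lengths (nt), same order.
#' @return Object of class `ladder_calibration` with `slope`, `intercept`,
#'   `r_squared`, `length_range`.
#' @export
calibrate_ladder <- function(positions, lengths) {
  if (length(positions) != length(lengths)) {
    stop("calibration error: positions and lengths differ in length")
  }
  if (length(positions) < 2L) {
    stop("calibration error: need >= 2 ladder bands")
  }
  if (anyDuplicated(lengths)) {
    stop("calibration error: ladder lengths must be distinct")
  }
  ord <- order(lengths)
  if (is.unsorted(rev(positions[ord]), strictly = FALSE) ||
      any(diff(positions[ord]) >= 0)) {
    stop("calibration error: positions must decrease with length")
  }
  x <- log10(lengths)
  fit <- stats::lm(positions ~ x)
  r2 <- .r_squared(fit, positions)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 length_range = range(lengths),
                 n_bands = length(positions)),
            class = "ladder_calibration")
}

#' @export
print.ladder_calibration <- function(x, ...) {
  cat(sprintf(
    "ladder_calibration: pos = %.2f %+.2f*log10(len); r2 = %.4f; %d bands, %g-%g nt\n",
    x$intercept, x$slope, x$r_squared, x$n_bands,
    x$length_range[1], x$length_range[2]))
  invisible(x)
}

#' Estimate product length from migration position
#'
#' Inverts a [calibrate_ladder()] fit.
#'
#' @param calib a `ladder_calibration`.
#' @param position pixel position(s) along the migration axis.
#' @return Estimated length(s) in nt.
#' @export
estimate_length <- function(calib, position) {
  stopifnot(inherits(calib, "ladder_calibration"))
  10^((position - calib$intercept) / calib$slope)
}

#' Assign detected bands to panel species by product length
#'
#' Each band is assigned to the panel species whose product length is
#' nearest its estimated length, if within `tolerance_nt`; otherwise it is
#' left unassigned. Equidistant ties go to the shorter length with an
#' `ambiguous_assignment` flag. If two bands claim the same species, the
#' nearer band wins and the other is unassigned and flagged.
#'
#' @param bands data.frame from [detect_bands()] (needs `center`).
#' @param calib a `ladder_calibration`.
#' @param panel a [panel_design()].
#' @param tolerance_nt maximum |estimated - panel| length difference.
#' @return `bands` with added columns `estimated_length`, `mirna_id`
#'   (NA when unassigned), and `flags`.
#' @export
assign_bands <- function(bands, calib, panel, tolerance_nt = 2) {
  stopifnot(inherits(panel, "panel_design"))
  bands$estimated_length <- estimate_length(calib, bands$center)
  bands$mirna_id <- rep(NA_character_, nrow(bands))
  bands$flags <- rep(".", nrow(bands))
  if (nrow(bands) == 0L) return(bands)
  lens <- panel$product_length
  for (b in seq_len(nrow(bands))) {
    d <- abs(lens - bands$estimated_length[b])
    best <- min(d)
    if (best > tolerance_nt) next
    hits <- which(d == best)
    if (length(hits) > 1L) {
      hits <- hits[which.min(lens[hits])]      # tie-break: shorter length
      bands$flags[b] <- add_flag(bands$flags[b], "ambiguous_assignment")
    }
    bands$mirna_id[b] <- panel$mirna_id[hits]
  }
  # duplicate claims: nearer band keeps the species
  for (id in unique(stats::na.omit(bands$mirna_id))) {
    claim <- which(bands$mirna_id %in% id)
    if (length(claim) > 1L) {
      len <- panel$product_length[panel$mirna_id == id]
      d <- abs(bands$estimated_length[claim] - len)
      losers <- claim[-which.min(d)]
      bands$mirna_id[losers] <- NA_character_
      bands$flags[losers] <- vapply(bands$flags[losers], add_flag,
                                    character(1), "ambiguous_assignment")
    }
  }
  bands
}

add_flag <- function(flags, flag) {
  existing <- setdiff(strsplit(flags, ";", fixed = TRUE)[[1]], ".")
  paste(unique(c(existing, flag)), collapse = ";")
}

#' Quantify a gel image into an intensity table
#'
#' Composition of the densitometry operators: lane segmentation (sample
#' lanes plus one ladder lane), per-lane background subtraction, band
#' detection, ladder migration calibration, length-based assignment to panel
#' species, and band integration (sum of the background-subtracted profile
#' over each band window — area, not peak height). Panel species with no
#' detected band are reported at intensity 0 with a `low_snr` flag;
#' saturated bands keep their integrated value and carry a `saturated` flag.
#'
#' @param image a [gel_image()] or numeric matrix.
#' @param sheet a [sample_sheet()]; its `lane` column gives physical lane
#'   indices.
#' @param panel a [panel_design()].
#' @param ladder_lane physical index of the ladder lane (default: one past
#'   the last sample lane).
#' @param ladder_lengths known ladder lengths (default: panel lengths).
#' @param min_snr band-detection prominence threshold.
#' @param tolerance_nt assignment tolerance.
#' @param window background-subtraction window (pixels).
#' @param counts_per_unit image counts per intensity unit (default 1).
#' @return An [intensity_table()] with the detected-band table as attribute
#'   `bands` and the ladder fit as attribute `calibration`.
#' @export
quantify_gel <- function(image, sheet, panel,
                         ladder_lane = max(sheet$lane) + 1L,
                         ladder_lengths = panel$product_length,
                         min_snr = 5, tolerance_nt = 2, window = 25L,
                         counts_per_unit = 1) {
  stopifnot(inherits(panel, "panel_design"))
  n_lanes <- max(c(sheet$lane, ladder_lane))
  seg <- detect_lanes(image, n_expected = n_lanes)
  if (nrow(seg) != n_lanes) {
    stop("layout error: detected ", nrow(seg), " lanes, sheet needs ", n_lanes)
  }
  bit_depth <- attr(image, "bit_depth")
  pixel_ceiling <- if (is.null(bit_depth)) Inf else 2^bit_depth - 1

  # ladder calibration
  lp <- subtract_background(lane_profile(image, seg, ladder_lane), window)
  lb <- detect_bands(lp, min_snr)
  if (nrow(lb) < length(ladder_lengths)) {
    stop("calibration error: only ", nrow(lb), " ladder bands detected, need ",
         length(ladder_lengths))
  }
  lb <- lb[order(-lb$prominence), ][seq_along(ladder_lengths), ]
  lb <- lb[order(lb$center), ]
  calib <- calibrate_ladder(lb$center, sort(ladder_lengths, decreasing = TRUE))

  rows <- vector("list", nrow(sheet))
  all_bands <- vector("list", nrow(sheet))
  for (s in seq_len(nrow(sheet))) {
    lane <- sheet$lane[s]
    raw <- lane_profile(image, seg, lane)
    seg_row <- seg[seg$lane == lane, ]
    n_cols <- seg_row$stop - seg_row$start
    prof <- subtract_background(raw, window)
    bands <- detect_bands(prof, min_snr)
    if (nrow(bands) > 0L) {
      # saturation is a per-pixel property: inspect the raw band windows
      bands$saturated <- vapply(seq_len(nrow(bands)), function(b)
        max(image[bands$start[b]:(bands$stop[b] - 1L),
                  seg_row$start:(seg_row$stop - 1L)]) >=
          pixel_ceiling * 0.999, logical(1))
    }
    bands <- assign_bands(bands, calib, panel, tolerance_nt)
    bands$intensity <- vapply(seq_len(nrow(bands)), function(b)
      sum(prof[bands$start[b]:(bands$stop[b] - 1L)]), numeric(1)) /
      counts_per_unit
    bands$lane <- rep(lane, nrow(bands))
    all_bands[[s]] <- bands

    inten <- stats::setNames(rep(0, nrow(panel)), panel$mirna_id)
    flags <- stats::setNames(rep("low_snr", nrow(panel)), panel$mirna_id)
    hit <- !is.na(bands$mirna_id)
    inten[bands$mirna_id[hit]] <- bands$intensity[hit]
    flags[bands$mirna_id[hit]] <- mapply(function(f, sat)
      if (sat) add_flag(f, "saturated") else f,
      bands$flags[hit], bands$saturated[hit])
    rows[[s]] <- intensity_table(sheet$gel_id[s], lane, sheet$sample_id[s],
                                 panel$mirna_id, unname(inten), unname(flags))
  }
  out <- do.call(rbind, rows)
  out <- structure(out, class = c("intensity_table", "data.frame"))
  attr(out, "bands") <- do.call(rbind, all_bands)
  attr(out, "calibration") <- calib
  out
}
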