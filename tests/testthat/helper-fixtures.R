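# Shared fixtures: small panels and noise models used across test files.

quiet_noise <- function(...) {
  noise_model(cv_intraday_raw = 0, capture_bias_cv = 0, scanner_drift_sd = 0,
              ...)
}

# equal-response panel for specificity-style tests (no per-probe yield spread)
flat_panel <- function(ids, roles = "target") {
  panel_design(data.frame(
    mirna_id = ids,
    product_length = 40L + 4L * (seq_along(ids) - 1L),
    role = rep_len(roles, length(ids)),
    response_factor = 1,
    stringsAsFactors = FALSE))
}

# replicate simulation at a constant amount per measured species
# (spike-ins enter at their own known amount via simulate_intensities)
replicate_table <- function(panel, amount, n_rep, noise, seed = 1L,
                            gel_id = NULL) {
  ids <- panel_targets(panel, c("target", "reference"))
  if (length(ids) == 0L) ids <- panel$mirna_id
  amt <- matrix(amount, nrow = length(ids), ncol = n_rep,
                dimnames = list(ids, paste0("rep", seq_len(n_rep))))
  sheet <- sample_sheet(colnames(amt),
                        gel_id = gel_id %||% "gel1",
                        replicate_id = seq_len(n_rep))
  simulate_intensities(amt, panel, noise, sheet, seed = seed)
}

# reference spike-in set matching a panel's expected (undrifted) intensities
panel_spikes <- function(panel, noise, table, spike_amol = 1000) {
  spike_ids <- panel_targets(panel, c("spike_in_pellet", "spike_in_mastermix"))
  bias <- attr(table, "capture_bias")
  ref_int <- vapply(spike_ids, function(id) {
    row <- panel[panel$mirna_id == id, ]
    expected_intensity(spike_amol, row$response_factor, noise,
                       bias = if (row$role == "spike_in_pellet" &&
                                  !is.null(bias)) bias[[id]] else 1,
                       capture = row$role == "spike_in_pellet")
  }, numeric(1))
  spike_in_set(spike_ids,
               ifelse(panel$role[match(spike_ids, panel$mirna_id)] ==
                        "spike_in_pellet", "cell_pellet", "mastermix"),
               spike_amol, ref_int)
}

# noise-free standard curves reproducing a panel's full signal chain
panel_curves <- function(panel, ids = panel_targets(panel,
                                                    c("target", "reference")),
                         noise = quiet_noise(), seed = 99L,
                         std_amounts = c(15, 150, 1500, 15000)) {
  curves <- lapply(ids, function(id) {
    std <- simulate_intensities(
      matrix(std_amounts, nrow = 1, ncol = length(std_amounts),
             dimnames = list(id, NULL)),
      panel, noise, sample_sheet(paste0("std", seq_along(std_amounts))),
      seed = seed + match(id, panel$mirna_id))
    fit_standard_curve(std_amounts, std$intensity[std$mirna_id == id], id)
  })
  stats::setNames(curves, ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
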