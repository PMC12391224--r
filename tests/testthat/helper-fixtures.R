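# Shared in-code fixtures for fast unit tests. Study-scale (48 h, 1 Hz)
# checks live in test-acceptance.R; everything here runs on reduced grids.

# Two-column mini cartridge: refs in rows A and F, samples in B and C.
mini_layout <- function() {
  plate_layout(data.frame(
    well_id = c("A1", "B1", "C1", "F1", "A2", "B2", "C2", "F2"),
    role = rep(c("reference", "sample", "sample", "reference"), 2),
    group = c(NA, "fast", "fast", NA, NA, "slow", "slow", NA),
    cells = c(0, 2e5, 2e5, 0, 0, 2e5, 2e5, 0)
  ))
}

# Kinetics compressed into a 2-h run so pipelines finish in milliseconds.
mini_profiles <- function() {
  list(
    fast = kinetic_profile(lag_s = 2000, rise_tau_s = 300,
                           peak_pW_per_cell = 50,
                           exhaustion_s = 5000, exhaustion_tau_s = 400),
    slow = kinetic_profile(lag_s = 2500, rise_tau_s = 600,
                           peak_pW_per_cell = 30)
  )
}

mini_pipeline_config <- function(...) {
  pipeline_config(trim_start_s = 100, quiescent_window = c(300, 1500),
                  smoothing_halfwidth_s = 30, ...)
}

mini_sim_config <- function(...) {
  defaults <- list(
    layout = mini_layout(), profiles = mini_profiles(),
    duration_s = 7200, sampling_rate_hz = 1, seed = 1L,
    spike_uW = 10, spike_tau_s = 200
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# A corrected_signal at a chosen stage from time/power vectors.
signal_at <- function(time_s, power_uW, stage, well_id = "B1") {
  as_corrected_signal(data.frame(time_s = time_s, power_uW = power_uW),
                      well_id = well_id, stage = stage)
}

# Fabricate a pairwise_comparisons object from a logical significance matrix
# (upper triangle), for compact-letter property tests.
fake_comparisons <- function(sig, groups = NULL) {
  k <- nrow(sig)
  groups <- groups %||% paste0("g", seq_len(k))
  idx <- utils::combn(k, 2)
  rows <- tibble::tibble(
    group1 = groups[idx[1, ]], group2 = groups[idx[2, ]],
    estimate = 0, std_error = 1, df = 10, statistic = 0,
    adj_p_value = ifelse(sig[t(idx)], 0.01, 0.5),
    significant = sig[t(idx)]
  )
  structure(rows,
    class = c("pairwise_comparisons", class(tibble::tibble())),
    alpha = 0.05, groups = groups
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Check the compact-letter contract: groups share a letter iff their pair is
# not significant.
cld_invariant_holds <- function(cld, comparisons) {
  shared <- function(a, b) {
    la <- strsplit(cld$letters[cld$group == a], "")[[1]]
    lb <- strsplit(cld$letters[cld$group == b], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  all(vapply(seq_len(nrow(comparisons)), function(i) {
    shared(comparisons$group1[i], comparisons$group2[i]) ==
      !comparisons$significant[i]
  }, logical(1)))
}
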