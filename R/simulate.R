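#' Parametric per-cell heat kinetics
#'
#' A phenomenological per-cell power curve with the features seen in
#' chondrocyte thermograms: a metabolically silent lag (cells acclimating
#' after encapsulation, typically 12-24 h), a saturating exponential rise
#' toward a per-cell peak, and either a hold at the peak for the rest of the
#' run (externally fed cells) or an exponential decay once intracellular
#' fuel is exhausted.
#'
#' @param lag_s Lag before any heat is produced, seconds.
#' @param rise_tau_s Time constant of the saturating rise, seconds (> 0).
#' @param peak_pW_per_cell Asymptotic per-cell power, pW/cell (0-100;
#'   mammalian cells are typically 4-50 pW/cell).
#' @param exhaustion_s Optional time at which fuel runs out and power decays
#'   exponentially; `NULL` (default) holds the plateau.
#' @param exhaustion_tau_s Decay time constant after exhaustion, seconds.
#' @return A list of class `kinetic_profile`.
#' @examples
#' kinetic_profile(lag_s = 12 * 3600, rise_tau_s = 2 * 3600,
#'                 peak_pW_per_cell = 48, exhaustion_s = 32 * 3600)
#' @export
kinetic_profile <- function(lag_s = 13 * 3600,
                            rise_tau_s = 4 * 3600,
                            peak_pW_per_cell = 30,
                            exhaustion_s = NULL,
                            exhaustion_tau_s = 4 * 3600) {
  stopifnot(
    is.numeric(lag_s), lag_s >= 0,
    is.numeric(rise_tau_s), rise_tau_s > 0,
    is.numeric(exhaustion_tau_s), exhaustion_tau_s > 0,
    is.null(exhaustion_s) || (is.numeric(exhaustion_s) && exhaustion_s > lag_s)
  )
  if (peak_pW_per_cell < 0 || peak_pW_per_cell > 100) {
    stop("peak_pW_per_cell must be within [0, 100]", call. = FALSE)
  }
  structure(
    list(lag_s = lag_s, rise_tau_s = rise_tau_s,
         peak_pW_per_cell = peak_pW_per_cell,
         exhaustion_s = exhaustion_s, exhaustion_tau_s = exhaustion_tau_s,
         hold = is.null(exhaustion_s)),
    class = "kinetic_profile"
  )
}

#' Metabolic power of a well at given times
#'
#' Deterministic evaluation of a [kinetic_profile()]: zero during the lag,
#' `peak * (1 - exp(-(t - lag)/rise_tau))` during the rise (per cell), and an
#' exponential decay after exhaustion when one is set. Per-cell pW are scaled
#' by the cell count and converted to µW.
#'
#' @param profile A [kinetic_profile()].
#' @param t Time(s) from the start of recording, seconds (vectorized).
#' @param cell_count Number of cells in the well.
#' @return Power in µW, same length as `t`.
#' @export
metabolic_power <- function(profile, t, cell_count) {
  stopifnot(inherits(profile, "kinetic_profile"), all(t >= 0),
            cell_count >= 0)
  amp <- profile$peak_pW_per_cell * 1e-6 * cell_count  # pW/cell -> µW total
  p <- numeric(length(t))
  rising <- t >= profile$lag_s
  if (!is.null(profile$exhaustion_s)) {
    rising <- rising & t < profile$exhaustion_s
    decaying <- t >= profile$exhaustion_s
    p_ex <- amp * (1 - exp(-(profile$exhaustion_s - profile$lag_s) /
                             profile$rise_tau_s))
    p[decaying] <- p_ex *
      exp(-(t[decaying] - profile$exhaustion_s) / profile$exhaustion_tau_s)
  }
  p[rising] <- amp * (1 - exp(-(t[rising] - profile$lag_s) /
                                profile$rise_tau_s))
  p
}

#' Closed-form total metabolic heat of a profile
#'
#' Analytic integral of [metabolic_power()] over `[0, duration_s]`; the
#' simulator's ground truth and the oracle for pipeline recovery tests.
#'
#' @inheritParams metabolic_power
#' @param duration_s Length of the run, seconds.
#' @return Total heat in µJ.
#' @export
expected_total_heat <- function(profile, cell_count, duration_s) {
  stopifnot(inherits(profile, "kinetic_profile"), duration_s >= 0,
            cell_count >= 0)
  amp <- profile$peak_pW_per_cell * 1e-6 * cell_count
  lag <- profile$lag_s
  tau <- profile$rise_tau_s
  if (duration_s <= lag || amp == 0) return(0)
  t1 <- if (is.null(profile$exhaustion_s)) duration_s else {
    min(profile$exhaustion_s, duration_s)
  }
  rise_heat <- amp * ((t1 - lag) - tau * (1 - exp(-(t1 - lag) / tau)))
  decay_heat <- 0
  if (!is.null(profile$exhaustion_s) && duration_s > profile$exhaustion_s) {
    p_ex <- amp * (1 - exp(-(profile$exhaustion_s - lag) / tau))
    td <- profile$exhaustion_tau_s
    decay_heat <- p_ex * td *
      (1 - exp(-(duration_s - profile$exhaustion_s) / td))
  }
  rise_heat + decay_heat
}

#' Default group kinetics for the 4-group chondrocyte layout
#'
#' Approximate study conditions: cell-free wells produce nothing; cells in
#' plain PBS burn intracellular stores (peak ~48 pW/cell, onset ~12 h,
#' exhaustion ~32 h); glucose- and glutamine-fed cells rise later and more
#' slowly, peaking near the 38-h mark and holding to the end of the run, with
#' the glucose profile the hotter of the two.
#'
#' @return Named list of [kinetic_profile()]s keyed by the groups of
#'   [default_layout()].
#' @export
default_profiles <- function() {
  list(
    "No Cells" = kinetic_profile(peak_pW_per_cell = 0),
    "Cells Only" = kinetic_profile(
      lag_s = 12 * 3600, rise_tau_s = 2 * 3600, peak_pW_per_cell = 48,
      exhaustion_s = 32 * 3600, exhaustion_tau_s = 4 * 3600
    ),
    "Cells + Glucose" = kinetic_profile(
      lag_s = 13 * 3600, rise_tau_s = 8 * 3600, peak_pW_per_cell = 30
    ),
    "Cells + Glutamine" = kinetic_profile(
      lag_s = 13 * 3600, rise_tau_s = 8 * 3600, peak_pW_per_cell = 20
    )
  )
}

#' Rescale profile peaks so per-cell totals hit target means
#'
#' [expected_total_heat()] is linear in the per-cell peak, so each profile's
#' peak is rescaled in closed form until its per-cell integral over the run
#' equals the requested target. Useful for closed-loop validation against a
#' published heat table.
#'
#' @param targets_uJ_per_cell Named numeric vector of per-cell totals
#'   (µJ/cell) keyed by group.
#' @param profiles Base profiles supplying the kinetic shape; defaults to
#'   [default_profiles()].
#' @param cell_count Cells per well the targets refer to.
#' @param duration_s Run length, seconds.
#' @return Named list of rescaled [kinetic_profile()]s.
#' @export
profiles_matching_means <- function(targets_uJ_per_cell,
                                    profiles = default_profiles(),
                                    cell_count = 150000,
                                    duration_s = 172800) {
  stopifnot(!is.null(names(targets_uJ_per_cell)),
            all(names(targets_uJ_per_cell) %in% names(profiles)))
  purrr::imap(targets_uJ_per_cell, function(target, grp) {
    p <- profiles[[grp]]
    p$peak_pW_per_cell <- 1
    unit_heat <- expected_total_heat(p, cell_count, duration_s) / cell_count
    if (unit_heat <= 0 && target > 0) {
      stop("profile for group '", grp,
           "' produces no heat; cannot match a positive target",
           call. = FALSE)
    }
    p$peak_pW_per_cell <- if (target == 0) 0 else target / unit_heat
    p
  })
}

#' Simulation configuration for a full cartridge
#'
#' Defines the study conditions emulated by the generator: 48 wells sampled
#' at 1 Hz for 48 h; a common loading-friction spike decaying over the first
#' hour; a slow common instrument drift shared by every well of a column
#' (removed exactly by reference subtraction); a smaller residual drift of
#' the sample channels relative to their column references (what the
#' pipeline's column-wise baseline correction must remove); per-well constant
#' offsets; additive i.i.d. Gaussian noise; and per-well lognormal
#' variability of the kinetic peak reproducing the within-group spread of
#' replicate gels.
#'
#' @param layout A [plate_layout()].
#' @param profiles Named list of [kinetic_profile()]s covering every sample
#'   group in the layout.
#' @param drift_uW_per_h Residual sample-channel drift rate relative to the
#'   column references (µW/h; scalar or one value per column).
#' @param common_drift_uW_per_h Instrument drift common to all wells of a
#'   column (µW/h); cancels at reference subtraction.
#' @param offset_sd_uW SD of per-well constant offsets (µW).
#' @param noise_sd_uW SD of additive Gaussian noise per sample point (µW).
#' @param spike_uW,spike_tau_s Amplitude and decay constant of the loading
#'   spike shared by all wells.
#' @param peak_cv Coefficient of variation of the per-well kinetic peak
#'   (lognormal, mean 1).
#' @param duration_s,sampling_rate_hz Run length and sampling rate.
#' @param seed Integer seed; per-well substreams are derived from
#'   `(seed, well index)`, so a fixed seed gives byte-identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(layout = default_layout(),
                              profiles = default_profiles(),
                              drift_uW_per_h = 0.05,
                              common_drift_uW_per_h = 0.02,
                              offset_sd_uW = 0.3,
                              noise_sd_uW = 0.2,
                              spike_uW = 40,
                              spike_tau_s = 3600,
                              peak_cv = 0.25,
                              duration_s = 172800,
                              sampling_rate_hz = 1,
                              seed = 1L) {
  stopifnot(
    inherits(layout, "plate_layout"),
    noise_sd_uW >= 0, offset_sd_uW >= 0, peak_cv >= 0,
    spike_tau_s > 0, duration_s > 0, sampling_rate_hz > 0
  )
  sample_groups <- unique(layout$group[layout$role == "sample"])
  missing_profiles <- setdiff(sample_groups, names(profiles))
  if (length(missing_profiles) > 0) {
    stop("no kinetic profile for group(s): ",
         paste(missing_profiles, collapse = ", "), call. = FALSE)
  }
  n_cols <- attr(layout, "n_cols")
  drift_uW_per_h <- rep_len(drift_uW_per_h, n_cols)
  common_drift_uW_per_h <- rep_len(common_drift_uW_per_h, n_cols)
  structure(
    list(layout = layout, profiles = profiles,
         drift_uW_per_h = drift_uW_per_h,
         common_drift_uW_per_h = common_drift_uW_per_h,
         offset_sd_uW = offset_sd_uW, noise_sd_uW = noise_sd_uW,
         spike_uW = spike_uW, spike_tau_s = spike_tau_s,
         peak_cv = peak_cv, duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a full cartridge with known ground truth
#'
#' Every well receives the loading spike, its column's common drift, a
#' constant offset and Gaussian noise; sample wells additionally receive the
#' residual column drift and their group's metabolic power (scaled by a
#' per-well lognormal peak multiplier). The ground truth records each well's
#' realized profile and its closed-form metabolic heat integral.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `thermograms` (a [thermogram_set()]) and
#'   `truth` (tibble: `well_id`, `group`, `cells`, `peak_pW_per_cell`,
#'   `true_total_uJ`, `true_per_cell_uJ`).
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- config$layout
  dt <- 1 / config$sampling_rate_hz
  time_s <- seq(0, config$duration_s, by = dt)
  n <- length(time_s)
  spike <- config$spike_uW * exp(-time_s / config$spike_tau_s)
  t_h <- time_s / 3600

  powers <- matrix(NA_real_, nrow = n, ncol = nrow(layout),
                   dimnames = list(NULL, layout$well_id))
  truth <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    w <- layout[i, ]
    set.seed((config$seed %% 1000003L) * 2011L + i)
    trace <- spike + config$common_drift_uW_per_h[w$column] * t_h +
      stats::rnorm(1, 0, config$offset_sd_uW)
    peak_realized <- NA_real_
    total <- 0
    if (w$role == "sample") {
      trace <- trace + config$drift_uW_per_h[w$column] * t_h
      profile <- config$profiles[[w$group]]
      mult <- if (config$peak_cv > 0) {
        s <- sqrt(log(1 + config$peak_cv^2))
        exp(stats::rnorm(1, -s^2 / 2, s))
      } else 1
      profile$peak_pW_per_cell <- profile$peak_pW_per_cell * mult
      peak_realized <- profile$peak_pW_per_cell
      trace <- trace + metabolic_power(profile, time_s, w$cells)
      total <- expected_total_heat(profile, w$cells, config$duration_s)
    }
    if (config$noise_sd_uW > 0) {
      trace <- trace + stats::rnorm(n, 0, config$noise_sd_uW)
    }
    powers[, i] <- trace
    truth[[i]] <- tibble::tibble(
      well_id = w$well_id, group = w$group, cells = w$cells,
      peak_pW_per_cell = peak_realized,
      true_total_uJ = total,
      true_per_cell_uJ = if (w$cells > 0) total / w$cells else NA_real_
    )
  }
  truth <- dplyr::bind_rows(truth)
  list(
    thermograms = thermogram_set(layout, time_s, powers),
    truth = truth[layout$role == "sample", ]  # layout is column-major already
  )
}
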