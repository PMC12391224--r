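#' Pipeline configuration
#'
#' Settings for the four-stage per-well processing chain: reference
#' subtraction, trimming of the loading procedure, baseline/drift correction,
#' and integration.
#'
#' @param trim_start_s Seconds discarded from the start of each trace
#'   (default 1800 s, the ~30 min thermal equilibration after loading).
#' @param trim_end_s Optional end of the retained window, seconds from the
#'   start of recording; `NULL` keeps the trace to its end.
#' @param quiescent_window Two seconds `c(from, to)` (default 5 h to 10 h)
#'   during which wells are metabolically quiet; the baseline drift is
#'   estimated here. Must lie inside the retained window.
#' @param smoothing_halfwidth_s Halfwidth, in seconds, of the moving-average
#'   smoother used for drift estimation and baseline placement (default
#'   300 s). Zero disables smoothing.
#' @param drift_mode `"per_column_linear"` (default): a straight line fitted
#'   to the smoothed reference-corrected traces of the same column over the
#'   quiescent window is removed before the baseline shift;
#'   `"per_well_constant"`: only the constant min-to-zero shift.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_start_s = 1800,
                            trim_end_s = NULL,
                            quiescent_window = c(5, 10) * 3600,
                            smoothing_halfwidth_s = 300,
                            drift_mode = c("per_column_linear",
                                           "per_well_constant")) {
  drift_mode <- match.arg(drift_mode)
  stopifnot(
    is.numeric(trim_start_s), length(trim_start_s) == 1, trim_start_s >= 0,
    is.null(trim_end_s) ||
      (is.numeric(trim_end_s) && length(trim_end_s) == 1),
    is.numeric(quiescent_window), length(quiescent_window) == 2,
    quiescent_window[1] < quiescent_window[2],
    is.numeric(smoothing_halfwidth_s), smoothing_halfwidth_s >= 0
  )
  if (!is.null(trim_end_s) && trim_end_s <= trim_start_s) {
    stop("trim_end_s must exceed trim_start_s", call. = FALSE)
  }
  if (quiescent_window[1] < trim_start_s ||
      (!is.null(trim_end_s) && quiescent_window[2] > trim_end_s)) {
    stop("quiescent_window must lie inside the retained window",
         call. = FALSE)
  }
  structure(
    list(trim_start_s = trim_start_s, trim_end_s = trim_end_s,
         quiescent_window = quiescent_window,
         smoothing_halfwidth_s = smoothing_halfwidth_s,
         drift_mode = drift_mode),
    class = "pipeline_config"
  )
}

#' Tag a data frame as a corrected signal
#'
#' Pipeline stages pass around `corrected_signal` tibbles tagged with the well
#' id and the processing stage reached. Use this to feed externally prepared
#' traces into a specific stage.
#'
#' @param df Data frame with numeric columns `time_s` and `power_uW`.
#' @param well_id Well identifier.
#' @param stage One of `"raw"`, `"reference_corrected"`, `"trimmed"`,
#'   `"baseline_corrected"`.
#' @return A `corrected_signal` tibble.
#' @export
as_corrected_signal <- function(df, well_id = "well",
                                stage = c("raw", "reference_corrected",
                                          "trimmed", "baseline_corrected")) {
  stage <- match.arg(stage)
  stopifnot(is.data.frame(df), all(c("time_s", "power_uW") %in% names(df)))
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  new_signal(df$time_s, df$power_uW, well_id, stage)
}

#' Subtract the averaged reference traces from a sample trace
#'
#' The per-column reference capsules see the same loading spike, instrument
#' drift and ambient fluctuations as the sample wells; their pointwise mean is
#' subtracted from the sample trace so that only sample-specific heat (plus
#' residual channel drift) remains.
#'
#' @param sample A `corrected_signal` at stage `"raw"` (see [get_trace()]).
#' @param references A list of traces on the identical time grid.
#' @return A `corrected_signal` at stage `"reference_corrected"`.
#' @export
reference_correct <- function(sample, references) {
  stopifnot(inherits(sample, "corrected_signal"))
  if (!is.list(references) || length(references) == 0 ||
      is.data.frame(references)) {
    stop("references must be a non-empty list of traces", call. = FALSE)
  }
  ref_mat <- vapply(references, function(r) {
    stopifnot(is.data.frame(r), all(c("time_s", "power_uW") %in% names(r)))
    if (nrow(r) != nrow(sample) || !isTRUE(all.equal(r$time_s, sample$time_s))) {
      stop("reference trace is not on the sample's time grid", call. = FALSE)
    }
    r$power_uW
  }, numeric(nrow(sample)))
  corrected <- sample$power_uW - rowMeans(ref_mat)
  new_signal(sample$time_s, corrected, attr(sample, "well_id"),
             "reference_corrected")
}

#' Trim the loading procedure and trailing steady state
#'
#' @param signal A `corrected_signal` at stage `"reference_corrected"`.
#' @param config A [pipeline_config()].
#' @return A `corrected_signal` at stage `"trimmed"`, restricted to
#'   `[trim_start_s, trim_end_s]`.
#' @export
trim_signal <- function(signal, config = pipeline_config()) {
  stopifnot(inherits(signal, "corrected_signal"))
  if (signal_stage(signal) != "reference_corrected") {
    stop("trim_signal expects a reference-corrected signal, got stage '",
         signal_stage(signal), "'", call. = FALSE)
  }
  keep <- signal$time_s >= config$trim_start_s
  if (!is.null(config$trim_end_s)) {
    keep <- keep & signal$time_s <= config$trim_end_s
  }
  if (!any(keep)) {
    stop("trimming removes the entire trace for well ",
         attr(signal, "well_id"), call. = FALSE)
  }
  new_signal(signal$time_s[keep], signal$power_uW[keep],
             attr(signal, "well_id"), "trimmed")
}

# Centered moving average with partial windows at the edges; O(n) via cumsum.
moving_average <- function(x, halfwidth_pts) {
  k <- as.integer(halfwidth_pts)
  if (k <= 0) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove baseline drift and set the quiescent baseline to zero
#'
#' With `drift_mode = "per_column_linear"` a straight line is fitted by least
#' squares to the smoothed traces of the same column pooled over the
#' quiescent window, and removed; the smoothed, drift-free trace is then
#' shifted so its minimum is exactly zero, which keeps heat generation
#' non-negative for the rest of the run. With `"per_well_constant"` only the
#' shift is applied, using the well's own smoothed minimum. The returned
#' powers are the smoothed trace (halfwidth `smoothing_halfwidth_s`), so that
#' a single noise excursion can never define the baseline; any residual
#' negative value is clipped at zero.
#'
#' @param signal A `corrected_signal` at stage `"trimmed"`.
#' @param column_signals List of stage-`"trimmed"` signals from the same
#'   column (on the same grid) used for the drift fit; defaults to the signal
#'   itself. Ignored for `"per_well_constant"`.
#' @param config A [pipeline_config()].
#' @return A `corrected_signal` at stage `"baseline_corrected"` with
#'   `min(power_uW) >= 0`.
#' @export
baseline_correct <- function(signal, column_signals = list(signal),
                             config = pipeline_config()) {
  stopifnot(inherits(signal, "corrected_signal"))
  if (signal_stage(signal) != "trimmed") {
    stop("baseline_correct expects a trimmed signal, got stage '",
         signal_stage(signal), "'", call. = FALSE)
  }
  t <- signal$time_s
  qw <- config$quiescent_window
  in_q <- t >= qw[1] & t <= qw[2]
  if (!any(in_q)) {
    stop("quiescent window [", qw[1], ", ", qw[2],
         "] s lies outside the trace for well ", attr(signal, "well_id"),
         call. = FALSE)
  }
  dt <- stats::median(diff(t))
  hw_pts <- round(config$smoothing_halfwidth_s / dt)

  if (config$drift_mode == "per_column_linear") {
    tq <- NULL; yq <- NULL
    for (s in column_signals) {
      if (nrow(s) != length(t) || !isTRUE(all.equal(s$time_s, t))) {
        stop("column signals must share the well's time grid", call. = FALSE)
      }
      sm <- moving_average(s$power_uW, hw_pts)
      tq <- c(tq, t[in_q]); yq <- c(yq, sm[in_q])
    }
    fit <- stats::lm.fit(cbind(1, tq), yq)
    drift <- fit$coefficients[1] + fit$coefficients[2] * t
  } else {
    drift <- 0
  }
  smoothed <- moving_average(signal$power_uW - drift, hw_pts)
  shifted <- smoothed - min(smoothed)
  shifted[shifted < 0] <- 0  # guard; min-shift already makes min exactly 0
  new_signal(t, shifted, attr(signal, "well_id"), "baseline_corrected")
}

#' Integrate a baseline-corrected trace to total heat
#'
#' Trapezoidal rule over the retained window; with power in µW and time in
#' seconds the result is in µJ. At the instrument's dense 1 Hz sampling,
#' higher-order quadrature offers nothing, and for piecewise-linear signals
#' sampled on their breakpoints the trapezoid is exact.
#'
#' @param signal A `corrected_signal` at stage `"baseline_corrected"` with at
#'   least two points.
#' @return Total heat in µJ (non-negative scalar).
#' @export
integrate_total_heat <- function(signal) {
  stopifnot(inherits(signal, "corrected_signal"))
  if (signal_stage(signal) != "baseline_corrected") {
    stop("integrate_total_heat expects a baseline-corrected signal, ",
         "got stage '", signal_stage(signal), "'", call. = FALSE)
  }
  if (nrow(signal) < 2) {
    stop("need at least two points to integrate", call. = FALSE)
  }
  y <- signal$power_uW
  t <- signal$time_s
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

#' Normalize total heat by cell count
#'
#' @param total_heat_uJ Non-negative total heat (µJ).
#' @param cell_count Non-negative integer number of cells in the well.
#' @return Heat per cell in µJ/cell, or `NA` when `cell_count` is zero
#'   (cell-free controls keep their raw totals; a per-cell value is
#'   undefined).
#' @export
normalize_per_cell <- function(total_heat_uJ, cell_count) {
  if (any(total_heat_uJ < 0) || any(cell_count < 0)) {
    stop("total heat and cell count must be non-negative", call. = FALSE)
  }
  ifelse(cell_count > 0, total_heat_uJ / cell_count, NA_real_)
}

#' Run the full per-well pipeline over a plate
#'
#' For every sample well: subtract the same-column reference average, trim,
#' remove baseline drift, integrate, and normalize by cell count.
#'
#' @param x A [thermogram_set()].
#' @param config A [pipeline_config()].
#' @return A tibble with one row per sample well in column-major order:
#'   `well_id`, `group`, `column`, `cells`, `total_heat_uJ`,
#'   `heat_per_cell_uJ`.
#' @export
process_plate <- function(x, config = pipeline_config()) {
  stopifnot(inherits(x, "thermogram_set"), inherits(config, "pipeline_config"))
  layout <- x$layout
  samples <- layout[layout$role == "sample", ]
  if (nrow(samples) == 0) {
    stop("layout contains no sample wells", call. = FALSE)
  }
  results <- purrr::map_dfr(sort(unique(samples$column)), function(col) {
    ref_ids <- layout$well_id[layout$role == "reference" &
                                layout$column == col]
    refs <- purrr::map(ref_ids, ~ get_trace(x, .x))
    col_samples <- samples[samples$column == col, ]
    trimmed <- purrr::map(col_samples$well_id, function(w) {
      rc <- withCallingHandlers(
        reference_correct(get_trace(x, w), refs),
        error = function(e) stop("well ", w, ": ", conditionMessage(e),
                                 call. = FALSE)
      )
      trim_signal(rc, config)
    })
    purrr::map2_dfr(trimmed, seq_along(trimmed), function(sig, i) {
      bc <- baseline_correct(sig, column_signals = trimmed, config = config)
      total <- integrate_total_heat(bc)
      tibble::tibble(
        well_id = col_samples$well_id[i],
        group = col_samples$group[i],
        column = col,
        cells = col_samples$cells[i],
        total_heat_uJ = total,
        heat_per_cell_uJ = normalize_per_cell(total, col_samples$cells[i])
      )
    })
  })
  results
}
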