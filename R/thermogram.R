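#' Bundle per-well heat-flow traces with their plate layout
#'
#' A `thermogram_set` holds every well's power trace on one shared, uniformly
#' sampled time grid, together with the [plate_layout()] that says which wells
#' are samples and which are references. Power is in microwatts, time in
#' seconds from the start of recording, so a time integral is directly in
#' microjoules.
#'
#' @param layout A [plate_layout()].
#' @param time_s Strictly increasing numeric vector of times (seconds).
#' @param powers Numeric matrix, `length(time_s)` rows, one named column per
#'   well (µW).
#' @return An object of class `thermogram_set`.
#' @export
thermogram_set <- function(layout, time_s, powers) {
  stopifnot(inherits(layout, "plate_layout"), is.matrix(powers))
  time_s <- as.numeric(time_s)
  if (nrow(powers) != length(time_s)) {
    stop("powers must have one row per time point", call. = FALSE)
  }
  check_time_grid(time_s)
  ids <- colnames(powers)
  if (is.null(ids) || anyNA(ids)) {
    stop("powers must have well ids as column names", call. = FALSE)
  }
  unknown <- setdiff(ids, layout$well_id)
  if (length(unknown) > 0) {
    stop("trace(s) for well id(s) not in the layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  needed <- layout$well_id[layout$role %in% c("sample", "reference")]
  missing_wells <- setdiff(needed, ids)
  if (length(missing_wells) > 0) {
    stop(length(missing_wells), " well(s) in the layout have no trace: ",
         paste(missing_wells, collapse = ", "), call. = FALSE)
  }
  if (anyNA(powers)) {
    stop("traces contain missing values after grid alignment", call. = FALSE)
  }
  structure(
    list(layout = layout, time_s = time_s,
         powers = powers[, layout$well_id, drop = FALSE]),
    class = "thermogram_set"
  )
}

# Strictly increasing, uniform up to a 2x-nominal gap tolerance.
check_time_grid <- function(time_s) {
  if (length(time_s) < 2) stop("need at least two time points", call. = FALSE)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
  nominal <- stats::median(dt)
  if (any(dt > 2 * nominal)) {
    i <- which(dt > 2 * nominal)[1]
    stop(sprintf(
      "sampling gap of %.6g s at t = %.6g s exceeds twice the nominal %.6g s interval",
      dt[i], time_s[i], nominal
    ), call. = FALSE)
  }
  invisible(1 / nominal)
}

#' @export
print.thermogram_set <- function(x, ...) {
  rate <- 1 / stats::median(diff(x$time_s))
  cat(sprintf(
    "<thermogram_set> %d wells x %d samples (%.4g Hz, %.3g-%.3g s)\n",
    ncol(x$powers), nrow(x$powers), rate, min(x$time_s), max(x$time_s)
  ))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.thermogram_set <- function(x, ...) {
  long <- tibble::tibble(
    time_s = rep(x$time_s, times = ncol(x$powers)),
    well_id = rep(colnames(x$powers), each = nrow(x$powers)),
    power_uW = as.vector(x$powers)
  )
  dplyr::left_join(
    long,
    tibble::as_tibble(x$layout)[, c("well_id", "column", "role", "group", "cells")],
    by = "well_id"
  )
}

#' Extract one well's trace
#'
#' @param x A [thermogram_set()].
#' @param well_id A single well id present in the set.
#' @return A `corrected_signal` tibble (`time_s`, `power_uW`) at stage `"raw"`.
#' @export
get_trace <- function(x, well_id) {
  stopifnot(inherits(x, "thermogram_set"), length(well_id) == 1)
  if (!well_id %in% colnames(x$powers)) {
    stop("no trace for well ", well_id, call. = FALSE)
  }
  new_signal(x$time_s, x$powers[, well_id], well_id, "raw")
}

new_signal <- function(time_s, power_uW, well_id, stage) {
  structure(
    tibble::tibble(time_s = as.numeric(time_s),
                   power_uW = as.numeric(power_uW)),
    class = c("corrected_signal", class(tibble::tibble())),
    well_id = well_id, stage = stage
  )
}

#' @export
print.corrected_signal <- function(x, ...) {
  cat(sprintf("<corrected_signal> well %s, stage '%s'\n",
              attr(x, "well_id"), attr(x, "stage")))
  NextMethod()
}

signal_stage <- function(x) attr(x, "stage")

#' Read per-well thermograms from delimited text
#'
#' Accepts two dialects (comma- or tab-delimited, auto-detected):
#' * wide -- a `time_s` column plus one column per well id;
#' * long -- columns `time_s`, `well_id`, `power_uW`.
#'
#' Traces are aligned to the time grid shared by every well (times present for
#' only some wells are dropped from both ends); an interior gap wider than
#' twice the nominal sampling interval is an error, not interpolated, because
#' silently filling gaps would bias downstream heat integrals.
#'
#' @param path Path to the thermogram file.
#' @param layout The [plate_layout()] the traces belong to. Every sample and
#'   reference well in the layout must have a trace.
#' @return A [thermogram_set()].
#' @export
read_thermograms <- function(path, layout) {
  if (!file.exists(path)) {
    stop("thermogram file not found: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE)
  cols <- names(dt)
  if (!"time_s" %in% cols) {
    stop("thermogram file must have a 'time_s' column", call. = FALSE)
  }
  if (setequal(cols, c("time_s", "well_id", "power_uW"))) {
    wide <- data.table::dcast(dt, time_s ~ well_id, value.var = "power_uW")
    time_s <- wide$time_s
    mat <- as.matrix(wide[, setdiff(names(wide), "time_s"), with = FALSE])
    # intersection-trim: drop leading/trailing rows not shared by all wells
    complete <- stats::complete.cases(mat)
    if (any(complete)) {
      keep <- seq(which(complete)[1], utils::tail(which(complete), 1))
      time_s <- time_s[keep]
      mat <- mat[keep, , drop = FALSE]
    }
    if (anyNA(mat)) {
      stop("long-format traces do not share a common time grid", call. = FALSE)
    }
  } else {
    time_s <- dt$time_s
    mat <- as.matrix(dt[, setdiff(names(dt), "time_s"), with = FALSE])
  }
  ord <- order(time_s)
  thermogram_set(layout, time_s[ord], mat[ord, , drop = FALSE])
}

#' Write a thermogram set to delimited text
#'
#' @param x A [thermogram_set()].
#' @param path Output path.
#' @param format `"wide"` (default; `time_s` + one column per well) or
#'   `"long"` (`time_s,well_id,power_uW`).
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_thermograms <- function(x, path, format = c("wide", "long"), sep = ",") {
  stopifnot(inherits(x, "thermogram_set"))
  format <- match.arg(format)
  if (format == "wide") {
    out <- data.table::data.table(time_s = x$time_s)
    for (id in colnames(x$powers)) out[[id]] <- x$powers[, id]
  } else {
    out <- data.table::data.table(
      time_s = rep(x$time_s, times = ncol(x$powers)),
      well_id = rep(colnames(x$powers), each = nrow(x$powers)),
      power_uW = as.vector(x$powers)
    )
  }
  data.table::fwrite(out, path, sep = sep)
  invisible(path)
}

#' Write a per-well heat summary table
#'
#' Writes the comma-delimited results table with header exactly
#' `well_id,group,total_heat_uJ,cells,heat_per_cell_uJ`, in column-major well
#' order (B1..E1, B2..E2, ...), the order in which the cartridge is read.
#'
#' @param summaries A data frame of heat summaries as produced by
#'   [process_plate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heat_table <- function(summaries, path) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0) {
    stop("no heat summaries to write", call. = FALSE)
  }
  required <- c("well_id", "group", "total_heat_uJ", "cells",
                "heat_per_cell_uJ")
  missing_cols <- setdiff(required, names(summaries))
  if (length(missing_cols) > 0) {
    stop("heat summary is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_well_id(summaries$well_id, n_rows = 26L, n_cols = 1000L)
  out <- summaries[order(parsed$column, parsed$row), required]
  data.table::fwrite(out, path, sep = ",")
  invisible(path)
}

#' Read a per-well heat summary table
#'
#' @param path Path to a table written by [write_heat_table()] (or any
#'   delimited table with the same columns).
#' @return A tibble with columns `well_id`, `group`, `total_heat_uJ`,
#'   `cells`, `heat_per_cell_uJ`.
#' @export
read_heat_table <- function(path) {
  if (!file.exists(path)) stop("heat table not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE)
  tibble::as_tibble(dt)
}
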