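#' Construct and validate a plate layout
#'
#' A plate layout maps each well of a microcalorimeter cartridge to its role
#' (`"sample"` or `"reference"`), experimental group, and the number of cells
#' loaded into the well. The instrument compares every sample well against the
#' reference wells of its own column, so each column that holds at least one
#' sample well must also hold at least one reference well; the common cartridge
#' configuration places references in the top and bottom rows, but any row is
#' accepted as long as it is declared.
#'
#' @param wells A data frame with one row per well and columns `well_id`
#'   (row letter + column number, e.g. `"D6"`), `role` (`"sample"` or
#'   `"reference"`), `group` (character; may be `NA` for reference wells), and
#'   `cells` (non-negative integer count of cells in the well; must be 0 for
#'   reference wells).
#' @param n_rows,n_cols Cartridge geometry. Rows are labelled `A`, `B`, ...
#'   from the top; defaults describe the 48-well (6 x 8) cartridge.
#'
#' @return A tibble of class `plate_layout` with columns `well_id`, `row`,
#'   `column`, `role`, `group`, `cells`, ordered column-major (column 1 top to
#'   bottom, then column 2, ...).
#' @examples
#' plate_layout(data.frame(
#'   well_id = c("A1", "B1", "F1"),
#'   role = c("reference", "sample", "reference"),
#'   group = c(NA, "Cells Only", NA),
#'   cells = c(0, 150000, 0)
#' ))
#' @export
plate_layout <- function(wells, n_rows = 6L, n_cols = 8L) {
  stopifnot(is.data.frame(wells))
  required <- c("well_id", "role", "group", "cells")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0) {
    stop("layout is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  wells <- tibble::as_tibble(wells)[required]

  if (nrow(wells) == 0) {
    out <- tibble::tibble(
      well_id = character(), row = character(), column = integer(),
      role = character(), group = character(), cells = integer()
    )
    return(new_plate_layout(out, n_rows, n_cols))
  }

  parsed <- parse_well_id(wells$well_id, n_rows, n_cols)
  wells$row <- parsed$row
  wells$column <- parsed$column

  dup <- wells$well_id[duplicated(wells$well_id)]
  if (length(dup) > 0) {
    stop("duplicate well id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- !wells$role %in% c("sample", "reference")
  if (any(bad_role)) {
    stop("invalid role for well(s) ",
         paste(wells$well_id[bad_role], collapse = ", "),
         " (must be 'sample' or 'reference')", call. = FALSE)
  }
  wells$group <- as.character(wells$group)
  wells$cells <- as_count(wells$cells, wells$well_id, "cells")

  ref <- wells$role == "reference"
  if (any(ref & wells$cells > 0)) {
    stop("reference well(s) with non-zero cell count: ",
         paste(wells$well_id[ref & wells$cells > 0], collapse = ", "),
         call. = FALSE)
  }
  no_group <- is.na(wells$group) | wells$group == ""
  if (any(!ref & no_group)) {
    stop("sample well(s) without a group label: ",
         paste(wells$well_id[!ref & no_group], collapse = ", "), call. = FALSE)
  }

  sample_cols <- unique(wells$column[!ref])
  ref_cols <- unique(wells$column[ref])
  orphan <- setdiff(sample_cols, ref_cols)
  if (length(orphan) > 0) {
    stop("column(s) ", paste(sort(orphan), collapse = ", "),
         " contain sample wells but no reference well", call. = FALSE)
  }

  wells <- dplyr::arrange(wells, .data$column, .data$row)
  out <- wells[, c("well_id", "row", "column", "role", "group", "cells")]
  new_plate_layout(out, n_rows, n_cols)
}

new_plate_layout <- function(df, n_rows, n_cols) {
  structure(df,
    class = c("plate_layout", class(tibble::tibble())),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf(
    "<plate_layout> %d x %d cartridge: %d sample, %d reference wells\n",
    attr(x, "n_rows"), attr(x, "n_cols"),
    sum(x$role == "sample"), sum(x$role == "reference")
  ))
  NextMethod()
}

# Split "D6" into row letter and column number, validating against geometry.
parse_well_id <- function(well_id, n_rows, n_cols) {
  well_id <- as.character(well_id)
  m <- regmatches(well_id, regexec("^([A-Za-z])([0-9]+)$", well_id))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop("malformed well id(s): ", paste(well_id[bad], collapse = ", "),
         call. = FALSE)
  }
  row <- toupper(vapply(m, `[`, character(1), 2))
  column <- as.integer(vapply(m, `[`, character(1), 3))
  row_idx <- match(row, LETTERS)
  out_of_range <- row_idx > n_rows | column < 1 | column > n_cols
  if (any(out_of_range)) {
    stop("well id(s) outside the ", n_rows, " x ", n_cols, " cartridge: ",
         paste(well_id[out_of_range], collapse = ", "), call. = FALSE)
  }
  list(row = row, column = column)
}

as_count <- function(x, ids, what) {
  x <- suppressWarnings(as.numeric(x))
  bad <- is.na(x) | x < 0 | x != round(x)
  if (any(bad)) {
    stop(what, " must be a non-negative integer; offending well(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  as.integer(round(x))
}

#' Read a plate layout from a YAML configuration file
#'
#' The configuration holds optional `n_rows`/`n_cols` keys and a `wells` list
#' whose entries carry `id`, `role`, `group` and `cells`:
#'
#' ```yaml
#' n_rows: 6
#' n_cols: 8
#' wells:
#'   - {id: A1, role: reference, group: ~, cells: 0}
#'   - {id: B1, role: sample, group: No Cells, cells: 0}
#' ```
#'
#' @param path Path to the layout file.
#' @return A validated [plate_layout()].
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$wells) || length(cfg$wells) == 0) {
    return(plate_layout(
      data.frame(well_id = character(), role = character(),
                 group = character(), cells = integer()),
      n_rows = cfg$n_rows %||% 6L, n_cols = cfg$n_cols %||% 8L
    ))
  }
  wells <- purrr::map_dfr(cfg$wells, function(w) {
    tibble::tibble(
      well_id = as.character(w$id %||% w$well_id %||% NA_character_),
      role = as.character(w$role %||% NA_character_),
      group = if (is.null(w$group)) NA_character_ else as.character(w$group),
      cells = as.numeric(w$cells %||% 0)
    )
  })
  plate_layout(wells, n_rows = cfg$n_rows %||% 6L, n_cols = cfg$n_cols %||% 8L)
}

#' Write a plate layout to the YAML configuration dialect
#'
#' @param layout A [plate_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  wells <- purrr::pmap(
    layout[, c("well_id", "role", "group", "cells")],
    function(well_id, role, group, cells) {
      list(id = well_id, role = role,
           group = if (is.na(group)) NULL else group,
           cells = as.integer(cells))
    }
  )
  yaml::write_yaml(
    list(n_rows = attr(layout, "n_rows"), n_cols = attr(layout, "n_cols"),
         wells = wells),
    path
  )
  invisible(path)
}

#' The 4-group, 8-replicate chondrocyte study layout
#'
#' The layout used in the 48-h chondrocyte microcalorimetry experiment this
#' package reproduces: reference capsules fill the top (A) and bottom (F) rows
#' (two per column, 16 total), and the 32 sample wells in rows B-E are grouped
#' in column pairs -- columns 1-2 "No Cells" (cell-free gels), 3-4 "Cells Only"
#' (150,000 chondrocytes, PBS), 5-6 "Cells + Glucose" and 7-8
#' "Cells + Glutamine" (150,000 chondrocytes, single-carbon-source media).
#'
#' @return A [plate_layout()] with 48 wells.
#' @export
default_layout <- function() {
  cols <- 1:8
  group_of <- c("No Cells", "No Cells", "Cells Only", "Cells Only",
                "Cells + Glucose", "Cells + Glucose",
                "Cells + Glutamine", "Cells + Glutamine")
  wells <- purrr::map_dfr(cols, function(j) {
    tibble::tibble(
      well_id = paste0(c("A", "B", "C", "D", "E", "F"), j),
      role = c("reference", rep("sample", 4), "reference"),
      group = c(NA, rep(group_of[j], 4), NA),
      cells = c(0L, rep(if (group_of[j] == "No Cells") 0L else 150000L, 4), 0L)
    )
  })
  plate_layout(wells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
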