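#' @keywords internal
"_PACKAGE"

# Fixed CSV dialect for per-cell tables: comma-separated, UTF-8, "." decimal,
# mandatory header with exactly these column names.
CELL_TABLE_COLUMNS <- c(
  "cell_id", "individual", "mother_id", "birth_time_min", "birth_area_um2",
  "perimeter_um", "pos_x_um", "pos_y_um", "n_neighbours_total",
  "n_sig_neighbours", "n_meristemoid_nb", "n_gmc_nb", "n_stoma_nb",
  "sig_contact_fraction", "behaviour"
)

CELL_NUMERIC_COLUMNS <- c(
  "birth_time_min", "birth_area_um2", "perimeter_um", "pos_x_um", "pos_y_um",
  "n_neighbours_total", "n_sig_neighbours", "n_meristemoid_nb", "n_gmc_nb",
  "n_stoma_nb", "sig_contact_fraction"
)

BEHAVIOUR_LEVELS <- c("ACD", "DIFF", "UNKNOWN")

#' Validate a per-cell table
#'
#' Checks the schema and invariants of an SLGC cell table: required columns,
#' numeric types, positive areas and perimeters, signaling-neighbour census
#' consistency (`n_sig_neighbours` must equal the sum of meristemoid, GMC and
#' stoma neighbour counts and may not exceed `n_neighbours_total`), contact
#' fraction in [0, 1], and behaviour labels in `ACD`/`DIFF`/`UNKNOWN`.
#'
#' @param cells data.frame of per-cell records.
#' @return `cells`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cell_table <- function(cells) {
  stopifnot(is.data.frame(cells))
  missing_cols <- setdiff(CELL_TABLE_COLUMNS, names(cells))
  if (length(missing_cols) > 0L) {
    stop("cell table schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in CELL_NUMERIC_COLUMNS) {
    if (!is.numeric(cells[[col]])) {
      stop("cell table parse error: column '", col, "' is not numeric",
           call. = FALSE)
    }
  }
  if (nrow(cells) == 0L) return(invisible(cells))

  bad <- function(rows, what) {
    if (any(rows)) {
      stop("cell table validation error: ", what, " in row(s): ",
           paste(utils::head(which(rows), 10L), collapse = ", "),
           call. = FALSE)
    }
  }
  bad(!(cells$behaviour %in% BEHAVIOUR_LEVELS),
      "behaviour not one of ACD/DIFF/UNKNOWN")
  bad(!(cells$birth_area_um2 > 0), "non-positive birth_area_um2")
  bad(!(cells$perimeter_um > 0), "non-positive perimeter_um")
  nb_sum <- cells$n_meristemoid_nb + cells$n_gmc_nb + cells$n_stoma_nb
  bad(cells$n_sig_neighbours != nb_sum,
      "n_sig_neighbours does not equal meristemoid+GMC+stoma counts")
  bad(cells$n_sig_neighbours > cells$n_neighbours_total,
      "n_sig_neighbours exceeds n_neighbours_total")
  bad(cells$sig_contact_fraction < 0 | cells$sig_contact_fraction > 1,
      "sig_contact_fraction outside [0, 1]")
  invisible(cells)
}

#' Read a per-cell table from CSV
#'
#' Reads one row per SLGC with the fixed column set
#' `cell_id, individual, mother_id, birth_time_min, birth_area_um2,
#' perimeter_um, pos_x_um, pos_y_um, n_neighbours_total, n_sig_neighbours,
#' n_meristemoid_nb, n_gmc_nb, n_stoma_nb, sig_contact_fraction, behaviour`
#' and validates every invariant. Row order is preserved.
#'
#' @param path path to a CSV file.
#' @return data.frame of validated cell records.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(CELL_TABLE_COLUMNS, names(cells))
  if (length(missing_cols) > 0L) {
    stop("cell table schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cells <- cells[, CELL_TABLE_COLUMNS]
  for (col in CELL_NUMERIC_COLUMNS) {
    raw <- cells[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- is.na(num) & !(is.na(raw) | raw == "")
    if (any(bad)) {
      stop("cell table parse error: non-numeric value in column '", col,
           "' at row(s): ", paste(utils::head(which(bad), 10L), collapse = ", "),
           call. = FALSE)
    }
    cells[[col]] <- num
  }
  cells$mother_id[cells$mother_id == ""] <- NA_character_
  # identifier columns are opaque strings
  for (col in c("cell_id", "individual", "mother_id", "behaviour")) {
    cells[[col]] <- as.character(cells[[col]])
  }
  validate_cell_table(cells)
  cells
}

#' Write a per-cell table to CSV
#'
#' Inverse of [read_cell_table()]: `read_cell_table(write_cell_table(x, f))`
#' reproduces `x` field for field. Absent mother identifiers are written as
#' empty fields.
#'
#' @param cells validated cell table (see [validate_cell_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  validate_cell_table(cells)
  out <- cells[, CELL_TABLE_COLUMNS, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a fluorescence trajectory
#'
#' A trajectory is the time-stamped SPCH intensity record of one cell,
#' re-based so its first sample is the cell's birth (t = 0). Times must be
#' strictly increasing and intensities finite and non-negative.
#'
#' @param cell_id identifier.
#' @param time_min numeric vector of sample times in minutes.
#' @param intensity matching vector of intensities (arbitrary units).
#' @param nuclear_area_um2 optional matching vector of nuclear areas.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(cell_id, time_min, intensity, nuclear_area_um2 = NULL) {
  stopifnot(length(time_min) == length(intensity), length(time_min) >= 1L)
  if (any(diff(time_min) <= 0)) {
    stop("trajectory times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("trajectory intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(nuclear_area_um2)) {
    stopifnot(length(nuclear_area_um2) == length(time_min))
  }
  structure(
    list(cell_id = as.character(cell_id),
         time_min = time_min - time_min[1L],
         intensity = intensity,
         nuclear_area_um2 = nuclear_area_um2),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> cell %s: %d samples over %g min\n",
              x$cell_id, length(x$time_min), max(x$time_min)))
  invisible(x)
}

#' Read trajectories from a long-format CSV
#'
#' Expects columns `cell_id`, `time_min`, `intensity_au` and optionally
#' `nuclear_area_um2`. Samples are grouped by cell (first-appearance order),
#' sorted by time, and re-based so each cell's first sample is t = 0.
#'
#' @param path path to a CSV file.
#' @return named list of [trajectory()] objects.
#' @export
read_trajectory_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("cell_id", "time_min", "intensity_au")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("trajectory table schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab[, c("cell_id", "time_min")])) {
    stop("trajectory table validation error: duplicate (cell_id, time_min) pair",
         call. = FALSE)
  }
  if (any(tab$intensity_au < 0)) {
    stop("trajectory table validation error: negative intensity", call. = FALSE)
  }
  ids <- unique(tab$cell_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    trajectory(id, sub$time_min, sub$intensity_au,
               if ("nuclear_area_um2" %in% names(sub)) sub$nuclear_area_um2)
  })
  names(out) <- ids
  out
}

#' Write trajectories to a long-format CSV
#'
#' @param trajs list of [trajectory()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    d <- data.frame(cell_id = tr$cell_id, time_min = tr$time_min,
                    intensity_au = tr$intensity,
                    stringsAsFactors = FALSE)
    if (!is.null(tr$nuclear_area_um2)) d$nuclear_area_um2 <- tr$nuclear_area_um2
    d
  })
  has_na <- vapply(rows, function(d) "nuclear_area_um2" %in% names(d), logical(1))
  if (any(has_na) && !all(has_na)) {
    rows <- lapply(rows, function(d) {
      if (!"nuclear_area_um2" %in% names(d)) d$nuclear_area_um2 <- NA_real_
      d
    })
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration
#'
#' YAML file with a top-level `seed` key plus module-specific parameter
#' blocks. A fixed seed makes every downstream output reproducible.
#'
#' @param path path to a YAML file.
#' @return named list; `$seed` is an integer.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run config must carry a top-level 'seed' key",
                              call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
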