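#' Gridded environmental covariates
#'
#' An `env_grid` holds a rectangular raster of cells, each carrying a vector
#' of environmental covariate values (one column per variable). Cells are
#' stored row-major with row 1 at the top (northernmost) edge, matching the
#' row order of ESRI ASCII grids. `origin` is the lower-left corner of the
#' grid in map units.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param values Numeric matrix with `n_rows * n_cols` rows and one column
#'   per variable; column names are the variable codes (e.g. `"Prec"`,
#'   `"Temp"`). A named list of full-length numeric vectors is also accepted.
#' @param cell_size Cell edge length in map units (km for the 8-km grids
#'   this package emulates). Must be positive.
#' @param origin Numeric length-2 `(x, y)` lower-left corner.
#' @param mask Logical vector of length `n_rows * n_cols`; `TRUE` marks a
#'   valid cell. Defaults to all valid.
#'
#' @return An object of class `env_grid`.
#' @examples
#' g <- env_grid(2, 2, values = cbind(Prec = c(700, 800, 900, 1000)))
#' cell_coords(g)
#' @export
env_grid <- function(n_rows, n_cols, values, cell_size = 8, origin = c(0, 0),
                     mask = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) {
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("cell_size must be a single positive number", call. = FALSE)
  }
  n_cells <- n_rows * n_cols
  if (is.list(values) && !is.data.frame(values)) {
    values <- do.call(cbind, values)
  }
  values <- as.matrix(values)
  if (nrow(values) != n_cells) {
    stop("values must have n_rows * n_cols rows (one per cell)", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyNA(colnames(values)) ||
      any(colnames(values) == "")) {
    stop("every variable column must be named with its code", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("variable codes must be unique", call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, n_cells)
  mask <- as.logical(mask)
  if (length(mask) != n_cells) {
    stop("mask must have one entry per cell", call. = FALSE)
  }
  if (any(!is.finite(values[mask, , drop = FALSE]))) {
    stop("unmasked cells must have finite values for every variable",
         call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         origin = as.numeric(origin)[1:2], variables = colnames(values),
         values = values, mask = mask),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %d x %d cells (%.3g map units/cell), %d masked\n",
              x$n_rows, x$n_cols, x$cell_size, sum(!x$mask)))
  cat("variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid An [env_grid()].
#' @return Data frame with `cell_id`, `row`, `col`, `x`, `y` (cell centres),
#'   in storage (row-major, top row first) order.
#' @export
cell_coords <- function(grid) {
  stopifnot(inherits(grid, "env_grid") || inherits(grid, "fav_surface"))
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(
    cell_id = seq_len(grid$n_rows * grid$n_cols),
    row = row, col = col,
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] + (grid$n_rows - row + 0.5) * grid$cell_size
  )
}

#' Per-cell presence/absence outcomes
#'
#' A `detection_grid` records, for each cell of a companion [env_grid()],
#' whether the species was detected (1), not detected (0), or not surveyed
#' (`NA`). Presence (`n1`) and absence (`n0`) counts are carried explicitly
#' because the favourability transform is anchored on them.
#'
#' @param outcomes Vector of 0/1/`NA`, one entry per cell.
#' @return An object of class `detection_grid` with fields `outcomes`,
#'   `n1`, `n0`.
#' @examples
#' d <- detection_grid(c(1, 0, NA, 1))
#' d$n1; d$n0
#' @export
detection_grid <- function(outcomes) {
  outcomes <- as.integer(outcomes)
  if (!all(outcomes %in% c(0L, 1L) | is.na(outcomes))) {
    stop("outcomes must be 0, 1 or NA", call. = FALSE)
  }
  structure(
    list(outcomes = outcomes,
         n1 = sum(outcomes == 1L, na.rm = TRUE),
         n0 = sum(outcomes == 0L, na.rm = TRUE)),
    class = "detection_grid"
  )
}

#' @export
print.detection_grid <- function(x, ...) {
  cat(sprintf("<detection_grid> %d cells: %d presences, %d absences, %d unsurveyed\n",
              length(x$outcomes), x$n1, x$n0, sum(is.na(x$outcomes))))
  invisible(x)
}

# shared check that a grid supplies every variable a model needs
check_variables <- function(grid, needed) {
  missing <- setdiff(needed, grid$variables)
  if (length(missing)) {
    stop("grid is missing model variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
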