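#' Read a coefficient set from CSV
#'
#' The file format is a CSV with columns `variable`, `coefficient`,
#' `inclusion_order`, preceded by a commented metadata header of
#' `# key: value` lines carrying `label`, `intercept`, `n1`, `n0` and
#' optional `note` lines. This keeps each published or fitted model in a
#' single human-readable file.
#'
#' @param path File path.
#' @return A [coefficient_set()].
#' @export
read_coefficient_set <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  meta <- list()
  notes <- character(0)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2]); val <- trimws(m[3])
      if (key == "note") notes <- c(notes, val) else meta[[key]] <- val
    }
  }
  for (k in c("label", "intercept")) {
    if (is.null(meta[[k]])) {
      stop("malformed coefficient file ", path, ": missing '# ", k,
           ":' header line", call. = FALSE)
    }
  }
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  need <- c("variable", "coefficient", "inclusion_order")
  if (!all(need %in% names(tab))) {
    stop("malformed coefficient file ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  coefs <- stats::setNames(as.numeric(tab$coefficient), tab$variable)
  ord <- as.integer(tab$inclusion_order)
  names(ord) <- tab$variable
  ord <- ord[!is.na(ord)]
  parse_count <- function(x) {
    if (is.null(x) || toupper(x) == "NA") NA_integer_ else as.integer(x)
  }
  coefficient_set(
    intercept = as.numeric(meta$intercept), coefficients = coefs,
    inclusion_order = if (length(ord)) ord else NULL,
    n1 = parse_count(meta$n1), n0 = parse_count(meta$n0),
    label = meta$label, notes = if (length(notes)) notes else NULL)
}

#' Write a coefficient set to CSV
#'
#' Inverse of [read_coefficient_set()]; write-then-read is the identity
#' up to numeric printing precision (15 significant digits).
#'
#' @param coefs A [coefficient_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coefficient_set <- function(coefs, path) {
  num <- function(x) formatC(x, digits = 15, format = "g")
  hdr <- c(
    sprintf("# label: %s", coefs$label),
    sprintf("# intercept: %s", num(coefs$intercept)),
    sprintf("# n1: %s", if (is.na(coefs$n1)) "NA" else coefs$n1),
    sprintf("# n0: %s", if (is.na(coefs$n0)) "NA" else coefs$n0))
  for (n in coefs$notes) hdr <- c(hdr, sprintf("# note: %s", n))
  ord <- rep(NA_integer_, length(coefs$coefficients))
  if (!is.null(coefs$inclusion_order)) {
    ord <- coefs$inclusion_order[names(coefs$coefficients)]
  }
  rows <- sprintf("%s,%s,%s", names(coefs$coefficients),
                  num(coefs$coefficients),
                  ifelse(is.na(ord), "NA", ord))
  writeLines(c(hdr, "variable,coefficient,inclusion_order", rows), path)
  invisible(path)
}

#' Write one grid variable as an ESRI ASCII raster
#'
#' @param grid An [env_grid()] or `fav_surface`.
#' @param variable Variable code to write (for a `fav_surface`, the single
#'   favourability layer is written and `variable` is ignored).
#' @param path Output `.asc` path.
#' @param nodata NODATA value written for masked cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, variable = NULL, path,
                             nodata = -9999) {
  if (inherits(grid, "fav_surface")) {
    v <- grid$F
  } else {
    check_variables(grid, variable)
    v <- grid$values[, variable]
  }
  v[!grid$mask] <- NA_real_
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  vc <- formatC(v, digits = 15, format = "g")
  vc[is.na(v)] <- formatC(nodata, digits = 15, format = "g")
  m <- matrix(vc, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  writeLines(c(hdr, apply(m, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Read an ESRI ASCII raster as a single-variable grid
#'
#' @param path `.asc` file path.
#' @param variable_code Code for the read layer.
#' @return An [env_grid()]; NODATA cells are masked.
#' @export
read_ascii_grid <- function(path, variable_code) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[k]])) {
      stop("malformed ASCII grid ", path, ": missing header '", k, "'",
           call. = FALSE)
    }
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("malformed ASCII grid ", path, ": expected ",
         hdr$ncols * hdr$nrows, " values, found ", length(vals),
         call. = FALSE)
  }
  mask <- rep(TRUE, length(vals))
  if (!is.null(hdr$nodata_value)) {
    mask <- vals != hdr$nodata_value
    vals[!mask] <- NA_real_
  }
  m <- matrix(vals, ncol = 1, dimnames = list(NULL, variable_code))
  env_grid(hdr$nrows, hdr$ncols, m, cell_size = hdr$cellsize,
           origin = c(hdr$xllcorner, hdr$yllcorner), mask = mask)
}

#' Write a multi-variable grid as a directory of ASCII rasters
#'
#' One `<variable>.asc` per variable.
#' @param grid An [env_grid()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid_dir <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in grid$variables) {
    write_ascii_grid(grid, v, file.path(dir, paste0(v, ".asc")))
  }
  invisible(dir)
}

#' Read a directory of ASCII rasters as one grid
#'
#' @param dir Directory containing `<variable>.asc` files.
#' @return An [env_grid()] with one variable per file.
#' @export
read_grid_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc files in ", dir, call. = FALSE)
  layers <- lapply(files, function(f) {
    read_ascii_grid(f, sub("\\.asc$", "", basename(f)))
  })
  do.call(combine_grids, layers)
}

#' Write detections as a cell table CSV
#'
#' Columns `cell_id, x, y, outcome` with cell-centre coordinates; missing
#' outcomes are written as `NA`.
#'
#' @param det A [detection_grid()].
#' @param grid The companion [env_grid()] (for coordinates).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(det, grid, path) {
  co <- cell_coords(grid)
  co$outcome <- det$outcomes
  utils::write.csv(co[, c("cell_id", "x", "y", "outcome")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read detections from a cell table CSV
#'
#' @param path CSV with at least `cell_id` and `outcome` columns.
#' @return A [detection_grid()] in `cell_id` order.
#' @export
read_detections <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("cell_id", "outcome") %in% names(tab))) {
    stop("malformed detections file ", path,
         ": need columns cell_id, outcome", call. = FALSE)
  }
  detection_grid(tab$outcome[order(tab$cell_id)])
}

#' Write a performance report as JSON
#'
#' Undefined indices (`NA`) round-trip as JSON `null`.
#' @param report A `performance_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- list(
    model_label = report$model_label,
    confusion = report$confusion[c("TP", "FP", "TN", "FN", "threshold",
                                   "score_kind")],
    indices = report[c("sensitivity", "specificity", "pcc", "ppp", "npp",
                       "tss", "kappa", "auc")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a performance report from JSON
#'
#' @param path JSON written by [write_report()].
#' @return A `performance_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path)
  cm <- structure(
    list(TP = x$confusion$TP, FP = x$confusion$FP, TN = x$confusion$TN,
         FN = x$confusion$FN, threshold = x$confusion$threshold,
         score_kind = x$confusion$score_kind),
    class = "confusion_matrix")
  null_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  rep <- performance_report(cm, auc = null_na(x$indices$auc),
                            model_label = x$model_label)
  # preserve stored indices verbatim (they equal the recomputed ones)
  for (k in c("sensitivity", "specificity", "pcc", "ppp", "npp", "tss",
              "kappa")) {
    rep[[k]] <- null_na(x$indices[[k]])
  }
  rep
}
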