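#' Known data-generating truth for simulated landscapes
#'
#' Bundles the logit-scale coefficients used to realize presence/absence
#' from covariates, plus optional nonlinear response shapes. A clamped
#' response (`type = "clamp"`) saturates the covariate's contribution
#' outside `[lower, upper]` — the simplest mechanism by which a linear
#' model fitted inside one covariate range extrapolates wrongly outside it.
#'
#' @param intercept Logit-scale intercept.
#' @param coefficients Named numeric vector of logit-scale slopes; names
#'   are grid variable codes.
#' @param response Optional named list; each element is
#'   `list(type = "clamp", lower = -Inf, upper = Inf)` for the matching
#'   variable. Variables without an entry respond linearly.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(intercept, coefficients, response = list()) {
  coefficients <- unlist(coefficients)
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    stop("coefficients must be named by variable code", call. = FALSE)
  }
  if (length(response)) {
    bad <- setdiff(names(response), names(coefficients))
    if (length(bad)) {
      stop("response shapes given for unknown variable(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients, response = response),
            class = "simulation_truth")
}

# apply the (possibly clamped) response shape of one variable
apply_response <- function(x, shape) {
  if (is.null(shape)) return(x)
  if (!identical(shape$type, "clamp")) {
    stop("unknown response type: ", shape$type, call. = FALSE)
  }
  lo <- if (is.null(shape$lower)) -Inf else shape$lower
  hi <- if (is.null(shape$upper)) Inf else shape$upper
  pmin(pmax(x, lo), hi)
}

# logit-scale truth surface for a grid
truth_linear_predictor <- function(truth, grid) {
  check_variables(grid, names(truth$coefficients))
  eta <- rep(truth$intercept, nrow(grid$values))
  for (v in names(truth$coefficients)) {
    eta <- eta + truth$coefficients[[v]] *
      apply_response(grid$values[, v], truth$response[[v]])
  }
  eta
}

# separable Gaussian blur with per-position renormalized truncated kernel,
# so border cells are smoothed over the kernel mass that falls inside
gaussian_smooth <- function(mat, radius) {
  if (radius <= 0) return(mat)
  half <- max(1L, ceiling(3 * radius))
  w <- exp(-(seq(-half, half))^2 / (2 * radius^2))
  smooth_rows <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (k in seq(-half, half)) {
      wk <- w[k + half + 1L]
      src <- pmin(pmax(seq_len(n) + k, 1L), n)
      keep <- (seq_len(n) + k) >= 1L & (seq_len(n) + k) <= n
      out[keep, ] <- out[keep, ] + wk * m[src[keep], , drop = FALSE]
      norm[keep] <- norm[keep] + wk
    }
    out / norm
  }
  t(smooth_rows(t(smooth_rows(mat))))
}

#' Simulate one spatially autocorrelated covariate field
#'
#' Draws i.i.d. Gaussian noise on the grid, smooths it with a Gaussian
#' kernel whose standard deviation is `autocorrelation_range` (in cells),
#' and linearly rescales the result so its minimum and maximum equal
#' `value_range` exactly. `autocorrelation_range = 0` gives white noise.
#'
#' The special code `"Lati"` is generated as the cell-centre y coordinate
#' rescaled into `value_range`, because latitude is a spatial coordinate,
#' not a random environmental field.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param variable_code Variable code for the produced layer.
#' @param value_range Length-2 numeric `(min, max)` with `min < max`.
#' @param autocorrelation_range Smoothing kernel sd, in cells (>= 0).
#' @param seed Integer seed; identical inputs give bit-identical fields.
#' @param cell_size,origin Passed to [env_grid()].
#' @return An [env_grid()] with a single variable.
#' @examples
#' g <- generate_covariate_field(20, 20, "Prec", c(600, 1200),
#'                               autocorrelation_range = 3, seed = 1)
#' range(g$values)
#' @export
generate_covariate_field <- function(n_rows, n_cols, variable_code,
                                     value_range, autocorrelation_range = 0,
                                     seed = 1, cell_size = 8,
                                     origin = c(0, 0)) {
  if (!all(is.finite(value_range)) || length(value_range) != 2L ||
      value_range[1] >= value_range[2]) {
    stop("value_range must be finite with min < max", call. = FALSE)
  }
  if (autocorrelation_range < 0) {
    stop("autocorrelation_range must be >= 0", call. = FALSE)
  }
  if (identical(variable_code, "Lati")) {
    row <- rep(seq_len(n_rows), each = n_cols)
    y <- origin[2] + (n_rows - row + 0.5) * cell_size
    v <- rescale_to(y, value_range)
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old))
    set.seed(seed)
    field <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    field <- gaussian_smooth(field, autocorrelation_range)
    v <- rescale_to(as.numeric(t(field)), value_range)  # row-major cell order
  }
  m <- matrix(v, ncol = 1, dimnames = list(NULL, variable_code))
  env_grid(n_rows, n_cols, m, cell_size = cell_size, origin = origin)
}

rescale_to <- function(x, rng) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(mean(rng), length(x)))
  rng[1] + (x - r[1]) / (r[2] - r[1]) * (rng[2] - rng[1])
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Combine single-variable grids into one multi-variable grid
#'
#' @param ... [env_grid()] objects on the same geometry.
#' @return An [env_grid()] holding all variables.
#' @export
combine_grids <- function(...) {
  gs <- list(...)
  g1 <- gs[[1]]
  for (g in gs[-1]) {
    if (g$n_rows != g1$n_rows || g$n_cols != g1$n_cols) {
      stop("all grids must share the same dimensions", call. = FALSE)
    }
  }
  vals <- do.call(cbind, lapply(gs, function(g) g$values))
  mask <- Reduce(`&`, lapply(gs, function(g) g$mask))
  env_grid(g1$n_rows, g1$n_cols, vals, cell_size = g1$cell_size,
           origin = g1$origin, mask = mask)
}

#' Realize presence/absence from a known truth
#'
#' Each unmasked cell's outcome is Bernoulli with
#' `P = plogis(intercept + sum(beta_i * g_i(x_i)))` where `g_i` is the
#' (possibly clamped) response shape of the truth. Masked cells get `NA`.
#'
#' @param grid An [env_grid()] supplying every truth variable.
#' @param truth A [simulation_truth()].
#' @param seed Integer seed for the Bernoulli draws.
#' @return A [detection_grid()].
#' @export
simulate_presence <- function(grid, truth, seed = 1) {
  p <- stats::plogis(truth_linear_predictor(truth, grid))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  y <- stats::rbinom(length(p), 1L, p)
  y[!grid$mask] <- NA_integer_
  detection_grid(y)
}

#' Two-region "edge of range" simulation scenario
#'
#' Generates two independent landscapes (training and target) from the
#' same truth coefficients but region-specific covariate ranges. Shifting
#' or disjoining a range between regions — e.g. a rainier target region —
#' combined with a nonlinear (clamped) truth response produces the
#' situation in which a model fitted in one region transfers poorly to
#' the other.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{n_rows, n_cols}{grid dimensions (shared by both regions).}
#'     \item{cell_size, origin}{optional grid geometry (defaults 8, (0,0)).}
#'     \item{variables}{named list; each element is a list with
#'       `train` and `target` length-2 ranges and optional
#'       `autocorrelation` (cells, default 5).}
#'     \item{truth}{a [simulation_truth()] or a list of arguments for one.}
#'     \item{seed}{master integer seed; all per-stage seeds derive from it.}
#'   }
#' @return List with `train` and `target`, each `list(grid, det)`, plus
#'   the `truth` used.
#' @examples
#' sc <- generate_two_region_scenario(edge_scenario_config(seed = 7))
#' sc$train$det
#' @export
generate_two_region_scenario <- function(config) {
  need <- c("n_rows", "n_cols", "variables", "truth", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("scenario config is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  truth <- config$truth
  if (!inherits(truth, "simulation_truth")) {
    truth <- do.call(simulation_truth, truth)
  }
  miss <- setdiff(names(truth$coefficients), names(config$variables))
  if (length(miss)) {
    stop("config lacks range specs for truth variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cell_size <- config$cell_size %||% 8
  origin <- config$origin %||% c(0, 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L,
                            2L * length(config$variables) + 2L)
  build_region <- function(which, det_seed) {
    layers <- vector("list", length(config$variables))
    for (i in seq_along(config$variables)) {
      v <- names(config$variables)[i]
      spec <- config$variables[[i]]
      idx <- (i - 1L) * 2L + if (which == "train") 1L else 2L
      layers[[i]] <- generate_covariate_field(
        config$n_rows, config$n_cols, v,
        value_range = spec[[which]],
        autocorrelation_range = spec$autocorrelation %||% 5,
        seed = stage_seeds[idx], cell_size = cell_size, origin = origin)
    }
    grid <- do.call(combine_grids, layers)
    list(grid = grid, det = simulate_presence(grid, truth, seed = det_seed))
  }
  list(train = build_region("train", stage_seeds[length(stage_seeds) - 1L]),
       target = build_region("target", stage_seeds[length(stage_seeds)]),
       truth = truth)
}

#' Default edge-of-range scenario configuration
#'
#' A compact benchmark mirroring the rainy-north vs drier-south contrast:
#' five covariates (altitude, precipitation, solar radiation, rain days,
#' latitude), with the target region's precipitation range disjoint from
#' (above) the training range and a truth whose precipitation response
#' saturates at the top of the training range. Rain days (`DPre`) carry
#' signal in both regions, so a locally refitted model retains
#' discrimination that the transferred one loses.
#'
#' @param n_rows,n_cols Region grid dimensions (default 50 x 50).
#' @param seed Master seed.
#' @param shift If `FALSE`, both regions use the training ranges
#'   (exchangeable-regions control).
#' @param variables Optional named list replacing the default variable
#'   specs (each element a list with `train`, `target` and optional
#'   `autocorrelation`), e.g. to match a published model's variable codes.
#' @param truth Optional [simulation_truth()] replacing the default.
#' @return A config list for [generate_two_region_scenario()].
#' @export
edge_scenario_config <- function(n_rows = 50, n_cols = 50, seed = 1,
                                 shift = TRUE, variables = NULL,
                                 truth = NULL) {
  prec_target <- if (shift) c(1500, 2500) else c(500, 1000)
  cfg <- list(
    n_rows = n_rows, n_cols = n_cols, cell_size = 8, origin = c(0, 0),
    seed = seed,
    variables = list(
      Alti = list(train = c(200, 2500), target = c(200, 2500),
                  autocorrelation = 5),
      Prec = list(train = c(500, 1000), target = prec_target,
                  autocorrelation = 5),
      SRad = list(train = c(3, 6), target = c(3, 6), autocorrelation = 5),
      DPre = list(train = c(80, 180), target = c(80, 180),
                  autocorrelation = 5),
      Lati = list(train = c(42.5, 43.2), target = c(42.5, 43.2))
    ),
    truth = simulation_truth(
      intercept = -11.5,
      coefficients = c(Prec = 0.01, DPre = 0.03),
      response = list(Prec = list(type = "clamp", upper = 1000))
    )
  )
  if (!is.null(variables)) cfg$variables <- variables
  if (!is.null(truth)) cfg$truth <- truth
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
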