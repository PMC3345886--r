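#' Fitted (or published) model coefficients
#'
#' A `coefficient_set` is the unit of model transference: the logit-scale
#' intercept and named slopes, the iteration at which each variable entered
#' during stepwise selection, the training presence/absence counts `n1`,
#' `n0` that anchor the favourability transform, and optionally the
#' per-variable training covariate ranges used for extrapolation
#' diagnostics.
#'
#' @param intercept Logit-scale intercept.
#' @param coefficients Named numeric vector of slopes.
#' @param inclusion_order Named integer vector (may be `NULL`): the rank at
#'   which each variable entered the model. Published tables occasionally
#'   print inconsistent ranks; they are stored as printed and flagged via
#'   `rank_consistent`.
#' @param n1,n0 Training presence/absence counts (`NA` when unknown, as for
#'   published coefficient tables that omit them).
#' @param label Free-text model label.
#' @param training_ranges Optional named list of length-2 ranges.
#' @param notes Optional free-text provenance notes.
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(intercept, coefficients,
                            inclusion_order = NULL, n1 = NA_integer_,
                            n0 = NA_integer_, label = "",
                            training_ranges = NULL, notes = NULL) {
  coefficients <- unlist(coefficients)
  if (length(coefficients) &&
      (is.null(names(coefficients)) || any(names(coefficients) == ""))) {
    stop("coefficients must be named by variable code", call. = FALSE)
  }
  rank_consistent <- TRUE
  if (!is.null(inclusion_order)) {
    inclusion_order <- unlist(inclusion_order)
    bad <- setdiff(names(inclusion_order), names(coefficients))
    if (length(bad)) {
      stop("inclusion_order names unknown variable(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ranks <- sort(as.integer(inclusion_order))
    rank_consistent <- identical(ranks, seq_along(ranks))
  }
  structure(
    list(intercept = as.numeric(intercept), coefficients = coefficients,
         inclusion_order = inclusion_order,
         rank_consistent = rank_consistent,
         n1 = as.integer(n1), n0 = as.integer(n0),
         label = label, training_ranges = training_ranges, notes = notes),
    class = "coefficient_set"
  )
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set> %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  intercept %.6g; %d variable(s)", x$intercept,
              length(x$coefficients)))
  if (!is.na(x$n1)) cat(sprintf("; n1=%d, n0=%d", x$n1, x$n0))
  cat("\n")
  if (length(x$coefficients)) {
    ord <- if (!is.null(x$inclusion_order)) {
      x$inclusion_order[names(x$coefficients)]
    } else rep(NA_integer_, length(x$coefficients))
    for (i in seq_along(x$coefficients)) {
      cat(sprintf("  %-8s %12.6g%s\n", names(x$coefficients)[i],
                  x$coefficients[i],
                  if (is.na(ord[i])) "" else sprintf("  (rank %d)", ord[i])))
    }
  }
  if (!x$rank_consistent) {
    cat("  note: inclusion ranks as printed are not a 1..k permutation\n")
  }
  invisible(x)
}

#' Logit-scale linear predictor on a grid
#'
#' Computes `y = intercept + sum(beta_i * x_i)` for every cell; masked
#' cells get `NA`.
#'
#' @param coefs A [coefficient_set()].
#' @param grid An [env_grid()] supplying every model variable.
#' @return Numeric vector, one value per cell.
#' @export
linear_predictor <- function(coefs, grid) {
  check_variables(grid, names(coefs$coefficients))
  y <- rep(coefs$intercept, nrow(grid$values))
  for (v in names(coefs$coefficients)) {
    y <- y + coefs$coefficients[[v]] * grid$values[, v]
  }
  y[!grid$mask] <- NA_real_
  unname(y)
}

#' Prevalence-corrected favourability transform
#'
#' Converts a logistic model's probability `P` into favourability
#' `F = (P/(1-P)) / (n1/n0 + P/(1-P))`: the odds of presence relative to
#' the odds expected at the training prevalence. `F = 0.5` exactly where
#' `P` equals the prevalence `n1/(n1+n0)`, so favourability values are
#' comparable across datasets with different prevalence. When
#' `n1 == n0` the transform is the identity.
#'
#' `P` is clamped to `[1e-12, 1 - 1e-12]` before forming the odds, so
#' extreme logits return 0 or 1 rather than `NaN`.
#'
#' @param P Probabilities in `[0, 1]` (vectorized).
#' @param n1,n0 Positive presence/absence counts.
#' @return Favourability values in `[0, 1]`.
#' @examples
#' favourability(0.8, 100, 300)   # 12/13
#' favourability(0.25, 100, 300)  # 0.5: P equals the prevalence
#' @export
favourability <- function(P, n1, n0) {
  if (is.na(n1) || is.na(n0) || n1 <= 0 || n0 <= 0) {
    stop("n1 and n0 must both be positive", call. = FALSE)
  }
  bad <- !is.na(P) & (P < 0 | P > 1)
  if (any(bad)) stop("P must lie in [0, 1]", call. = FALSE)
  Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  odds <- Pc / (1 - Pc)
  odds / (n1 / n0 + odds)
}

#' Favourability surface for a model on a grid
#'
#' Composes [linear_predictor()], the logistic inverse link, and
#' [favourability()] per cell. On the logit scale the transform is
#' `F = exp(y) / (n1/n0 + exp(y))`.
#'
#' @param coefs A [coefficient_set()]; must carry `n1`, `n0` when
#'   `prevalence_source = "training"`.
#' @param grid An [env_grid()].
#' @param prevalence_source `"training"` (use `coefs$n1`, `coefs$n0`) or a
#'   length-2 numeric `c(n1, n0)` to re-anchor on other counts.
#' @return An object of class `fav_surface`: the grid geometry plus
#'   per-cell `F` in `[0, 1]` and a `provenance` record.
#' @export
favourability_surface <- function(coefs, grid,
                                  prevalence_source = "training") {
  if (identical(prevalence_source, "training")) {
    n1 <- coefs$n1; n0 <- coefs$n0
    if (is.na(n1) || is.na(n0)) {
      stop("coefficient set carries no training n1/n0; supply counts via ",
           "prevalence_source", call. = FALSE)
    }
    src <- "training"
  } else {
    n1 <- prevalence_source[1]; n0 <- prevalence_source[2]
    src <- sprintf("supplied (n1=%s, n0=%s)", n1, n0)
  }
  y <- linear_predictor(coefs, grid)
  F_ <- favourability(stats::plogis(y), n1, n0)
  structure(
    list(n_rows = grid$n_rows, n_cols = grid$n_cols,
         cell_size = grid$cell_size, origin = grid$origin,
         F = F_, mask = grid$mask,
         provenance = list(model = coefs$label, prevalence_source = src,
                           n1 = n1, n0 = n0)),
    class = "fav_surface"
  )
}

#' @export
print.fav_surface <- function(x, ...) {
  cat(sprintf("<fav_surface> %d x %d cells; F in [%.3f, %.3f]\n",
              x$n_rows, x$n_cols, min(x$F, na.rm = TRUE),
              max(x$F, na.rm = TRUE)))
  cat(sprintf("  model: %s; prevalence source: %s\n",
              if (nzchar(x$provenance$model)) x$provenance$model else
                "(unlabelled)", x$provenance$prevalence_source))
  invisible(x)
}

#' Fit a presence/absence logistic GLM on a grid
#'
#' Maximum-likelihood logistic regression of cell outcomes on the listed
#' grid variables. Covariates are standardized internally for a
#' well-conditioned IRLS fit and coefficients back-transformed to raw
#' units, so the reported scales match the covariates' natural units
#' (e.g. mm of precipitation). Convergence uses a relative deviance
#' tolerance of 1e-8 with at most 100 iterations.
#'
#' Complete separation is reported as a warning (condition class
#' `fav_separation`) listing the diverging coefficients; a singular design
#' (constant or aliased covariates) is an error.
#'
#' @param grid An [env_grid()].
#' @param det A [detection_grid()] aligned with `grid` (masked or `NA`
#'   cells are dropped).
#' @param variables Character vector of grid variable codes; empty for an
#'   intercept-only fit.
#' @param label Label stored on the result.
#' @return A [coefficient_set()] with `n1`, `n0`, training ranges,
#'   raw-scale standard errors in `$std_errors`, and the fitted `glm`
#'   attached as attribute `"fit"`.
#' @export
fit_logistic <- function(grid, det, variables = grid$variables,
                         label = "fitted model") {
  dat <- model_frame(grid, det, variables)
  if (sum(dat$y == 1L) < 1L || sum(dat$y == 0L) < 1L) {
    stop("need at least one presence and one absence", call. = FALSE)
  }
  scaled <- scale_covariates(dat, variables)
  fit <- withCallingHandlers(
    stats::glm(stats::reformulate(c("1", scaled$safe_names), "y"),
               family = stats::binomial(), data = scaled$frame,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  beta <- unscale_coefficients(fit, scaled, variables)
  diverging <- names(beta$slopes)[abs(stats::coef(fit)[-1]) > 15]
  if (length(diverging)) {
    warning(structure(
      class = c("fav_separation", "warning", "condition"),
      list(message = paste0(
        "possible complete separation; diverging coefficient(s): ",
        paste(diverging, collapse = ", ")), call = sys.call())))
  }
  ranges <- lapply(variables, function(v) range(dat[[v]]))
  names(ranges) <- variables
  out <- coefficient_set(
    intercept = beta$intercept, coefficients = beta$slopes,
    n1 = sum(dat$y == 1L), n0 = sum(dat$y == 0L), label = label,
    training_ranges = if (length(variables)) ranges else NULL)
  out$std_errors <- beta$std_errors
  attr(out, "fit") <- fit
  out
}

# assemble the modelling frame over usable (unmasked, surveyed) cells
model_frame <- function(grid, det, variables) {
  check_variables(grid, variables)
  if (length(det$outcomes) != nrow(grid$values)) {
    stop("detection grid and environmental grid differ in cell count",
         call. = FALSE)
  }
  keep <- grid$mask & !is.na(det$outcomes)
  if (!any(keep)) stop("no usable cells", call. = FALSE)
  dat <- as.data.frame(grid$values[keep, variables, drop = FALSE])
  names(dat) <- variables
  dat$y <- det$outcomes[keep]
  dat
}

# standardize covariates; syntactically safe column names for the formula
scale_covariates <- function(dat, variables) {
  safe <- if (length(variables)) paste0("V", seq_along(variables)) else
    character(0)
  frame <- data.frame(y = dat$y)
  centers <- scales <- numeric(length(variables))
  for (i in seq_along(variables)) {
    x <- dat[[variables[i]]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("covariate ", variables[i],
           " is constant over the usable cells (singular design)",
           call. = FALSE)
    }
    centers[i] <- mean(x); scales[i] <- s
    frame[[safe[i]]] <- (x - centers[i]) / s
  }
  list(frame = frame, safe_names = safe, centers = centers, scales = scales)
}

unscale_coefficients <- function(fit, scaled, variables) {
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("singular design: aliased coefficient(s) ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  slopes_std <- co[-1]
  slopes <- if (length(variables)) slopes_std / scaled$scales else numeric(0)
  names(slopes) <- variables
  intercept <- co[1] - sum(slopes * scaled$centers)
  # raw-scale coefficients are a linear map A of the standardized ones;
  # propagate the covariance for raw-scale standard errors
  p <- length(variables)
  A <- diag(1, p + 1L)
  if (p) {
    A[1L, -1L] <- -scaled$centers / scaled$scales
    diag(A)[-1L] <- 1 / scaled$scales
  }
  V <- A %*% stats::vcov(fit) %*% t(A)
  se <- sqrt(diag(V))
  names(se) <- c("(Intercept)", variables)
  list(intercept = unname(intercept), slopes = slopes, std_errors = se)
}

#' Forward stepwise variable selection with inclusion-order bookkeeping
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' with the smallest likelihood-ratio p-value (1-df chi-square on the
#' deviance drop), while that p-value is below `entry_alpha`; with
#' `criterion = "AIC"` it instead adds the candidate with the largest AIC
#' improvement while any candidate improves AIC. The returned
#' `inclusion_order` records the iteration at which each variable entered.
#'
#' @param grid An [env_grid()].
#' @param det A [detection_grid()].
#' @param candidates Non-empty character vector of candidate variables.
#' @param entry_alpha Likelihood-ratio entry threshold (default 0.05).
#' @param criterion `"LRT"` (default) or `"AIC"`.
#' @param label Label for the returned model.
#' @return A [coefficient_set()] for the selected model.
#' @export
forward_stepwise <- function(grid, det, candidates, entry_alpha = 0.05,
                             criterion = c("LRT", "AIC"),
                             label = "stepwise model") {
  criterion <- match.arg(criterion)
  if (!length(candidates)) {
    stop("candidates must be non-empty", call. = FALSE)
  }
  check_variables(grid, candidates)
  selected <- character(0)
  order_in <- integer(0)
  current <- suppressWarnings(fit_logistic(grid, det, character(0)))
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    dev0 <- attr(current, "fit")$deviance
    aic0 <- attr(current, "fit")$aic
    best <- NULL; best_stat <- Inf
    for (v in remaining) {
      trial <- tryCatch(
        suppressWarnings(fit_logistic(grid, det, c(selected, v))),
        error = function(e) NULL)
      if (is.null(trial)) next
      stat <- if (criterion == "LRT") {
        stats::pchisq(dev0 - attr(trial, "fit")$deviance, df = 1,
                      lower.tail = FALSE)
      } else {
        attr(trial, "fit")$aic - aic0  # negative = improvement
      }
      if (stat < best_stat) { best_stat <- stat; best <- v }
    }
    qualifies <- if (criterion == "LRT") {
      !is.null(best) && best_stat < entry_alpha
    } else {
      !is.null(best) && best_stat < 0
    }
    if (!qualifies) break
    selected <- c(selected, best)
    order_in <- c(order_in, length(selected))
    current <- suppressWarnings(fit_logistic(grid, det, selected))
  }
  names(order_in) <- selected
  final <- fit_logistic(grid, det, selected, label = label)
  out <- coefficient_set(
    intercept = final$intercept, coefficients = final$coefficients,
    inclusion_order = if (length(order_in)) order_in else NULL,
    n1 = final$n1, n0 = final$n0, label = label,
    training_ranges = final$training_ranges)
  attr(out, "fit") <- attr(final, "fit")
  out
}
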