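test_that("linear_predictor is an exact dot product per cell", {
  set.seed(4)
  vals <- matrix(runif(50 * 5, -2, 2), 50, 5,
                 dimnames = list(NULL, paste0("V", 1:5)))
  g <- env_grid(5, 10, vals)
  beta <- runif(5, -1, 1)
  names(beta) <- colnames(vals)
  cs <- coefficient_set(0.7, beta)
  y <- linear_predictor(cs, g)
  # term-by-term oracle accumulated in a different order
  y_oracle <- vapply(seq_len(50), function(i) {
    sum(rev(beta * vals[i, ])) + 0.7
  }, numeric(1))
  expect_lt(max(abs(y - y_oracle)), 1e-12)

  # constant model
  cs0 <- coefficient_set(3.2, stats::setNames(numeric(5), colnames(vals)))
  expect_equal(linear_predictor(cs0, g), rep(3.2, 50))

  # masked cells propagate NA; missing variable is named in the error
  gm <- env_grid(5, 10, vals, mask = c(FALSE, rep(TRUE, 49)))
  expect_true(is.na(linear_predictor(cs, gm)[1]))
  expect_error(linear_predictor(coefficient_set(0, c(Zed = 1)), g), "Zed")
})

test_that("the published transferred model's constant is its all-zero logit", {
  sp <- desman_models()$spanish
  g <- env_grid(1, 1, matrix(0, 1, length(sp$coefficients),
                             dimnames = list(NULL, names(sp$coefficients))))
  expect_equal(linear_predictor(sp, g), -44.63)
})

test_that("favourability transform identities and hand values hold", {
  P <- seq(0, 1, length.out = 1000)
  # prevalence 0.5 makes the correction the identity
  for (n in c(1, 10, 250)) {
    expect_lte(max(abs(favourability(P, n, n) - P)), 1e-12)
  }
  # P at the training prevalence maps to 0.5
  pairs <- cbind(n1 = c(1, 5, 10, 100, 100, 250, 37, 999, 3, 60),
                 n0 = c(9, 5, 90, 300, 100, 50, 63, 1, 997, 140))
  for (i in seq_len(nrow(pairs))) {
    n1 <- pairs[i, 1]; n0 <- pairs[i, 2]
    expect_lt(abs(favourability(n1 / (n1 + n0), n1, n0) - 0.5), 1e-12)
  }
  # hand evaluation: odds 4 against reference odds 1/3
  expect_equal(favourability(0.8, 100, 300), 12 / 13, tolerance = 1e-12)

  # strictly increasing in P; strictly decreasing in prevalence odds
  Fv <- favourability(seq(0.01, 0.99, 0.01), 80, 120)
  expect_true(all(diff(Fv) > 0))
  expect_true(favourability(0.4, 50, 150) > favourability(0.4, 150, 50))

  expect_error(favourability(0.5, 0, 10), "positive")
  expect_error(favourability(-0.1, 10, 10), "\\[0, 1\\]")
  expect_error(favourability(1.1, 10, 10), "\\[0, 1\\]")
})

test_that("favourability_surface composes the two steps exactly", {
  g <- uniform_grid(10, 10, c("A", "B"), list(c(-1, 1), c(0, 5)), seed = 2)
  cs <- coefficient_set(-1, c(A = 1.5, B = -0.4), n1 = 120L, n0 = 380L,
                        label = "toy")
  surf <- favourability_surface(cs, g)
  expect_s3_class(surf, "fav_surface")
  expect_true(all(surf$F >= 0 & surf$F <= 1))
  # unfused oracle
  y <- -1 + 1.5 * g$values[, "A"] - 0.4 * g$values[, "B"]
  F_oracle <- (exp(y)) / (120 / 380 + exp(y))
  expect_lt(max(abs(surf$F - F_oracle)), 1e-12)

  # constant y = 0 with balanced prevalence: F = 0.5 everywhere
  cs0 <- coefficient_set(0, c(A = 0), n1 = 5L, n0 = 5L)
  expect_equal(favourability_surface(cs0, g)$F, rep(0.5, 100))

  # monotone in any covariate with positive coefficient
  g2 <- g
  g2$values[1, "A"] <- g$values[1, "A"] + 0.5
  expect_gt(favourability_surface(cs, g2)$F[1], surf$F[1])

  # prevalence must come from somewhere
  cs_na <- coefficient_set(0, c(A = 1))
  expect_error(favourability_surface(cs_na, g), "n1/n0")
  expect_equal(favourability_surface(cs_na, g, c(10, 10))$provenance$n1, 10)
})

test_that("intercept-only fit returns the log-odds of prevalence", {
  g <- uniform_grid(10, 20, "X", list(c(0, 1)), seed = 8)
  set.seed(21)
  det <- detection_grid(rbinom(200, 1, 0.3))
  cs <- fit_logistic(g, det, character(0))
  expect_equal(cs$intercept, log(det$n1 / det$n0), tolerance = 1e-6)
  expect_length(cs$coefficients, 0)
})

test_that("null covariates come out near zero and truth is recovered", {
  g <- uniform_grid(50, 100, c("A", "B"), list(c(-2, 2), c(-2, 2)),
                    seed = 31)
  # outcomes independent of covariates
  set.seed(77)
  det <- detection_grid(rbinom(5000, 1, 0.4))
  cs <- fit_logistic(g, det)
  for (v in c("A", "B")) {
    expect_lt(abs(cs$coefficients[[v]]), 3 * cs$std_errors[[v]])
  }

  # single-replicate parameter recovery at the documented truth
  truth <- simulation_truth(-0.3, c(A = 0.8, B = -0.5))
  det2 <- simulate_presence(g, truth, seed = 5)
  cs2 <- fit_logistic(g, det2)
  expect_lt(abs(cs2$coefficients[["A"]] - 0.8), 3 * cs2$std_errors[["A"]])
  expect_lt(abs(cs2$coefficients[["B"]] + 0.5), 3 * cs2$std_errors[["B"]])
  expect_lt(abs(cs2$intercept + 0.3), 3 * cs2$std_errors[["(Intercept)"]])
  expect_identical(cs2$n1 + cs2$n0, 5000L)
  expect_equal(cs2$training_ranges$A, range(g$values[, "A"]))
})

test_that("degenerate designs fail loudly", {
  g <- uniform_grid(5, 10, "X", list(c(0, 1)), seed = 3)
  const <- env_grid(5, 10, cbind(X = g$values[, 1], C = rep(1, 50)))
  set.seed(1)
  det <- detection_grid(rbinom(50, 1, 0.5))
  expect_error(fit_logistic(const, det, c("X", "C")), "constant")
  expect_error(fit_logistic(g, detection_grid(rep(1, 50)), "X"),
               "at least one")
  # perfectly separated outcome triggers the separation warning
  det_sep <- detection_grid(as.integer(g$values[, "X"] > 0.5))
  expect_warning(fit_logistic(g, det_sep, "X"), class = "fav_separation")
})

test_that("forward stepwise ranks a strong signal first and respects alpha", {
  g <- uniform_grid(40, 50, c("S", "N1", "N2"),
                    list(c(-1, 1), c(-1, 1), c(-1, 1)), seed = 12)
  truth <- simulation_truth(0, c(S = 2))
  det <- simulate_presence(g, truth, seed = 9)
  cs <- forward_stepwise(g, det, c("N1", "S", "N2"))
  expect_identical(cs$inclusion_order[["S"]], 1L)
  expect_true(cs$rank_consistent)

  # nothing can enter at alpha = 0
  cs0 <- forward_stepwise(g, det, c("S", "N1"), entry_alpha = 0)
  expect_length(cs0$coefficients, 0)
  expect_equal(cs0$intercept, log(det$n1 / det$n0), tolerance = 1e-6)

  expect_error(forward_stepwise(g, det, character(0)), "non-empty")

  # AIC mode also finds the signal variable first
  cs_aic <- forward_stepwise(g, det, c("N1", "S", "N2"),
                             criterion = "AIC")
  expect_identical(cs_aic$inclusion_order[["S"]], 1L)
})
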