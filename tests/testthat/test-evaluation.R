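test_that("confusion matrices tally hand-checkable cases", {
  d <- detection_grid(c(1, 1, 1, 0, 0, 0))
  cm <- confusion_matrix(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), d, 0.5)
  expect_identical(c(cm$TP, cm$FN, cm$FP, cm$TN), c(2L, 1L, 1L, 2L))

  # perfect classifier: scores equal to outcomes
  cm_perf <- confusion_matrix(c(1, 1, 1, 0, 0, 0), d, 0.5)
  expect_identical(c(cm_perf$FP, cm_perf$FN), c(0L, 0L))

  # everything predicted absent
  cm_none <- confusion_matrix(rep(0.1, 6), d, 0.5)
  expect_identical(c(cm_none$TP, cm_none$FP), c(0L, 0L))
  expect_identical(c(cm_none$FN, cm_none$TN), c(d$n1, d$n0))

  # ties at the threshold classify as present
  cm_tie <- confusion_matrix(rep(0.5, 6), d, 0.5)
  expect_identical(cm_tie$TP + cm_tie$FP, 6L)

  expect_error(confusion_matrix(c(NA, NA), detection_grid(c(1, 0)), 0.5),
               "no evaluable")
  expect_error(confusion_matrix(c(1, 0), d, 0.5), "cell count")
  expect_error(confusion_matrix(c(1, 0), detection_grid(c(1, 0)), NaN),
               "finite")
})

test_that("threshold indices reproduce hand arithmetic and the oracle", {
  cm <- confusion_matrix(c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30)),
                         detection_grid(c(rep(1, 50), rep(0, 50))), 0.5)
  expect_identical(c(cm$TP, cm$FN, cm$FP, cm$TN), c(40L, 10L, 20L, 30L))
  idx <- threshold_indices(cm)
  expect_identical(idx$sensitivity, 0.8)
  expect_identical(idx$specificity, 0.6)
  expect_identical(idx$pcc, 0.7)
  expect_equal(idx$ppp, 2 / 3, tolerance = 1e-15)
  expect_identical(idx$npp, 0.75)
  expect_identical(idx$tss, 0.8 + 0.6 - 1)
  expect_equal(idx$tss, 0.4, tolerance = 1e-12)

  # randomized matrices against the single-division rational oracle
  set.seed(17)
  for (r in 1:20) {
    counts <- as.list(sample(0:500, 4, replace = TRUE))
    names(counts) <- c("TP", "FP", "TN", "FN")
    cm_r <- structure(c(counts, list(threshold = 0.5,
                                     score_kind = "favourability")),
                      class = "confusion_matrix")
    got <- threshold_indices(cm_r)
    want <- indices_oracle(counts$TP, counts$FP, counts$TN, counts$FN)
    for (k in names(want)) {
      if (is.na(want[[k]])) expect_true(is.na(got[[k]]))
      else expect_equal(got[[k]], want[[k]], tolerance = 1e-13)
    }
  }
})

test_that("degenerate and boundary matrices behave as documented", {
  mk <- function(TP, FP, TN, FN) {
    structure(list(TP = TP, FP = FP, TN = TN, FN = FN, threshold = 0.5,
                   score_kind = "favourability"),
              class = "confusion_matrix")
  }
  # perfect
  perf <- threshold_indices(mk(10, 0, 10, 0))
  expect_true(all(unlist(perf[c("sensitivity", "specificity", "pcc",
                                "ppp", "npp", "tss", "kappa")]) == 1))
  # predictions independent of truth: TSS = 0, kappa = 0
  rand <- threshold_indices(mk(30, 30, 20, 20))
  expect_equal(rand$tss, 0)
  expect_equal(rand$kappa, 0)
  # zero denominators reported as NA, never as 0
  none <- threshold_indices(mk(0, 0, 10, 10))
  expect_true(is.na(none$ppp))
  expect_identical(none$sensitivity, 0)
})

test_that("rank AUC equals exhaustive pair counting, with ties", {
  d <- detection_grid(c(1, 1, 0, 0))
  expect_identical(auc(c(0.9, 0.8, 0.2, 0.1), d), 1)       # separated
  expect_identical(auc(rep(0.4, 4), d), 0.5)               # all ties
  expect_error(auc(1:4, detection_grid(rep(1, 4))), "at least one")

  set.seed(23)
  for (r in 1:100) {
    n <- sample(10:500, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(y) == 0 || sum(y) == n) y[sample(n, 2)] <- c(0, 1)
    # coarse score grid injects plenty of ties
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    expect_lt(abs(auc(s, detection_grid(y)) - auc_bruteforce(s, y)),
              1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(5)
  y <- rbinom(300, 1, 0.4)
  y[1:2] <- c(0, 1)
  logit <- rnorm(300)
  d <- detection_grid(y)
  a_logit <- auc(logit, d)
  a_fav <- auc(favourability(plogis(logit), 70, 230), d)
  expect_equal(a_fav, a_logit, tolerance = 1e-12)
})

test_that("evaluate_model returns an internally consistent report", {
  g <- uniform_grid(40, 50, c("A", "B"), list(c(-2, 2), c(-2, 2)),
                    seed = 61)
  truth <- simulation_truth(0, c(A = 1.2, B = -0.8))
  det <- simulate_presence(g, truth, seed = 62)
  cs <- fit_logistic(g, det, label = "truth-shaped")
  rep_ <- evaluate_model(cs, g, det)
  expect_gt(rep_$auc, 0.5)
  expect_gt(rep_$tss, 0)
  expect_equal(rep_$tss, rep_$sensitivity + rep_$specificity - 1)
  expect_identical(rep_$confusion$TP + rep_$confusion$FP +
                     rep_$confusion$TN + rep_$confusion$FN, 2000L)

  # a pure-noise model hovers near chance on a fresh large sample
  noise <- coefficient_set(0, c(A = 0, B = 0.001), n1 = det$n1,
                           n0 = det$n0, label = "noise")
  expect_lt(abs(evaluate_model(noise, g, det)$auc - 0.5), 0.1)
})

test_that("threshold policies resolve as documented", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.3, 0.7, 0.4, 0.3, 0.2, 0.2, 0.1, 0.1)
  d <- detection_grid(y)
  expect_identical(resolve_threshold(s, d, "default"), 0.5)
  expect_identical(resolve_threshold(s, d, 0.42), 0.42)
  expect_equal(resolve_threshold(s, d, "prevalence"), 0.3)
  th <- resolve_threshold(s, d, "maxTSS")
  best <- threshold_indices(confusion_matrix(s, d, th))$tss
  others <- sapply(unique(s), function(t_) {
    threshold_indices(confusion_matrix(s, d, t_))$tss
  })
  expect_gte(best, max(others))
  expect_error(resolve_threshold(s, d, "nope"), "unknown threshold")
})

test_that("TSS shifts less than kappa when absences are thinned", {
  g <- uniform_grid(40, 50, "X", list(c(-2, 2)), seed = 91)
  det <- simulate_presence(g, simulation_truth(0, c(X = 1.5)), seed = 92)
  cs <- fit_logistic(g, det)
  surf <- favourability_surface(cs, g)
  base <- threshold_indices(confusion_matrix(surf$F, det, 0.5))
  d_tss <- d_kap <- numeric(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    abs_idx <- which(det$outcomes == 0L)
    drop <- sample(abs_idx, length(abs_idx) %/% 2)
    y2 <- det$outcomes
    y2[drop] <- NA_integer_
    thin <- threshold_indices(confusion_matrix(surf$F,
                                               detection_grid(y2), 0.5))
    d_tss[s] <- abs(thin$tss - base$tss)
    d_kap[s] <- abs(thin$kappa - base$kappa)
  }
  expect_lt(mean(d_tss), mean(d_kap))
})
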