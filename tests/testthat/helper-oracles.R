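# Independent oracles used across the suite. These deliberately take the
# slow, direct route (pair enumeration, neighbour sums, single-division
# rationals) so they share no code path with the implementation.

# lag-1 Moran's I with rook neighbours on a matrix
morans_i <- function(m) {
  z <- m - mean(m)
  num <- 0
  W <- 0
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          num <- num + z[i, j] * z[ii, jj]
          W <- W + 1
        }
      }
    }
  }
  (length(m) / W) * num / sum(z^2)
}

# exhaustive O(n1*n0) pairwise AUC with half-credit ties
auc_bruteforce <- function(scores, outcomes) {
  sp <- scores[outcomes == 1]
  sa <- scores[outcomes == 0]
  cmp <- outer(sp, sa, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# index suite as single divisions of exact integer-valued doubles
indices_oracle <- function(TP, FP, TN, FN) {
  n <- TP + FP + TN + FN
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(TP, TP + FN)
  spec <- div(TN, TN + FP)
  pe_num <- (TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)
  kappa <- if (n > 0 && n^2 - pe_num != 0) {
    (n * (TP + TN) - pe_num) / (n^2 - pe_num)
  } else NA_real_
  list(sensitivity = sens, specificity = spec,
       pcc = div(TP + TN, n), ppp = div(TP, TP + FP),
       npp = div(TN, TN + FN), tss = sens + spec - 1, kappa = kappa)
}

# grid with i.i.d. uniform covariates, for fitting tests
uniform_grid <- function(n_rows, n_cols, vars, ranges, seed) {
  layers <- lapply(seq_along(vars), function(i) {
    generate_covariate_field(n_rows, n_cols, vars[i], ranges[[i]],
                             autocorrelation_range = 0,
                             seed = seed + i * 1000L)
  })
  do.call(combine_grids, layers)
}

# matrix view of a per-cell vector (row-major storage, top row first)
as_matrix_grid <- function(grid, values) {
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}
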