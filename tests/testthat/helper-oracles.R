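# Independent oracles used across tests. These deliberately avoid the package
# code paths they are checking.

# normal-equation least squares (vs the package's QR route)
ols_normal_equations <- function(y, X) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# coupon-collector completeness probability by inclusion-exclusion
coupon_collector_exact <- function(n_draws, n_classes) {
  j <- 0:n_classes
  sum((-1)^j * choose(n_classes, j) * (1 - j / n_classes)^n_draws)
}

# brute-force evaluation of the factorial effect model for one genotype
effect_model_brute <- function(origins, model) {
  x <- as.numeric(origins == "Col")
  val <- model$mu + sum(model$a * x)
  for (nm in names(model$two_way)) {
    idx <- as.integer(sub("Chr", "", strsplit(nm, ":")[[1]]))
    val <- val + model$two_way[[nm]] * prod(x[idx])
  }
  for (nm in names(model$three_way)) {
    idx <- as.integer(sub("Chr", "", strsplit(nm, ":")[[1]]))
    val <- val + model$three_way[[nm]] * prod(x[idx])
  }
  val
}

# all 'stable' two-way term sets under the per-term alpha rule: every included
# term significant when fitted, every excluded term non-significant when added
# singly (mains always retained)
stable_twoway_sets <- function(y, geno, alpha) {
  X <- design_matrix(geno, max_order = 2)
  two <- grep(":", colnames(X), value = TRUE)
  base <- setdiff(colnames(X), two)
  p_of <- function(cols, term) {
    f <- fit_linear(y, X[, cols, drop = FALSE])
    unname(f$p[term])
  }
  subsets <- unlist(lapply(0:length(two), function(k)
    utils::combn(two, k, simplify = FALSE)), recursive = FALSE)
  keep <- Filter(function(S) {
    cols <- c(base, S)
    ok_in <- all(vapply(S, function(tm) p_of(cols, tm) <= alpha, TRUE))
    ok_out <- all(vapply(setdiff(two, S),
                         function(tm) p_of(c(cols, tm), tm) > alpha, TRUE))
    ok_in && ok_out
  }, subsets)
  lapply(keep, sort)
}

# two-marker RIL haplotype distribution: P(Col at q | flanking genotypes),
# composing adjacent-interval switch probabilities of the RIL Markov chain
ril_conditional_brute <- function(xL, xR, dL, dR) {
  rL <- ril_recomb(dL); rR <- ril_recomb(dR)
  p_path <- function(xq) {
    pa <- if (xL == xq) 1 - rL else rL
    pb <- if (xq == xR) 1 - rR else rR
    pa * pb
  }
  p_path(1) / (p_path(1) + p_path(0))
}
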