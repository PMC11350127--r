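#' Ordinary least squares on a named design matrix
#'
#' The regression engine behind all factorial model comparisons. Solves by QR
#' decomposition and refuses rank-deficient designs, naming the collinear
#' columns.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix with named columns (including an intercept
#'   column when wanted).
#' @return list: \code{coefficients}, \code{se}, \code{t}, \code{p} (named),
#'   \code{sigma2}, \code{df_residual}, \code{rss}, \code{r2},
#'   \code{logLik}, \code{fitted}, \code{XtX_inv}.
#' @export
fit_linear <- function(y, X) {
  if (length(y) != nrow(X)) stop("rows of X must match length of y")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) rss / df else NA_real_
  XtX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  list(coefficients = beta, se = se, t = tval, p = pval,
       sigma2 = sigma2, df_residual = df, rss = rss,
       r2 = if (tss > 0) 1 - rss / tss else 1,
       logLik = ll, fitted = fitted, XtX_inv = XtX_inv)
}

#' Backward elimination of design-matrix terms
#'
#' Repeatedly refits the model and drops the least significant unprotected
#' candidate term until all remaining candidates are significant. Two drop
#' rules are available: \code{"f"} (default) tests each candidate by partial
#' F-test (for a single column the partial F equals the squared t statistic)
#' against \code{alpha}; \code{"aic"} uses a penalised-likelihood rule in
#' which a term is droppable when its likelihood-ratio statistic falls below
#' the chi-square(1) quantile at \code{alpha} — an AIC-style criterion whose
#' penalty multiplier is calibrated to the same per-term level. Deterministic
#' tie-break: largest p (smallest statistic), then smallest |t|, then first
#' term name in lexicographic order.
#'
#' @param y response vector.
#' @param X full design matrix (with intercept column).
#' @param candidates column names eligible for elimination.
#' @param alpha per-term significance threshold.
#' @param criterion \code{"f"} or \code{"aic"}.
#' @return list: \code{kept} (surviving candidates), \code{fit} (final
#'   \code{\link{fit_linear}}), \code{columns} (final column names),
#'   \code{trace} (data.frame of drops).
#' @keywords internal
backward_eliminate <- function(y, X, candidates, alpha, criterion = "f") {
  cols <- colnames(X)
  trace <- data.frame(term = character(0), p = numeric(0), stringsAsFactors = FALSE)
  repeat {
    fit <- fit_linear(y, X[, cols, drop = FALSE])
    cand <- intersect(cols, candidates)
    if (!length(cand)) break
    if (criterion == "aic") {
      # likelihood-ratio statistic of dropping each candidate singly
      n <- length(y)
      lr <- vapply(cand, function(tm) {
        f0 <- fit_linear(y, X[, setdiff(cols, tm), drop = FALSE])
        if (fit$rss <= 0) return(if (f0$rss > 0) Inf else 0)
        n * log(f0$rss / fit$rss)
      }, 0)
      p <- stats::pchisq(lr, 1, lower.tail = FALSE)
    } else {
      p <- fit$p[cand]
    }
    p[is.na(p)] <- 1  # zero coefficient with zero residual: no contribution
    t_ <- abs(fit$t[cand])
    t_[is.na(t_)] <- 0
    drop_ok <- which(p > alpha)
    if (!length(drop_ok)) break
    # least significant first: max p, then min |t|, then lexicographic
    ord <- order(-p[drop_ok], t_[drop_ok], cand[drop_ok])
    victim <- cand[drop_ok][ord[1L]]
    trace <- rbind(trace, data.frame(term = victim, p = unname(p[victim]),
                                     stringsAsFactors = FALSE))
    cols <- setdiff(cols, victim)
  }
  list(kept = intersect(colnames(X), intersect(cols, candidates)),
       fit = fit, columns = cols, trace = trace)
}

.interaction_order <- function(term) lengths(regmatches(term, gregexpr(":", term))) + 1L

#' Verify the marginality structure of a term set
#'
#' @param terms character vector of model terms (no intercept).
#' @return TRUE when every lower-order term nested under each interaction is
#'   present; otherwise FALSE with attribute \code{missing}.
#' @export
check_marginality <- function(terms) {
  need <- unique(unlist(lapply(terms, nested_terms)))
  miss <- setdiff(need, terms)
  if (length(miss)) structure(FALSE, missing = miss) else TRUE
}

#' Stage 1: select significant three-way chromosome interactions
#'
#' Starting from the full factorial model (all main, two- and three-way
#' terms), backward-eliminates three-way terms by partial F-test until all
#' survivors are significant at \code{alpha}. Lower-order terms are never
#' candidates at this stage.
#'
#' @param y per-plant (spatially corrected) trait values.
#' @param geno chromosome-origin matrix, one row per plant.
#' @param alpha per-term threshold (default the multiple-testing-corrected
#'   5e-5).
#' @param criterion drop rule, \code{"f"} (partial F-test, default) or
#'   \code{"aic"} (see \code{\link{backward_eliminate}}).
#' @return character vector of surviving three-way terms, with attribute
#'   \code{trace}.
#' @export
select_threeway <- function(y, geno, alpha = 5e-5, criterion = "f") {
  X <- design_matrix(geno, max_order = 3)
  cand <- colnames(X)[.interaction_order(colnames(X)) == 3L]
  res <- backward_eliminate(y, X, cand, alpha, criterion)
  structure(res$kept, trace = res$trace)
}

#' Stage 2: select significant two-way interactions
#'
#' Backward elimination over two-way terms, protecting (by the marginality
#' principle) every pair nested under a selected three-way interaction: those
#' pairs are retained unconditionally and never tested.
#'
#' @inheritParams select_threeway
#' @param S3 selected three-way terms from \code{\link{select_threeway}}.
#' @return character vector of two-way terms in the model (protected plus
#'   surviving), with attribute \code{trace}.
#' @export
select_twoway <- function(y, geno, S3, alpha = 5e-5, criterion = "f") {
  Xall <- design_matrix(geno, max_order = 3)
  ord <- .interaction_order(colnames(Xall))
  two <- colnames(Xall)[ord == 2L]
  keep_cols <- c(colnames(Xall)[ord <= 2L], S3)
  X <- Xall[, keep_cols, drop = FALSE]
  protected <- intersect(two, unique(unlist(lapply(S3, nested_terms))))
  cand <- setdiff(two, protected)
  res <- backward_eliminate(y, X, cand, alpha, criterion)
  structure(union(protected, res$kept), trace = res$trace)
}

#' Stage 3: final factorial model with pruned main effects
#'
#' Fits the model containing the selected interactions and all main effects,
#' backward-eliminates main effects not protected by a selected interaction,
#' tests the final model against the intercept-only model (overall F), and
#' computes coefficients with 95\% confidence intervals, the final and
#' main-effects-only R-squared, and model-predicted class means for each
#' selected interaction (effect-plot data, delta-method CIs).
#'
#' @inheritParams select_threeway
#' @param S2,S3 selected two- and three-way term sets.
#' @param alpha_main threshold for pruning unprotected main effects.
#' @return object of class \code{"csl_selection"}.
#' @export
final_model <- function(y, geno, S2, S3, alpha_main = 5e-5, criterion = "f") {
  Xall <- design_matrix(geno, max_order = 3)
  ord <- .interaction_order(colnames(Xall))
  mains <- setdiff(colnames(Xall)[ord == 1L], "intercept")
  cols <- c("intercept", mains, S2, S3)
  X <- Xall[, cols, drop = FALSE]
  protected <- intersect(mains, unique(unlist(lapply(c(S2, S3), nested_terms))))
  cand <- setdiff(mains, protected)
  res <- backward_eliminate(y, X, cand, alpha_main, criterion)
  fit <- res$fit
  terms <- setdiff(res$columns, "intercept")
  stopifnot(isTRUE(check_marginality(terms)))

  # overall test: final model VI against the intercept-only model V
  fit0 <- fit_linear(y, Xall[, "intercept", drop = FALSE])
  k <- length(terms)
  overall <- if (k > 0) {
    Fst <- ((fit0$rss - fit$rss) / k) / (fit$rss / fit$df_residual)
    c(F = Fst, df1 = k, df2 = fit$df_residual,
      p = stats::pf(Fst, k, fit$df_residual, lower.tail = FALSE))
  } else c(F = 0, df1 = 0, df2 = fit0$df_residual, p = 1)

  fit_main <- fit_linear(y, Xall[, c("intercept", mains), drop = FALSE])
  tcrit <- stats::qt(0.975, fit$df_residual)
  coefs <- data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$se), t = unname(fit$t), p = unname(fit$p),
    ci_lower = unname(fit$coefficients - tcrit * fit$se),
    ci_upper = unname(fit$coefficients + tcrit * fit$se),
    stringsAsFactors = FALSE, row.names = NULL
  )
  interactions <- c(S2, S3)
  cm <- lapply(interactions, function(tm)
    .class_means(tm, fit, Xall[, res$columns, drop = FALSE], geno))
  names(cm) <- interactions

  structure(list(
    terms = terms, S2 = S2, S3 = S3,
    coefficients = coefs,
    r2 = fit$r2, r2_main_only = fit_main$r2,
    overall = overall,
    class_means = cm,
    sigma = sqrt(fit$sigma2),
    trace = res$trace,
    fit = fit
  ), class = "csl_selection")
}

# model-predicted mean of each 0/1 corner class of an interaction term,
# averaging the remaining predictors over the observed plants in the class
.class_means <- function(term, fit, X, geno) {
  idx <- term_indices(term)
  xo <- origin_indicator(geno[, idx, drop = FALSE])
  corners <- expand.grid(rep(list(0:1), length(idx)))
  tcrit <- stats::qt(0.975, fit$df_residual)
  out <- lapply(seq_len(nrow(corners)), function(i) {
    corner <- as.integer(corners[i, ])
    rows <- which(colSums(t(xo) != corner) == 0L)
    lab <- paste(sprintf("Chr%d^%s", idx, ifelse(corner == 1, "Col", "Ler")),
                 collapse = "/")
    if (!length(rows))
      return(data.frame(class = lab, n = 0L, mean = NA_real_,
                        se = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_))
    cvec <- colMeans(X[rows, , drop = FALSE])
    m <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$XtX_inv %*% cvec) * fit$sigma2)
    data.frame(class = lab, n = length(rows), mean = m, se = se,
               ci_lower = m - tcrit * se, ci_upper = m + tcrit * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @method print csl_selection
#' @export
print.csl_selection <- function(x, ...) {
  cat("Factorial epistasis decomposition\n")
  cat("  selected terms:", if (length(x$terms)) paste(x$terms, collapse = " + ")
      else "(intercept only)", "\n")
  cat(sprintf("  R2 = %.3f (main effects only: %.3f)\n", x$r2, x$r2_main_only))
  cat(sprintf("  overall F = %.2f on %d and %d df, p = %.3g\n",
              x$overall["F"], x$overall["df1"], x$overall["df2"],
              x$overall["p"]))
  invisible(x)
}

#' Full staged epistasis decomposition of a CSL trial
#'
#' Runs the three-stage backward-elimination cascade on per-plant values:
#' three-way selection, two-way selection under marginality protection, and
#' the final pruned model with the overall test.
#'
#' @param records per-plant data with \code{line_id} and the value column.
#' @param panel CSL panel table mapping \code{line_id} to chromosome origins.
#' @param value_col which column of \code{records} to analyse (default the
#'   spatially \code{corrected} values).
#' @param alpha3,alpha2,alpha_main per-stage thresholds.
#' @param criterion drop rule for every stage: \code{"f"} or \code{"aic"}.
#' @return a \code{"csl_selection"} object (see \code{\link{final_model}}).
#' @export
epistasis_decomposition <- function(records, panel, value_col = "corrected",
                                    alpha3 = 5e-5, alpha2 = 5e-5,
                                    alpha_main = alpha2, criterion = "f") {
  y <- records[[value_col]]
  if (is.null(y)) stop("records have no column '", value_col, "'")
  geno <- .align_genotypes(records$line_id, panel)
  S3 <- select_threeway(y, geno, alpha = alpha3, criterion = criterion)
  S2 <- select_twoway(y, geno, S3, alpha = alpha2, criterion = criterion)
  final_model(y, geno, S2, S3, alpha_main = alpha_main, criterion = criterion)
}

.align_genotypes <- function(line_ids, panel) {
  m <- panel_matrix(panel)
  miss <- setdiff(unique(line_ids), rownames(m))
  if (length(miss))
    stop("records reference lines absent from the panel: ",
         paste(utils::head(miss, 5), collapse = ", "))
  m[line_ids, , drop = FALSE]
}

#' Chromosome main effects within one recurrent background
#'
#' Analyses a recurrent parent plus its single-chromosome substitution lines:
#' fits the main-effects model and backward-eliminates chromosomes that do
#' not contribute significantly, against the intercept-only baseline.
#'
#' @param y per-plant values.
#' @param geno chromosome-origin matrix, one row per plant; all lines must be
#'   one parent plus sCSLs in that parent's background.
#' @param alpha per-chromosome threshold.
#' @return list: \code{background}, \code{selected} chromosomes (term names),
#'   \code{coefficients} table, \code{r2}, \code{trace}.
#' @export
scsl_main_effects <- function(y, geno, alpha = 1e-3) {
  ids <- apply(geno, 1L, genotype_id)
  uniq <- !duplicated(ids)
  cls <- apply(geno[uniq, , drop = FALSE], 1L, classify_genotype)
  labs <- vapply(cls, `[[`, "", "label")
  bgs <- vapply(cls, `[[`, "", "background")
  if (any(labs == "multi_substitution"))
    stop("input contains multi-substitution lines; expected one parent plus its sCSLs")
  bg <- unique(bgs[labs == "single_substitution"])
  if (length(bg) > 1L)
    stop("mixed backgrounds in input: ", paste(bg, collapse = ", "))
  X <- design_matrix(geno, max_order = 1)
  mains <- setdiff(colnames(X), "intercept")
  res <- backward_eliminate(y, X, mains, alpha)
  fit <- res$fit
  tcrit <- stats::qt(0.975, fit$df_residual)
  list(background = if (length(bg)) bg else bgs[1],
       selected = res$kept,
       coefficients = data.frame(
         term = names(fit$coefficients),
         estimate = unname(fit$coefficients), se = unname(fit$se),
         p = unname(fit$p),
         ci_lower = unname(fit$coefficients - tcrit * fit$se),
         ci_upper = unname(fit$coefficients + tcrit * fit$se),
         stringsAsFactors = FALSE),
       r2 = fit$r2, trace = res$trace)
}

#' Chromosome-by-background interaction test on reciprocal sCSLs
#'
#' Fits the chromosome x background model on both parents plus all ten
#' reciprocal single-chromosome substitution lines:
#' \deqn{y_{ir} = \mu + \sum_k a_k x_{ik} + b z_i + \sum_k c_k x_{ik} z_i
#'   + \epsilon_{ir},}
#' where \eqn{z_i} is 0 for the Ler background and 1 for Col. The interaction
#' terms \eqn{c_k} are backward-eliminated at \code{alpha}; the main effects
#' and the background effect are retained by marginality.
#'
#' @param y per-plant values.
#' @param geno chromosome-origin matrix, one row per plant (both parents and
#'   all reciprocal sCSLs must be present).
#' @param alpha interaction threshold (default the multiple-testing-corrected
#'   1e-3).
#' @return list: \code{selected} interaction terms (e.g. \code{"Chr5:BG"}),
#'   \code{coefficients} table, \code{r2}, \code{trace}.
#' @export
background_interaction <- function(y, geno, alpha = 1e-3) {
  n <- ncol(geno)
  cls <- apply(geno, 1L, classify_genotype)
  labs <- vapply(cls, `[[`, "", "label")
  if (any(labs == "multi_substitution"))
    stop("input contains multi-substitution lines; expected parents plus all sCSLs")
  bgs <- vapply(cls, `[[`, "", "background")
  # completeness: each chromosome substituted in each background
  x <- origin_indicator(geno)
  for (k in seq_len(n)) {
    for (b in c("Col", "Ler")) {
      want <- labs == "single_substitution" & bgs == b &
        x[, k] == (b == "Ler")  # substituted chromosome carries the other origin
      if (!any(want)) {
        sub <- if (b == "Col") "Ler" else "Col"
        stop("missing reciprocal sCSL: Chr", k, "^", sub, " in ", b,
             " background")
      }
    }
  }
  z <- as.numeric(bgs == "Col")
  X1 <- design_matrix(geno, max_order = 1)
  Xint <- x * z
  colnames(Xint) <- paste0("Chr", seq_len(n), ":BG")
  X <- cbind(X1, BG = z, Xint)
  res <- backward_eliminate(y, X, colnames(Xint), alpha)
  fit <- res$fit
  tcrit <- stats::qt(0.975, fit$df_residual)
  list(selected = res$kept,
       coefficients = data.frame(
         term = names(fit$coefficients),
         estimate = unname(fit$coefficients), se = unname(fit$se),
         p = unname(fit$p),
         ci_lower = unname(fit$coefficients - tcrit * fit$se),
         ci_upper = unname(fit$coefficients + tcrit * fit$se),
         stringsAsFactors = FALSE),
       r2 = fit$r2, trace = res$trace)
}
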