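#' Spatial adjustment of field-trial phenotypes
#'
#' Removes environmental field structure from per-plant records and produces
#' genotype-level adjusted and shrunken means. The model is a standard REML
#' mixed model:
#' fixed overall mean, population and block effects plus a low-degree
#' tensor-product polynomial surface in (row, col); random row, random column
#' and random genotype-within-population effects, with a separate genetic
#' variance per population (heterogeneous genetic variances, e.g. CSL vs RIL
#' or the reciprocal NIL panels).
#'
#' Corrected plant values are the raw values minus the fitted environmental
#' part (block + surface + row + column), retaining the genotypic signal;
#' shrunken genotype means are the population mean plus the genotype BLUP.
#'
#' When the data carry essentially no within-genotype variation (a noiseless
#' simulation) the REML residual variance is on the boundary and the mixed
#' model is skipped: corrected values equal the raw values and genotype means
#' are the plain line means.
#'
#' @param records plant records (\code{line_id}, \code{block}, \code{row},
#'   \code{col}, \code{value}; a \code{trait} column is allowed and must be
#'   constant).
#' @param populations named character vector or data.frame
#'   (\code{line_id}, \code{population}) mapping lines to populations;
#'   defaults to a single population.
#' @param surface_degree polynomial degree of the smooth surface in each of
#'   row and column (tensor product).
#' @return object of class \code{"csl_adjusted"}: list with \code{plants}
#'   (records plus \code{corrected}), \code{genotypes} (\code{line_id},
#'   \code{population}, \code{n}, \code{adjusted_mean}, \code{shrunken_mean}),
#'   \code{varcomp} (genetic variance per population, row, column, residual,
#'   surface variance) and \code{fit} (the lme4 fit, or NULL on the
#'   degenerate path).
#' @export
fit_spatial <- function(records, populations = NULL, surface_degree = 3) {
  need <- c("line_id", "block", "row", "col", "value")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if ("trait" %in% names(records) && length(unique(records$trait)) > 1L)
    stop("records mix traits; filter to a single trait first")
  df <- records[!is.na(records$value), , drop = FALSE]
  if (nrow(df) < 3L) stop("too few records")
  if (length(unique(paste(df$row, df$col))) == 1L)
    stop("degenerate design: all records share one grid cell")
  tab <- table(df$line_id)
  if (max(tab) < 2L)
    stop("no replication: every genotype has a single plant")

  if (is.null(populations)) {
    pop <- stats::setNames(rep("pop1", length(unique(df$line_id))),
                           unique(df$line_id))
  } else if (is.data.frame(populations)) {
    pop <- stats::setNames(populations$population, populations$line_id)
  } else pop <- populations
  miss <- setdiff(unique(df$line_id), names(pop))
  if (length(miss))
    stop("lines without a population assignment: ",
         paste(utils::head(miss, 5), collapse = ", "))
  df$population <- unname(pop[df$line_id])

  line_means <- tapply(df$value, df$line_id, mean)
  within_var <- stats::var(df$value - line_means[df$line_id])
  scale2 <- max(stats::var(df$value), .Machine$double.eps)

  if (!is.finite(within_var) || within_var < 1e-10 * scale2) {
    # noiseless degenerate path: nothing environmental to estimate
    df$corrected <- df$value
    gt <- .genotype_table(df, line_means[names(line_means)],
                          shrunken = line_means[names(line_means)], pop = pop)
    pops <- unique(df$population)
    gvar <- vapply(pops, function(p) {
      v <- line_means[names(line_means) %in% names(pop)[pop == p]]
      if (length(v) > 1L) stats::var(v) else 0
    }, 0)
    return(structure(list(
      plants = df, genotypes = gt,
      varcomp = list(genetic = as.list(gvar), row = 0, col = 0,
                     residual = 0, surface = 0),
      fit = NULL), class = "csl_adjusted"))
  }

  df$.rowf <- factor(df$row)
  df$.colf <- factor(df$col)
  df$.blockf <- factor(df$block)
  df$.linef <- factor(df$line_id)
  # sum-to-zero contrasts keep the fitted environmental part near zero mean
  stats::contrasts(df$.blockf) <- stats::contr.sum(nlevels(df$.blockf))
  pops <- sort(unique(df$population))
  fixed <- "value ~ 1"
  if (length(pops) > 1L) {
    df$.popf <- factor(df$population)
    stats::contrasts(df$.popf) <- stats::contr.sum(nlevels(df$.popf))
    fixed <- paste(fixed, "+ .popf")
  }
  if (nlevels(df$.blockf) > 1L) fixed <- paste(fixed, "+ .blockf")
  deg <- surface_degree
  surf_term <- sprintf("poly(row, %d) * poly(col, %d)", deg, deg)
  fixed <- paste(fixed, "+", surf_term)
  rand <- "(1 | .rowf) + (1 | .colf)"
  if (length(pops) > 1L) {
    for (p in pops) {
      v <- paste0(".g_", make.names(p))
      df[[v]] <- as.numeric(df$population == p)
      rand <- paste0(rand, " + (0 + ", v, " | .linef)")
    }
  } else rand <- paste(rand, "+ (1 | .linef)")
  form <- stats::as.formula(paste(fixed, "+", rand))
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))

  # environmental part: block + surface fixed effects, row/col BLUPs
  X <- stats::model.matrix(fit)
  beta <- lme4::fixef(fit)
  asgn <- attr(X, "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  env_terms <- which(labs %in% c(".blockf") | grepl("poly\\(", labs))
  env_cols <- which(asgn %in% env_terms)
  env_fixed <- if (length(env_cols))
    drop(X[, env_cols, drop = FALSE] %*% beta[env_cols]) else 0
  re <- lme4::ranef(fit)
  u_row <- stats::setNames(re$.rowf[[1]], rownames(re$.rowf))
  u_col <- stats::setNames(re$.colf[[1]], rownames(re$.colf))
  env <- env_fixed + u_row[as.character(df$row)] + u_col[as.character(df$col)]
  df$corrected <- df$value - unname(env)

  # genotype-level means
  pop_part <- {
    int_cols <- which(asgn %in% c(0L, which(labs == ".popf")))
    drop(X[, int_cols, drop = FALSE] %*% beta[int_cols])
  }
  pop_mean <- tapply(pop_part, df$line_id, mean)
  u_geno <- rep(0, nlevels(df$.linef))
  names(u_geno) <- levels(df$.linef)
  if (length(pops) > 1L) {
    for (p in pops) {
      v <- paste0(".g_", make.names(p))
      rg <- re$.linef[[v]]
      lines_p <- levels(df$.linef)[levels(df$.linef) %in% names(pop)[pop == p]]
      u_geno[lines_p] <- stats::setNames(rg, rownames(re$.linef))[lines_p]
    }
  } else {
    u_geno[rownames(re$.linef)] <- re$.linef[[1]]
  }
  adj_mean <- tapply(df$corrected, df$line_id, mean)
  shrunk <- pop_mean[names(adj_mean)] + u_geno[names(adj_mean)]
  gt <- .genotype_table(df, adj_mean, shrunken = shrunk, pop = pop)

  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp, nm = NA) {
    # lme4 suffixes repeated grouping factors (.linef, .linef.1, ...)
    i <- startsWith(vc$grp, grp) & (is.na(nm) | vc$var1 == nm)
    i[is.na(i)] <- FALSE
    if (any(i)) vc$vcov[i][1] else 0
  }
  gvar <- if (length(pops) > 1L) {
    stats::setNames(lapply(pops, function(p)
      getv(".linef", paste0(".g_", make.names(p)))), pops)
  } else list(pop1 = getv(".linef"))
  varcomp <- list(
    genetic = gvar,
    row = getv(".rowf"), col = getv(".colf"),
    residual = vc$vcov[vc$grp == "Residual"][1],
    surface = stats::var(as.numeric(env_fixed))
  )
  structure(list(plants = df, genotypes = gt, varcomp = varcomp, fit = fit),
            class = "csl_adjusted")
}

.genotype_table <- function(df, adj_mean, shrunken, pop) {
  ids <- names(adj_mean)
  data.frame(
    line_id = ids,
    population = unname(pop[ids]),
    n = as.integer(table(df$line_id)[ids]),
    adjusted_mean = unname(adj_mean),
    shrunken_mean = unname(shrunken[ids]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @method print csl_adjusted
#' @export
print.csl_adjusted <- function(x, ...) {
  cat("Spatially adjusted trial: ", nrow(x$plants), " plants, ",
      nrow(x$genotypes), " genotypes\n", sep = "")
  cat("Variance components:\n")
  for (p in names(x$varcomp$genetic))
    cat(sprintf("  genetic[%s] = %.4g\n", p, x$varcomp$genetic[[p]]))
  cat(sprintf("  row = %.4g  col = %.4g  residual = %.4g  surface = %.4g\n",
              x$varcomp$row, x$varcomp$col, x$varcomp$residual,
              x$varcomp$surface))
  invisible(x)
}

#' Extract corrected data from a spatial fit
#'
#' Plant level returns per-replicate spatially corrected values (the input
#' for the CSL epistasis decomposition, preserving residual degrees of
#' freedom); genotype level returns shrunken genotype means (the input for
#' RIL/NIL linkage scans).
#'
#' @param adjusted a \code{\link{fit_spatial}} result.
#' @param level \code{"plant"} or \code{"genotype"}.
#' @return data.frame.
#' @export
corrected_table <- function(adjusted, level = c("plant", "genotype")) {
  level <- match.arg(level)
  if (level == "plant") {
    keep <- intersect(c("line_id", "block", "row", "col", "trait",
                        "value", "corrected"), names(adjusted$plants))
    out <- adjusted$plants[, keep, drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    adjusted$genotypes
  }
}
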