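#' Expected allele dosages on an evaluation grid
#'
#' Computes, for every line and every grid position, the conditional
#' expectation of the Col-allele indicator given the flanking marker
#' genotypes, using RIL recombination fractions (Haldane map function with
#' the selfing expansion R = 2c/(1+2c)). The grid is the union of all marker
#' positions and a regular walk at most \code{step_cM} apart, so dosages are
#' exactly 0 or 1 at genotyped markers. Beyond the outermost markers of a
#' chromosome the dosage extrapolates from the nearest marker.
#'
#' @param panel recombinant panel (\code{\link{ril_panel}} /
#'   \code{\link{nil_panel}}).
#' @param map marker map.
#' @param step_cM maximum spacing of evaluation positions.
#' @param chroms chromosomes to include (default all on the map).
#' @return object of class \code{"genetic_predictors"}: list with \code{grid}
#'   (data.frame \code{chrom}, \code{cM}, \code{is_marker}), \code{dosage}
#'   (lines x positions matrix in [0,1]) and \code{map}.
#' @export
genetic_predictors <- function(panel, map, step_cM = 5, chroms = NULL) {
  validate_map(map)
  m <- origin_indicator(marker_matrix(panel, map))
  if (is.null(chroms)) chroms <- unique(map$chrom)
  grids <- list(); dos <- list()
  for (k in chroms) {
    sel <- which(map$chrom == k)
    if (length(sel) == 0L) { warning("no markers on chromosome ", k); next }
    pos <- map$cM[sel]
    grid <- sort(unique(c(pos, seq(min(pos), max(pos), by = step_cM))))
    xk <- m[, sel, drop = FALSE]
    dk <- matrix(NA_real_, nrow(m), length(grid))
    for (j in seq_along(grid)) {
      q <- grid[j]
      iR <- findInterval(q, pos, left.open = TRUE) + 1L
      iL <- findInterval(q, pos)
      if (iL >= 1L && pos[iL] == q) { dk[, j] <- xk[, iL]; next }
      if (iL < 1L) {             # left of first marker
        r <- ril_recomb(pos[1L] - q)
        dk[, j] <- xk[, 1L] * (1 - r) + (1 - xk[, 1L]) * r
      } else if (iR > length(pos)) {  # right of last marker
        r <- ril_recomb(q - pos[length(pos)])
        dk[, j] <- xk[, length(pos)] * (1 - r) + (1 - xk[, length(pos)]) * r
      } else {
        rL <- ril_recomb(q - pos[iL]); rR <- ril_recomb(pos[iR] - q)
        xL <- xk[, iL]; xR <- xk[, iR]
        pL1 <- ifelse(xL == 1, 1 - rL, rL)   # P(path L -> Col at q)
        p1R <- ifelse(xR == 1, 1 - rR, rR)   # P(Col at q -> R)
        pL0 <- 1 - pL1; p0R <- 1 - p1R
        dk[, j] <- pL1 * p1R / (pL1 * p1R + pL0 * p0R)
      }
    }
    grids[[length(grids) + 1L]] <-
      data.frame(chrom = k, cM = grid, is_marker = grid %in% pos)
    dos[[length(dos) + 1L]] <- dk
  }
  grid <- do.call(rbind, grids)
  dosage <- do.call(cbind, dos)
  rownames(dosage) <- rownames(m)
  colnames(dosage) <- sprintf("c%d_%g", grid$chrom, grid$cM)
  structure(list(grid = grid, dosage = dosage, map = map),
            class = "genetic_predictors")
}

#' Li-Ji effective number of tests and genome-wide threshold
#'
#' Estimates the effective number of independent tests from the eigenvalues
#' of the marker correlation matrix: each eigenvalue contributes
#' \eqn{I(\lambda \ge 1) + (\lambda - \lfloor\lambda\rfloor)}. By default
#' the computation is per chromosome and summed; \code{per_chrom = FALSE}
#' uses the whole-genome matrix. The per-test level is the Sidak correction
#' \eqn{\alpha_p = 1 - (1-\alpha)^{1/M_{eff}}}.
#'
#' @param panel recombinant panel.
#' @param map marker map.
#' @param alpha genome-wide significance level.
#' @param per_chrom compute M_eff per chromosome and sum (default).
#' @return list: \code{M_eff}, \code{alpha_per_test}, \code{threshold}
#'   (the \eqn{-\log_{10}} significance threshold), \code{dropped}
#'   (monomorphic markers removed).
#' @export
li_ji_threshold <- function(panel, map, alpha = 0.05, per_chrom = TRUE) {
  x <- origin_indicator(marker_matrix(panel, map))
  if (nrow(x) < 3L || ncol(x) < 2L) stop("need >= 3 lines and >= 2 markers")
  keep <- apply(x, 2L, function(v) stats::var(v) > 0)
  dropped <- map$marker[!keep]
  if (length(dropped))
    warning("dropping monomorphic marker(s): ",
            paste(utils::head(dropped, 5), collapse = ", "))
  x <- x[, keep, drop = FALSE]
  mp <- map[keep, , drop = FALSE]
  meff_of <- function(mat) {
    if (ncol(mat) == 1L) return(1)
    lam <- eigen(stats::cor(mat), symmetric = TRUE, only.values = TRUE)$values
    lam[lam < 0] <- 0
    sum(as.numeric(lam >= 1) + (lam - floor(lam)))
  }
  M_eff <- if (per_chrom) {
    sum(vapply(unique(mp$chrom), function(k)
      meff_of(x[, mp$chrom == k, drop = FALSE]), 0))
  } else meff_of(x)
  alpha_p <- 1 - (1 - alpha)^(1 / M_eff)
  list(M_eff = M_eff, alpha_per_test = alpha_p,
       threshold = -log10(alpha_p), dropped = dropped)
}

#' Single-pass QTL scan by dosage regression
#'
#' At each grid position, regresses the phenotype on the local expected
#' allele dosage plus the dosages of the supplied cofactor positions,
#' excluding any cofactor on the same chromosome within
#' \code{cofactor_window} cM of the tested position. The reported statistic
#' is the partial F-test p-value of the dosage term as \eqn{-\log_{10}(p)}.
#'
#' @param pheno named numeric vector of genotype-level phenotypes (names are
#'   line ids; must be a subset of the predictor lines).
#' @param predictors a \code{\link{genetic_predictors}} object.
#' @param cofactors data.frame with columns \code{chrom}, \code{cM} of
#'   cofactor positions (must lie on the predictor grid), or NULL.
#' @param cofactor_window cofactor exclusion window in cM.
#' @return data.frame: \code{chrom}, \code{cM}, \code{effect} (Col-allele
#'   effect), \code{se}, \code{minus_log10_p}.
#' @export
scan_qtl <- function(pheno, predictors, cofactors = NULL,
                     cofactor_window = 50) {
  grid <- predictors$grid
  miss <- setdiff(names(pheno), rownames(predictors$dosage))
  if (length(miss))
    stop("phenotyped lines missing from predictors: ",
         paste(utils::head(miss, 5), collapse = ", "))
  D <- predictors$dosage[names(pheno), , drop = FALSE]
  cof_idx <- integer(0)
  if (!is.null(cofactors) && nrow(cofactors)) {
    cof_idx <- vapply(seq_len(nrow(cofactors)), function(i) {
      j <- which(grid$chrom == cofactors$chrom[i] & grid$cM == cofactors$cM[i])
      if (!length(j)) stop("cofactor at chr", cofactors$chrom[i], ":",
                           cofactors$cM[i], " cM is not on the predictor grid")
      j[1L]
    }, 0L)
  }
  n <- length(pheno)
  out <- data.frame(chrom = grid$chrom, cM = grid$cM,
                    effect = NA_real_, se = NA_real_,
                    minus_log10_p = NA_real_)
  for (j in seq_len(nrow(grid))) {
    use_cof <- cof_idx[!(grid$chrom[cof_idx] == grid$chrom[j] &
                           abs(grid$cM[cof_idx] - grid$cM[j]) < cofactor_window)]
    X <- cbind(intercept = 1, dosage = D[, j],
               if (length(use_cof)) D[, use_cof, drop = FALSE])
    if (stats::var(D[, j]) < 1e-12) next  # monomorphic position
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      # drop collinear cofactor columns, keep the tested dosage
      keep <- qrX$pivot[seq_len(qrX$rank)]
      if (!(2L %in% keep)) next
      X <- X[, sort(keep), drop = FALSE]
    }
    f <- fit_linear(pheno, X)
    out$effect[j] <- f$coefficients["dosage"]
    out$se[j] <- f$se["dosage"]
    lp <- -stats::pt(abs(f$t["dosage"]), f$df_residual,
                     lower.tail = FALSE, log.p = TRUE) / log(10) - log10(2)
    out$minus_log10_p[j] <- lp
  }
  out
}

#' Greedy peak selection from a scan profile
#'
#' @param profile a \code{\link{scan_qtl}} result.
#' @param threshold \eqn{-\log_{10}(p)} significance threshold.
#' @param min_sep minimum separation between selected QTLs on one chromosome
#'   (cM).
#' @return data.frame of selected peaks (\code{chrom}, \code{cM},
#'   \code{minus_log10_p}, \code{effect}).
#' @keywords internal
select_peaks <- function(profile, threshold, min_sep = 30) {
  pr <- profile[!is.na(profile$minus_log10_p), , drop = FALSE]
  picked <- pr[0, , drop = FALSE]
  repeat {
    cand <- pr[pr$minus_log10_p > threshold, , drop = FALSE]
    if (nrow(picked)) {
      ok <- vapply(seq_len(nrow(cand)), function(i) {
        same <- picked$chrom == cand$chrom[i]
        !any(same & abs(picked$cM - cand$cM[i]) < min_sep)
      }, TRUE)
      cand <- cand[ok, , drop = FALSE]
    }
    if (!nrow(cand)) break
    picked <- rbind(picked, cand[which.max(cand$minus_log10_p), , drop = FALSE])
  }
  picked[order(picked$chrom, picked$cM), , drop = FALSE]
}

#' Composite interval mapping by iterated cofactor scans
#'
#' Alternates between scanning and QTL selection: an initial single-QTL scan
#' selects peaks above the threshold (respecting the minimum separation);
#' selected QTLs then enter the model as cofactors and the genome is
#' rescanned, until the QTL set is stable or \code{max_rounds} is reached.
#' Effect signs follow the +Col / +Ler convention (positive effect = Col
#' allele increases the trait).
#'
#' @inheritParams scan_qtl
#' @param threshold genome-wide \eqn{-\log_{10}(p)} threshold (e.g. from
#'   \code{\link{li_ji_threshold}}).
#' @param min_sep minimum QTL separation (cM).
#' @param max_rounds maximum scan/select iterations.
#' @param drop support-interval drop in \eqn{-\log_{10}(p)} units.
#' @return object of class \code{"scan_result"}: list with \code{profile}
#'   (final scan), \code{qtls} (peak table with signs and support
#'   intervals), \code{threshold}, \code{rounds}, \code{stable}.
#' @export
cim_iterate <- function(pheno, predictors, threshold, cofactor_window = 50,
                        min_sep = 30, max_rounds = 10, drop = 2) {
  qtls <- NULL
  profile <- scan_qtl(pheno, predictors, NULL, cofactor_window)
  stable <- FALSE
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    new_qtls <- select_peaks(profile, threshold, min_sep)
    key <- function(q) paste(q$chrom, q$cM, collapse = ";")
    if (!is.null(qtls) && identical(key(new_qtls), key(qtls))) {
      stable <- TRUE
      break
    }
    qtls <- new_qtls
    if (rounds >= max_rounds) {
      warning("QTL set did not stabilise in ", max_rounds,
              " rounds; returning the last set")
      break
    }
    if (!nrow(qtls)) { stable <- TRUE; break }
    profile <- scan_qtl(pheno, predictors, qtls[, c("chrom", "cM")],
                        cofactor_window)
  }
  qtab <- if (nrow(qtls)) {
    si <- lapply(seq_len(nrow(qtls)), function(i) {
      pk <- profile[profile$chrom == qtls$chrom[i], , drop = FALSE]
      support_interval(pk, qtls$cM[i], drop = drop, map = predictors$map)
    })
    data.frame(
      chrom = qtls$chrom, peak_cM = qtls$cM,
      minus_log10_p = qtls$minus_log10_p,
      effect = qtls$effect,
      sign = ifelse(qtls$effect >= 0, "+Col", "+Ler"),
      si_left_cM = vapply(si, `[[`, 0, "left_cM"),
      si_right_cM = vapply(si, `[[`, 0, "right_cM"),
      si_left_bp = vapply(si, `[[`, 0, "left_bp"),
      si_right_bp = vapply(si, `[[`, 0, "right_bp"),
      stringsAsFactors = FALSE
    )
  } else data.frame(chrom = integer(0), peak_cM = numeric(0),
                    minus_log10_p = numeric(0), effect = numeric(0),
                    sign = character(0), si_left_cM = numeric(0),
                    si_right_cM = numeric(0), si_left_bp = numeric(0),
                    si_right_bp = numeric(0))
  structure(list(profile = profile, qtls = qtab, threshold = threshold,
                 rounds = rounds, stable = stable),
            class = "scan_result")
}

#' @method print scan_result
#' @export
print.scan_result <- function(x, ...) {
  cat("Composite interval mapping scan (threshold -log10 p = ",
      round(x$threshold, 2), ")\n", sep = "")
  if (nrow(x$qtls)) print(x$qtls) else cat("  no QTLs above threshold\n")
  invisible(x)
}

#' Support interval around a QTL peak
#'
#' The contiguous region around the peak where the \eqn{-\log_{10}(p)}
#' profile stays within \code{drop} units of the peak value (the analogue of
#' a 2-LOD support interval), clipped at the chromosome ends. Physical
#' coordinates are obtained by piecewise-linear interpolation of the marker
#' map when it carries \code{bp} positions (nearest-marker bp beyond the
#' outermost markers).
#'
#' @param profile_chrom scan profile rows for a single chromosome
#'   (\code{cM}, \code{minus_log10_p}).
#' @param peak_cM position of the peak (must be on the profile grid).
#' @param drop drop in \eqn{-\log_{10}(p)} units.
#' @param map optional marker map for bp interpolation.
#' @return list: \code{left_cM}, \code{right_cM}, \code{left_bp},
#'   \code{right_bp} (bp values NA without a physical map).
#' @export
support_interval <- function(profile_chrom, peak_cM, drop = 2, map = NULL) {
  pr <- profile_chrom[order(profile_chrom$cM), , drop = FALSE]
  j <- which(pr$cM == peak_cM)
  if (!length(j)) stop("peak position not on the profile grid")
  j <- j[1L]
  cut <- pr$minus_log10_p[j] - drop
  lo <- j
  while (lo > 1L && !is.na(pr$minus_log10_p[lo - 1L]) &&
         pr$minus_log10_p[lo - 1L] >= cut) lo <- lo - 1L
  hi <- j
  nmax <- nrow(pr)
  while (hi < nmax && !is.na(pr$minus_log10_p[hi + 1L]) &&
         pr$minus_log10_p[hi + 1L] >= cut) hi <- hi + 1L
  k <- unique(pr$chrom)[1]
  to_bp <- function(cm) {
    if (is.null(map) || !("bp" %in% names(map))) return(NA_real_)
    mk <- map[map$chrom == k, , drop = FALSE]
    if (!nrow(mk)) return(NA_real_)
    if (cm <= min(mk$cM)) return(mk$bp[which.min(mk$cM)])
    if (cm >= max(mk$cM)) return(mk$bp[which.max(mk$cM)])
    stats::approx(mk$cM, mk$bp, xout = cm, ties = mean)$y
  }
  list(left_cM = pr$cM[lo], right_cM = pr$cM[hi],
       left_bp = to_bp(pr$cM[lo]), right_bp = to_bp(pr$cM[hi]))
}

#' Per-marker NIL fine-mapping scan with reciprocal backgrounds
#'
#' For each background panel of single-chromosome recombinant NILs,
#' regresses the phenotype on the local marker genotype at every marker of
#' the target chromosome, applies a per-chromosome Li-Ji correction within
#' the panel, and reports a heatmap-ready effect/significance table plus the
#' drop-2 support interval around the strongest marker.
#'
#' @param panels named list of NIL panels (names = backgrounds, e.g.
#'   \code{"Col"}, \code{"Ler"}), each from \code{\link{nil_panel}}.
#' @param pheno named list of phenotype vectors matching \code{panels}
#'   (names = line ids).
#' @param map marker map.
#' @param alpha per-panel genome-wide (chromosome-wide) significance level.
#' @param drop support-interval drop.
#' @return list with \code{table} (marker x background rows: \code{marker},
#'   \code{cM}, \code{background}, \code{effect}, \code{minus_log10_p},
#'   \code{significant}) and \code{intervals} (per background: peak and
#'   support interval, NULL when nothing is significant).
#' @export
nil_scan <- function(panels, pheno, map, alpha = 0.05, drop = 2) {
  stopifnot(is.list(panels), is.list(pheno),
            identical(names(panels), names(pheno)))
  tabs <- list(); ivs <- list()
  for (bg in names(panels)) {
    panel <- panels[[bg]]
    target <- unique(panel$target_chrom)
    if (length(target) != 1L)
      stop("panel '", bg, "' is not a single-chromosome NIL panel")
    sel <- which(map$chrom == target)
    x <- origin_indicator(marker_matrix(panel, map))[, sel, drop = FALSE]
    y <- pheno[[bg]][panel$line_id]
    res <- data.frame(marker = map$marker[sel], cM = map$cM[sel],
                      background = bg, effect = NA_real_, se = NA_real_,
                      minus_log10_p = NA_real_, stringsAsFactors = FALSE)
    poly_cols <- which(apply(x, 2L, function(v) stats::var(v) > 0))
    for (j in poly_cols) {
      f <- fit_linear(y, cbind(intercept = 1, allele = x[, j]))
      res$effect[j] <- f$coefficients["allele"]
      res$se[j] <- f$se["allele"]
      res$minus_log10_p[j] <-
        -stats::pt(abs(f$t["allele"]), f$df_residual,
                   lower.tail = FALSE, log.p = TRUE) / log(10) - log10(2)
    }
    thr <- if (length(poly_cols) >= 2L) {
      sub_map <- map[sel[poly_cols], , drop = FALSE]
      li_ji_threshold(panel, sub_map, alpha = alpha)$threshold
    } else -log10(alpha)
    res$significant <- !is.na(res$minus_log10_p) & res$minus_log10_p > thr
    tabs[[bg]] <- res
    ivs[[bg]] <- if (any(res$significant)) {
      pk <- res$cM[which.max(res$minus_log10_p)]
      prof <- data.frame(chrom = target, cM = res$cM,
                         minus_log10_p = res$minus_log10_p)
      c(list(peak_cM = pk, threshold = thr),
        support_interval(prof[!is.na(prof$minus_log10_p), ], pk,
                         drop = drop, map = map))
    } else NULL
  }
  list(table = do.call(rbind, tabs), intervals = ivs)
}
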