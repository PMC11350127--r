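#' Construct a chromosome effect model
#'
#' The generative (and fitted) model for CSL phenotypes is a full-factorial
#' decomposition: for plant r of genotype i,
#' \deqn{y_{ir} = \mu + \sum_k a_k x_{ik} + \sum_{k<l} b_{kl} x_{ik} x_{il}
#'   + \sum_{k<l<m} c_{klm} x_{ik} x_{il} x_{im} + \epsilon_{ir},}
#' with \eqn{x_{ik} = 0} when chromosome k of genotype i is Ler and 1 when it
#' is Col, and \eqn{\epsilon_{ir} \sim N(0, \sigma_e^2)}.
#'
#' @param mu overall mean: the expected trait value of the all-Ler genotype
#'   (trait units).
#' @param a named or unnamed numeric vector of chromosome main effects
#'   \eqn{a_k}; length sets the chromosome number.
#' @param two_way named numeric vector of two-way interaction effects,
#'   names like \code{"Chr1:Chr3"} with increasing indices.
#' @param three_way named numeric vector of three-way effects, names like
#'   \code{"Chr1:Chr2:Chr5"}.
#' @param sigma_e residual standard deviation (trait units, >= 0).
#' @return object of class \code{"effect_model"}.
#' @export
effect_model <- function(mu, a, two_way = NULL, three_way = NULL, sigma_e = 1) {
  n <- length(a)
  if (n < 1) stop("need at least one chromosome main effect")
  if (sigma_e < 0) stop("sigma_e must be >= 0")
  names(a) <- paste0("Chr", seq_len(n))
  chk <- function(v, ord) {
    if (is.null(v) || length(v) == 0L) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(v)) || any(names(v) == ""))
      stop("interaction effects must be named, e.g. 'Chr1:Chr3'")
    for (nm in names(v)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      idx <- suppressWarnings(as.integer(sub("^Chr", "", parts)))
      if (anyNA(idx) || length(idx) != ord ||
          is.unsorted(idx, strictly = TRUE) ||
          any(idx < 1) || any(idx > n))
        stop("bad interaction term '", nm, "': need ", ord,
             " strictly increasing chromosome indices in 1..", n)
    }
    v
  }
  structure(list(mu = mu, a = a, two_way = chk(two_way, 2L),
                 three_way = chk(three_way, 3L),
                 sigma_e = sigma_e, n_chrom = n),
            class = "effect_model")
}

#' @method print effect_model
#' @export
print.effect_model <- function(x, ...) {
  cat("Chromosome effect model (", x$n_chrom, " chromosomes)\n", sep = "")
  cat("  mu =", x$mu, " sigma_e =", x$sigma_e, "\n")
  cat("  main effects:", paste(sprintf("%s=%g", names(x$a), x$a), collapse = " "), "\n")
  if (length(x$two_way))
    cat("  two-way:", paste(sprintf("%s=%g", names(x$two_way), x$two_way), collapse = " "), "\n")
  if (length(x$three_way))
    cat("  three-way:", paste(sprintf("%s=%g", names(x$three_way), x$three_way), collapse = " "), "\n")
  invisible(x)
}

#' Default trait models for the two study traits
#'
#' Fixed reference conditions for the simulated phenotyping experiment:
#' short-day flowering time (days after germination) and main stem length at
#' first flower opening (mm). Effect sizes are on realistic Arabidopsis
#' Col/Ler scales: flowering time is dominated by chromosomes 2 and 5 with
#' moderate two-way epistasis among chromosomes 1, 3 and 5; stem length is
#' dominated by chromosome 2 (the ERECTA chromosome) with an antagonistic
#' chromosome 3 x 5 interaction and a three-way interaction among chromosomes
#' 1, 2 and 5.
#'
#' @param trait \code{"flowering_time"} or \code{"main_stem_length"}.
#' @return an \code{\link{effect_model}}.
#' @export
default_effect_model <- function(trait = c("flowering_time", "main_stem_length")) {
  trait <- match.arg(trait)
  if (trait == "flowering_time") {
    effect_model(
      mu = 70,                                   # all-Ler baseline, days
      a = c(2, -5, 2.5, 1.5, -8),                # Col-allele effects, days
      two_way = c("Chr1:Chr3" = 2, "Chr1:Chr5" = 3, "Chr3:Chr5" = 3.5),
      sigma_e = 2
    )
  } else {
    effect_model(
      mu = 150,                                  # all-Ler baseline, mm
      a = c(25, 120, -20, 5, 30),                # Col-allele effects, mm
      two_way = c("Chr1:Chr2" = -30, "Chr1:Chr5" = -25, "Chr2:Chr5" = -35,
                  "Chr3:Chr5" = -40),
      three_way = c("Chr1:Chr2:Chr5" = -60),
      sigma_e = 20
    )
  }
}

#' Coefficient vector of an effect model on the design-matrix basis
#'
#' @param model an \code{\link{effect_model}}.
#' @param max_order interaction order of the target design matrix.
#' @return named numeric vector aligned to \code{\link{design_matrix}} columns
#'   (absent interactions are zero).
#' @export
model_coefficients <- function(model, max_order = 3) {
  n <- model$n_chrom
  X <- design_matrix(enumerate_panel(n)[1, , drop = FALSE], max_order = max_order)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta["intercept"] <- model$mu
  beta[names(model$a)] <- model$a
  for (nm in names(model$two_way))
    if (nm %in% names(beta)) beta[nm] <- model$two_way[[nm]]
  for (nm in names(model$three_way))
    if (nm %in% names(beta)) beta[nm] <- model$three_way[[nm]]
  beta
}

#' Expected trait value of genotypes under an effect model
#'
#' Evaluates the factorial model (no noise, no field effects) for each
#' genotype.
#'
#' @param panel panel data.frame or origin matrix.
#' @param model an \code{\link{effect_model}}.
#' @return named numeric vector of expected values, one per line.
#' @export
genotype_value <- function(panel, model) {
  m <- if (is.matrix(panel)) panel else panel_matrix(panel)
  if (ncol(m) != model$n_chrom)
    stop("genotypes have ", ncol(m), " chromosomes but model has ", model$n_chrom)
  X <- design_matrix(m, max_order = 3)
  beta <- model_coefficients(model, max_order = 3)
  stats::setNames(drop(X %*% beta[colnames(X)]), rownames(m))
}

#' Build a randomised complete block field layout
#'
#' Places lines on a rows x columns grid split column-wise into complete
#' blocks; within each block every line appears its per-block replicate count
#' at randomised positions. The default experiment is the combined CSL + RIL
#' trial: 32 CSLs at 4 replicates per block and 100 RILs at 1 per block, in
#' three 12 x 20 blocks of a 12 x 60 grid (684 plants, 36 empty positions).
#'
#' @param reps data.frame with columns \code{line_id} and
#'   \code{reps_per_block}.
#' @param n_rows,n_cols grid dimensions.
#' @param n_blocks number of complete blocks (columns are divided evenly).
#' @return data.frame of class \code{"field_layout"}: \code{row}, \code{col},
#'   \code{block}, \code{line_id} (NA for empty positions), \code{replicate}.
#' @export
make_layout <- function(reps, n_rows = 12, n_cols = 60, n_blocks = 3) {
  if (!all(c("line_id", "reps_per_block") %in% names(reps)))
    stop("reps needs columns line_id, reps_per_block")
  if (anyDuplicated(reps$line_id)) stop("duplicated line_id in reps")
  if (n_cols %% n_blocks != 0)
    stop("n_cols (", n_cols, ") must divide evenly into ", n_blocks, " blocks")
  block_cols <- n_cols / n_blocks
  capacity <- n_rows * block_cols
  demand <- sum(reps$reps_per_block)
  if (demand > capacity)
    stop("block capacity exceeded: ", demand, " plants requested per block, ",
         capacity, " positions available")
  per_block <- rep(reps$line_id, times = reps$reps_per_block)
  out <- lapply(seq_len(n_blocks), function(b) {
    cols <- (b - 1L) * block_cols + seq_len(block_cols)
    grid <- expand.grid(row = seq_len(n_rows), col = cols)
    ids <- rep(NA_character_, nrow(grid))
    ids[sample.int(nrow(grid), length(per_block))] <- sample(per_block)
    data.frame(row = grid$row, col = grid$col, block = b, line_id = ids,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$row, out$col), ]
  rownames(out) <- NULL
  # replicate number within line, in position order
  out$replicate <- NA_integer_
  occ <- !is.na(out$line_id)
  out$replicate[occ] <- stats::ave(seq_len(sum(occ)), out$line_id[occ],
                                   FUN = seq_along)
  class(out) <- c("field_layout", class(out))
  out
}

#' Default CSL + RIL trial layout specification
#'
#' @param csl_ids,ril_ids line identifiers for the CSL panel and RIL panel.
#' @param csl_reps_per_block,ril_reps_per_block per-block replicate counts
#'   (defaults 4 and 1: twelve and three total replicates over three blocks).
#' @return a \code{reps} data.frame for \code{\link{make_layout}}.
#' @export
default_trial_reps <- function(csl_ids, ril_ids = character(0),
                               csl_reps_per_block = 4, ril_reps_per_block = 1) {
  rbind(
    data.frame(line_id = csl_ids, reps_per_block = csl_reps_per_block,
               stringsAsFactors = FALSE),
    if (length(ril_ids))
      data.frame(line_id = ril_ids, reps_per_block = ril_reps_per_block,
                 stringsAsFactors = FALSE)
  )
}

#' Simulate a smooth spatial field surface
#'
#' Environmental trend over the grid: a sum of a few low-frequency 2-D cosine
#' components with random phases and orientations, plus independent random
#' row and column offsets. The surface is centred to zero mean over the grid
#' and rescaled so its standard deviation over grid positions equals
#' \code{amplitude} exactly (so the surface variance is \code{amplitude^2}).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param amplitude target standard deviation of the surface (trait units;
#'   0 gives a flat surface).
#' @param n_components number of cosine components.
#' @param max_cycles maximum number of cosine cycles across the grid extent
#'   (low values keep the surface smooth).
#' @param rowcol_sd standard deviation of the raw row/column offsets relative
#'   to the raw cosine amplitude.
#' @return numeric matrix \code{n_rows x n_cols} of offsets.
#' @export
spatial_surface <- function(n_rows, n_cols, amplitude, n_components = 3,
                            max_cycles = 1, rowcol_sd = 0.5) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  s <- matrix(0, n_rows, n_cols)
  if (amplitude == 0) return(s)
  r <- (seq_len(n_rows) - 1) / max(1, n_rows - 1)
  c_ <- (seq_len(n_cols) - 1) / max(1, n_cols - 1)
  for (i in seq_len(n_components)) {
    fr <- stats::runif(1, 0.1, max_cycles)
    fc <- stats::runif(1, 0.1, max_cycles)
    ph_r <- stats::runif(1, 0, 2 * pi)
    ph_c <- stats::runif(1, 0, 2 * pi)
    s <- s + outer(cos(2 * pi * fr * r + ph_r), cos(2 * pi * fc * c_ + ph_c))
  }
  s <- s + matrix(stats::rnorm(n_rows, sd = rowcol_sd), n_rows, n_cols)
  s <- s + matrix(stats::rnorm(n_cols, sd = rowcol_sd), n_rows, n_cols, byrow = TRUE)
  s <- s - mean(s)
  sdev <- stats::sd(as.vector(s))
  if (sdev > 0) s <- s * (amplitude / sdev)
  s
}

#' Simulate per-plant phenotype records on a field layout
#'
#' Each plant's value is its line's true genotypic value plus its block
#' effect, the spatial surface offset at its grid position, and independent
#' Gaussian residual noise. The generative truth (line values, block effects,
#' surface, residual SD) is attached as attribute \code{"truth"} so
#' simulations are auditable.
#'
#' @param layout a \code{\link{make_layout}} result.
#' @param line_values named numeric vector: true genotypic value per line id
#'   (e.g. from \code{\link{genotype_value}}).
#' @param sigma_e residual standard deviation.
#' @param block_sd standard deviation of i.i.d. Gaussian block effects
#'   (0 = no block effects).
#' @param surface matrix from \code{\link{spatial_surface}} matching the grid,
#'   or NULL for no trend.
#' @param trait trait name stored in the records.
#' @param drop_rate fraction of plants dropped at random (missing plants),
#'   emulating outlier removal in real trials.
#' @return data.frame of plant records: \code{line_id}, \code{block},
#'   \code{row}, \code{col}, \code{trait}, \code{value}.
#' @export
simulate_experiment <- function(layout, line_values, sigma_e, block_sd = 0,
                                surface = NULL, trait = "trait",
                                drop_rate = 0) {
  occ <- layout[!is.na(layout$line_id), , drop = FALSE]
  miss <- setdiff(unique(occ$line_id), names(line_values))
  if (length(miss))
    stop("layout lines without a genotypic value: ",
         paste(utils::head(miss, 5), collapse = ", "))
  n_blocks <- max(layout$block)
  block_eff <- if (block_sd > 0) stats::rnorm(n_blocks, sd = block_sd) else
    rep(0, n_blocks)
  surf <- if (is.null(surface)) 0 else surface[cbind(occ$row, occ$col)]
  y <- line_values[occ$line_id] + block_eff[occ$block] + surf +
    stats::rnorm(nrow(occ), sd = sigma_e)
  rec <- data.frame(line_id = occ$line_id, block = occ$block,
                    row = occ$row, col = occ$col, trait = trait,
                    value = as.numeric(y), stringsAsFactors = FALSE)
  if (drop_rate > 0) {
    keep <- stats::runif(nrow(rec)) >= drop_rate
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(rec, "truth") <- list(line_values = line_values,
                             block_effects = block_eff,
                             surface = surface, sigma_e = sigma_e)
  rec
}

#' Simulate genotype-level RIL phenotypes from marker QTLs
#'
#' Additive marker-QTL model for recombinant panels: each QTL contributes its
#' effect when the line carries the Col allele at the marker nearest the QTL
#' position; Gaussian noise is added per line (genotype-level values, as used
#' for linkage scans).
#'
#' @param panel recombinant panel (\code{\link{ril_panel}} /
#'   \code{\link{nil_panel}}).
#' @param map the panel's marker map.
#' @param qtl data.frame with columns \code{chrom}, \code{cM}, \code{effect};
#'   zero rows give pure-noise phenotypes.
#' @param sigma_e residual SD.
#' @param mu intercept.
#' @return named numeric vector of phenotypes (names = line ids), with
#'   attribute \code{"truth"} holding the realised QTL marker positions.
#' @export
simulate_qtl_phenotype <- function(panel, map, qtl, sigma_e = 1, mu = 0) {
  m <- marker_matrix(panel, map)
  y <- rep(mu, nrow(m))
  used <- NULL
  if (!is.null(qtl) && nrow(qtl)) {
    for (i in seq_len(nrow(qtl))) {
      sel <- which(map$chrom == qtl$chrom[i])
      if (!length(sel)) stop("QTL on chromosome ", qtl$chrom[i], " not on map")
      j <- sel[which.min(abs(map$cM[sel] - qtl$cM[i]))]
      y <- y + qtl$effect[i] * origin_indicator(m[, j])
      used <- rbind(used, data.frame(chrom = qtl$chrom[i], cM = map$cM[j],
                                     marker = map$marker[j],
                                     effect = qtl$effect[i]))
    }
  }
  y <- y + stats::rnorm(nrow(m), sd = sigma_e)
  names(y) <- rownames(m)
  attr(y, "truth") <- used
  y
}
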