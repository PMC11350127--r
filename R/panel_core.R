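#' Chromosome-origin allele labels
#'
#' CSL genotypes are vectors of whole-chromosome origins, one of the two
#' parental accessions \code{"Ler"} or \code{"Col"}. Throughout the package
#' the indicator coding is Ler = 0, Col = 1, so fitted coefficients are the
#' phenotypic change caused by substituting a Col chromosome into a Ler
#' context.
#' @keywords internal
#' @name allele-coding
NULL

.ALLELES <- c("Ler", "Col")

#' Validate a CSL genotype vector
#'
#' @param origins character vector of chromosome origins.
#' @param n_chrom expected haploid chromosome number, or NULL to accept any
#'   length.
#' @return the validated vector, invisibly usable.
#' @keywords internal
validate_genotype <- function(origins, n_chrom = NULL) {
  if (!is.character(origins) || length(origins) < 1L)
    stop("genotype must be a non-empty character vector of chromosome origins")
  bad <- !(origins %in% .ALLELES)
  if (any(bad))
    stop("invalid chromosome origin label(s): ",
         paste(unique(origins[bad]), collapse = ", "),
         " (expected 'Col' or 'Ler')")
  if (!is.null(n_chrom) && length(origins) != n_chrom)
    stop("genotype has ", length(origins), " chromosomes, expected ", n_chrom)
  origins
}

#' Convert chromosome origins to 0/1 indicators
#'
#' Ler maps to 0 and Col to 1.
#'
#' @param origins character vector or matrix with values in \code{c("Col","Ler")}.
#' @return integer vector or matrix of the same shape.
#' @export
origin_indicator <- function(origins) {
  (origins == "Col") + 0L
}

#' Canonical line identifier for a CSL genotype
#'
#' @param origins character vector of chromosome origins.
#' @return a string such as \code{"CSL_CLLCC"} (C = Col, L = Ler, chromosome 1
#'   first).
#' @export
genotype_id <- function(origins) {
  validate_genotype(origins)
  paste0("CSL_", paste(substr(origins, 1, 1), collapse = ""))
}

#' Enumerate the complete chromosome-substitution panel
#'
#' Produces all \eqn{2^n} whole-chromosome genotype combinations of two
#' parental accessions for a species with haploid chromosome number \code{n}.
#' For Arabidopsis (\code{n_chrom = 5}) this is the complete 32-line panel.
#'
#' Rows are in deterministic lexicographic order with chromosome 1 as the most
#' significant digit and Ler before Col, so the first row is the all-Ler
#' parent and the last row the all-Col parent.
#'
#' @param n_chrom haploid chromosome number; must lie in 1..20.
#' @return a data.frame with columns \code{line_id}, \code{Chr1} ..
#'   \code{Chr<n>}, each chromosome column a character vector in
#'   \code{c("Col","Ler")}; one row per genotype, \eqn{2^n} rows total.
#' @examples
#' nrow(enumerate_panel(5))  # 32
#' @export
enumerate_panel <- function(n_chrom) {
  if (!is.numeric(n_chrom) || length(n_chrom) != 1L || is.na(n_chrom) ||
      n_chrom != floor(n_chrom) || n_chrom < 1 || n_chrom > 20)
    stop("n_chrom must be a single integer in 1..20")
  n_chrom <- as.integer(n_chrom)
  idx <- 0:(2L^n_chrom - 1L)
  # chromosome 1 is the most significant bit; bit 1 -> Col
  geno <- matrix("", nrow = length(idx), ncol = n_chrom)
  for (k in seq_len(n_chrom)) {
    bit <- idx %/% 2L^(n_chrom - k) %% 2L
    geno[, k] <- .ALLELES[bit + 1L]
  }
  colnames(geno) <- paste0("Chr", seq_len(n_chrom))
  out <- data.frame(
    line_id = apply(geno, 1L, genotype_id),
    geno, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Extract the chromosome-origin matrix from a panel table
#'
#' @param panel a data.frame with \code{Chr*} columns as produced by
#'   \code{\link{enumerate_panel}} or read by \code{\link{read_genotypes}}.
#' @return character matrix, rows named by \code{line_id} when present.
#' @export
panel_matrix <- function(panel) {
  chr_cols <- grep("^Chr[0-9]+$", names(panel), value = TRUE)
  if (length(chr_cols) == 0L) stop("panel has no Chr<k> columns")
  ord <- order(as.integer(sub("^Chr", "", chr_cols)))
  m <- as.matrix(panel[, chr_cols[ord], drop = FALSE])
  apply(m, 2L, validate_genotype)
  if ("line_id" %in% names(panel)) rownames(m) <- panel$line_id
  m
}

#' Classify a CSL genotype within the panel
#'
#' A genotype is \code{parental} when all chromosomes share one origin,
#' \code{single_substitution} when exactly one chromosome differs from the
#' majority origin (an sCSL), and \code{multi_substitution} otherwise. The
#' \code{background} is the recurrent parent for parental lines and sCSLs and
#' \code{"none"} for multi-substitution lines. \code{n_substituted} counts the
#' minority-origin chromosomes (the distance to the nearest parent).
#'
#' @param origins character vector of chromosome origins.
#' @return list with elements \code{label}, \code{background},
#'   \code{n_substituted}.
#' @examples
#' classify_genotype(c("Col","Col","Col","Col","Col"))$label  # "parental"
#' @export
classify_genotype <- function(origins) {
  validate_genotype(origins)
  n_col <- sum(origins == "Col")
  n_ler <- length(origins) - n_col
  n_sub <- min(n_col, n_ler)
  if (n_sub == 0L) {
    list(label = "parental",
         background = if (n_col > 0L) "Col" else "Ler",
         n_substituted = 0L)
  } else if (n_sub == 1L) {
    list(label = "single_substitution",
         background = if (n_col > n_ler) "Col" else "Ler",
         n_substituted = 1L)
  } else {
    list(label = "multi_substitution", background = "none",
         n_substituted = n_sub)
  }
}

#' Classify every line of a panel
#'
#' @param panel panel data.frame (see \code{\link{enumerate_panel}}).
#' @return data.frame with \code{line_id}, \code{label}, \code{background},
#'   \code{n_substituted}, in panel order.
#' @export
classify_panel <- function(panel) {
  m <- panel_matrix(panel)
  cls <- apply(m, 1L, classify_genotype)
  data.frame(
    line_id = if (!is.null(rownames(m))) rownames(m) else seq_len(nrow(m)),
    label = vapply(cls, `[[`, "", "label"),
    background = vapply(cls, `[[`, "", "background"),
    n_substituted = vapply(cls, `[[`, 0L, "n_substituted"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Full-factorial design matrix for chromosome effects
#'
#' Builds the predictor matrix of the factorial effect model: an intercept,
#' main-effect indicators \eqn{x_k} (Ler = 0, Col = 1) and, when requested,
#' all two-way products \eqn{x_k x_l} (k < l) and three-way products
#' \eqn{x_k x_l x_m} (k < l < m). Interaction columns are exact elementwise
#' products of their parent main-effect columns, so the marginality structure
#' is built in. Column names follow the \code{Chr1}, \code{Chr1:Chr3},
#' \code{Chr1:Chr2:Chr5} convention.
#'
#' @param panel panel data.frame or chromosome-origin matrix.
#' @param max_order highest interaction order to include: 1, 2 or 3.
#' @return numeric matrix with rows in panel order; first column
#'   \code{intercept}.
#' @export
design_matrix <- function(panel, max_order = 3) {
  if (!max_order %in% 1:3) stop("max_order must be 1, 2 or 3")
  m <- if (is.matrix(panel)) panel else panel_matrix(panel)
  if (nrow(m) == 0L) stop("empty genotype list")
  x <- origin_indicator(m)
  n <- ncol(x)
  cols <- list(intercept = rep(1, nrow(x)))
  for (k in seq_len(n)) cols[[paste0("Chr", k)]] <- x[, k]
  if (max_order >= 2 && n >= 2) {
    for (p in utils::combn(n, 2, simplify = FALSE))
      cols[[paste(paste0("Chr", p), collapse = ":")]] <- x[, p[1]] * x[, p[2]]
  }
  if (max_order >= 3 && n >= 3) {
    for (p in utils::combn(n, 3, simplify = FALSE))
      cols[[paste(paste0("Chr", p), collapse = ":")]] <-
        x[, p[1]] * x[, p[2]] * x[, p[3]]
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(m)
  out
}

#' Split an interaction term name into its chromosome indices
#'
#' @param term a term name such as \code{"Chr1:Chr3"}; \code{"BG"} components
#'   are preserved as the string \code{"BG"}.
#' @return integer vector of chromosome indices (with attribute dropped for
#'   plain main effects); \code{"BG"} parts are returned as \code{NA} index
#'   alongside attribute \code{bg = TRUE}.
#' @keywords internal
term_indices <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  chr <- grepl("^Chr[0-9]+$", parts)
  idx <- as.integer(sub("^Chr", "", parts[chr]))
  structure(sort(idx), bg = any(parts == "BG"))
}

#' All lower-order terms nested under an interaction term
#'
#' Implements the marginality principle: a model containing
#' \code{"Chr1:Chr2:Chr5"} must retain \code{Chr1}, \code{Chr2}, \code{Chr5}
#' and the three pairwise products.
#'
#' @param term interaction term name.
#' @return character vector of nested term names (excluding \code{term}
#'   itself); empty for main effects.
#' @export
nested_terms <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (length(parts) <= 1L) return(character(0))
  out <- character(0)
  for (ord in seq_len(length(parts) - 1L))
    out <- c(out, utils::combn(parts, ord, paste, collapse = ":"))
  out
}
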