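#' Haldane map function and selfing-RIL expansion
#'
#' \code{haldane_c} converts a genetic distance in cM to a gamete
#' recombination fraction assuming no crossover interference;
#' \code{ril_recomb} applies the expected expansion for a population of
#' recombinant inbred lines produced by repeated selfing, R = 2c/(1+2c).
#'
#' @param d_cM genetic distance in centiMorgans (vectorised).
#' @return recombination fraction in [0, 0.5].
#' @export
haldane_c <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' @rdname haldane_c
#' @export
kosambi_c <- function(d_cM) tanh(2 * d_cM / 100) / 2

#' @rdname haldane_c
#' @param map_fun map function for the gamete recombination fraction:
#'   \code{"haldane"} (no interference; the default, matching the crossover
#'   simulator) or \code{"kosambi"}.
#' @export
ril_recomb <- function(d_cM, map_fun = c("haldane", "kosambi")) {
  map_fun <- match.arg(map_fun)
  c_ <- if (map_fun == "haldane") haldane_c(d_cM) else kosambi_c(d_cM)
  2 * c_ / (1 + 2 * c_)
}

#' Default Arabidopsis-like marker map
#'
#' Builds a regular marker grid over chromosomes of realistic genetic length.
#' Physical positions assume a constant ~0.5 Mbp/cM so that marker spacing of
#' 5 cM corresponds to roughly 2.5 Mbp.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths_cM numeric vector of chromosome lengths in cM (recycled to
#'   \code{n_chrom}).
#' @param spacing_cM distance between adjacent markers in cM.
#' @return a marker map data.frame with columns \code{marker}, \code{chrom},
#'   \code{cM}, \code{bp}.
#' @export
default_marker_map <- function(n_chrom = 5,
                               lengths_cM = c(120, 90, 95, 100, 110),
                               spacing_cM = 5) {
  lengths_cM <- rep_len(lengths_cM, n_chrom)
  maps <- lapply(seq_len(n_chrom), function(k) {
    pos <- seq(0, lengths_cM[k], by = spacing_cM)
    data.frame(
      marker = sprintf("M%d_%03d", k, seq_along(pos)),
      chrom = k, cM = pos, bp = round(pos * 5e5),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  validate_map(out)
}

#' Validate a marker map
#'
#' @param map data.frame with columns \code{marker}, \code{chrom}, \code{cM}
#'   and optionally \code{bp}.
#' @return the map, with chromosome blocks ordered and positions checked
#'   non-decreasing.
#' @export
validate_map <- function(map) {
  need <- c("marker", "chrom", "cM")
  if (!all(need %in% names(map)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker)) stop("duplicated marker names in map")
  ord <- order(map$chrom, map$cM)
  if (!identical(ord, seq_len(nrow(map))))
    stop("marker map must be sorted by chromosome then cM position")
  for (k in unique(map$chrom)) {
    pos <- map$cM[map$chrom == k]
    if (is.unsorted(pos)) stop("cM positions decrease within chromosome ", k)
  }
  map
}

#' Draw one achiasmatic gamete
#'
#' Models gamete formation in a crossover-suppressed F1 hybrid: each whole
#' chromosome segregates independently to the gamete with probability 1/2 per
#' parental origin and no within-chromosome recombination, so any specific
#' whole-chromosome combination occurs with probability \eqn{1/2^n}.
#'
#' Randomness uses R's global generator; call \code{set.seed} for
#' reproducibility.
#'
#' @param n_chrom haploid chromosome number.
#' @return character vector of chromosome origins.
#' @export
achiasmatic_gamete <- function(n_chrom) {
  sample(.ALLELES, n_chrom, replace = TRUE)
}

#' Simulate a doubled-haploid CSL panel
#'
#' Each line is an independent achiasmatic gamete converted to a fully
#' homozygous doubled haploid, i.e. an i.i.d. uniform draw from the \eqn{2^n}
#' panel.
#'
#' @param n_lines number of DH lines to produce (>= 1).
#' @param n_chrom haploid chromosome number.
#' @return panel data.frame (\code{line_id}, \code{Chr*}); line ids carry a
#'   running suffix so repeated genotypes remain distinct rows.
#' @export
dh_panel <- function(n_lines, n_chrom = 5) {
  if (!is.numeric(n_lines) || length(n_lines) != 1L || n_lines < 1)
    stop("n_lines must be a positive integer")
  geno <- matrix(sample(.ALLELES, n_lines * n_chrom, replace = TRUE),
                 nrow = n_lines, ncol = n_chrom)
  colnames(geno) <- paste0("Chr", seq_len(n_chrom))
  data.frame(
    line_id = sprintf("DH%04d_%s", seq_len(n_lines),
                      apply(geno, 1L, function(g) paste(substr(g, 1, 1), collapse = ""))),
    geno, stringsAsFactors = FALSE
  )
}

#' Report panel genotypes missing from a set of lines
#'
#' @param lines panel data.frame of observed genotypes.
#' @param n_chrom haploid chromosome number (defaults to the number of
#'   \code{Chr*} columns in \code{lines}).
#' @return data.frame of missing genotypes in panel order (zero rows when the
#'   panel is complete), plus attribute \code{n_observed_distinct}.
#' @export
panel_completeness <- function(lines, n_chrom = NULL) {
  m <- panel_matrix(lines)
  if (is.null(n_chrom)) n_chrom <- ncol(m)
  full <- enumerate_panel(n_chrom)
  seen <- unique(apply(m, 1L, genotype_id))
  miss <- full[!(full$line_id %in% seen), , drop = FALSE]
  rownames(miss) <- NULL
  attr(miss, "n_observed_distinct") <- length(seen)
  miss
}

#' Exact probability of completing the panel (inclusion-exclusion)
#'
#' Closed-form coupon-collector probability that \code{n_lines} i.i.d. uniform
#' draws from the \eqn{2^n} genotype classes cover every class:
#' \deqn{P = \sum_j (-1)^j {N \choose j} (1 - j/N)^{n_{lines}}, N = 2^n.}
#' Serves as the analytic reference for the Monte-Carlo simulator.
#'
#' @param n_lines number of DH lines genotyped.
#' @param n_chrom haploid chromosome number.
#' @return probability in [0, 1].
#' @export
completeness_probability <- function(n_lines, n_chrom = 5) {
  N <- 2^n_chrom
  j <- 0:N
  sum((-1)^j * choose(N, j) * (1 - j / N)^n_lines)
}

## ---- recombinant (marker-level) genotypes ----------------------------------

#' Draw a recombinant haploid gamete from two genotyped parents
#'
#' Meiosis with crossovers: per chromosome the crossover count is Poisson in
#' the map length (Morgans), crossover positions are uniform on the genetic
#' map and there is no interference (Haldane model). The gamete starts in a
#' random parental phase and switches phase at every crossover.
#'
#' @param parent_a,parent_b character vectors of per-marker alleles aligned to
#'   \code{map} (values \code{"Col"}/\code{"Ler"}).
#' @param map marker map (see \code{\link{validate_map}}).
#' @return character vector of per-marker alleles for one gamete.
#' @export
recombinant_gamete <- function(parent_a, parent_b, map) {
  validate_map(map)
  if (length(parent_a) != nrow(map) || length(parent_b) != nrow(map))
    stop("parent allele vectors must match the marker map (",
         nrow(map), " markers)")
  out <- character(nrow(map))
  for (k in unique(map$chrom)) {
    sel <- which(map$chrom == k)
    pos <- map$cM[sel]
    len_M <- (max(pos) - min(pos)) / 100
    n_xo <- stats::rpois(1, len_M)
    xo <- sort(stats::runif(n_xo, min(pos), max(pos)))
    # phase 0 = parent_a, switches at each crossover
    phase0 <- sample(0:1, 1)
    n_before <- vapply(pos, function(p) sum(xo < p), 0L)
    phase <- (phase0 + n_before) %% 2L
    out[sel] <- ifelse(phase == 0L, parent_a[sel], parent_b[sel])
  }
  out
}

#' Marker-level alleles of a whole-chromosome genotype
#'
#' @param origins CSL chromosome-origin vector.
#' @param map marker map.
#' @return per-marker allele vector (each chromosome monomorphic for its
#'   origin).
#' @export
expand_to_markers <- function(origins, map) {
  validate_genotype(origins, n_chrom = max(map$chrom))
  origins[map$chrom]
}

#' Simulate a NIL panel from an sCSL x recurrent-parent cross
#'
#' Backcrossing a single-chromosome substitution line to its recurrent parent
#' gives an F1 that is heterozygous only for the substituted chromosome;
#' doubled haploids of its gametes are near-isogenic lines recombinant for
#' that single chromosome. All other chromosomes are monomorphic for the
#' recurrent background.
#'
#' @param scsl,recurrent CSL origin vectors differing on exactly one
#'   chromosome.
#' @param n_lines number of DH lines.
#' @param map marker map.
#' @return data.frame, one row per line: \code{line_id}, \code{panel},
#'   \code{target_chrom}, \code{background}, then one column per marker with
#'   \code{Col}/\code{Ler} calls.
#' @export
nil_panel <- function(scsl, recurrent, n_lines, map) {
  validate_genotype(scsl)
  validate_genotype(recurrent)
  diff <- which(scsl != recurrent)
  if (length(diff) != 1L)
    stop("scsl and recurrent must differ on exactly one chromosome (differ on ",
         length(diff), ")")
  target <- diff
  bg <- recurrent[1L]
  pa <- expand_to_markers(scsl, map)
  pb <- expand_to_markers(recurrent, map)
  sel_other <- map$chrom != target
  geno <- matrix("", nrow = n_lines, ncol = nrow(map))
  for (i in seq_len(n_lines)) {
    g <- recombinant_gamete(pa, pb, map)
    g[sel_other] <- pb[sel_other]  # only the target chromosome segregates
    geno[i, ] <- g
  }
  colnames(geno) <- map$marker
  data.frame(
    line_id = sprintf("NIL%s_chr%d_%03d", bg, target, seq_len(n_lines)),
    panel = "NIL", target_chrom = target, background = bg,
    geno, stringsAsFactors = FALSE, check.names = FALSE
  )
}

#' Introgression boundaries of a NIL chromosome
#'
#' Detects runs of donor alleles along the target chromosome and reports both
#' flanking-marker and midpoint boundary estimates for each introgressed
#' segment.
#'
#' @param alleles per-marker allele vector for one chromosome (map order).
#' @param pos cM positions of the markers.
#' @param donor donor allele label.
#' @return data.frame with one row per donor segment: first/last donor marker
#'   positions and the flanking/midpoint boundary coordinates.
#' @export
introgression_boundaries <- function(alleles, pos, donor) {
  is_donor <- alleles == donor
  if (!any(is_donor))
    return(data.frame(start_marker = numeric(0), end_marker = numeric(0),
                      start_flank = numeric(0), end_flank = numeric(0),
                      start_mid = numeric(0), end_mid = numeric(0)))
  r <- rle(is_donor)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(j) {
    i1 <- starts[j]; i2 <- ends[j]
    left_out <- if (i1 > 1L) pos[i1 - 1L] else pos[i1]
    right_out <- if (i2 < length(pos)) pos[i2 + 1L] else pos[i2]
    data.frame(start_marker = pos[i1], end_marker = pos[i2],
               start_flank = left_out, end_flank = right_out,
               start_mid = (pos[i1] + left_out) / 2,
               end_mid = (pos[i2] + right_out) / 2)
  })
  do.call(rbind, out)
}

#' Simulate a recombinant inbred line panel
#'
#' Generates homozygous RIL genotypes marker-by-marker as a Markov chain along
#' each chromosome, with adjacent-marker switch probability given by the
#' selfing-RIL expansion of the Haldane recombination fraction,
#' R = 2c/(1+2c). Chromosomes are independent; the first marker of each
#' chromosome is Col or Ler with probability 1/2.
#'
#' @param n_lines number of RILs (>= 1).
#' @param map marker map.
#' @param map_fun map function for adjacent-marker recombination
#'   (see \code{\link{ril_recomb}}).
#' @return data.frame: \code{line_id}, \code{panel}, then one column per
#'   marker.
#' @export
ril_panel <- function(n_lines, map, map_fun = "haldane") {
  validate_map(map)
  if (n_lines < 1) stop("n_lines must be >= 1")
  geno <- matrix("", nrow = n_lines, ncol = nrow(map))
  for (k in unique(map$chrom)) {
    sel <- which(map$chrom == k)
    pos <- map$cM[sel]
    rr <- ril_recomb(diff(pos), map_fun = map_fun)
    cur <- sample(.ALLELES, n_lines, replace = TRUE)
    geno[, sel[1L]] <- cur
    for (j in seq_along(rr)) {
      switch_ <- stats::runif(n_lines) < rr[j]
      cur <- ifelse(switch_, ifelse(cur == "Col", "Ler", "Col"), cur)
      geno[, sel[j + 1L]] <- cur
    }
  }
  colnames(geno) <- map$marker
  data.frame(
    line_id = sprintf("RIL%03d", seq_len(n_lines)),
    panel = "RIL", geno, stringsAsFactors = FALSE, check.names = FALSE
  )
}

#' Per-marker allele matrix of a recombinant panel
#'
#' @param panel data.frame from \code{\link{ril_panel}} or
#'   \code{\link{nil_panel}}.
#' @param map marker map the panel was simulated on.
#' @return character matrix lines x markers, rows named by line id.
#' @export
marker_matrix <- function(panel, map) {
  miss <- setdiff(map$marker, names(panel))
  if (length(miss))
    stop("panel lacks marker column(s): ", paste(utils::head(miss, 5), collapse = ", "))
  m <- as.matrix(panel[, map$marker, drop = FALSE])
  rownames(m) <- panel$line_id
  m
}
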