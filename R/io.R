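#' Read and write whole-chromosome genotype panels
#'
#' Panels are tab-separated with a header \code{line_id} followed by
#' \code{Chr1..Chr<n>}; values must be \code{Col} or \code{Ler}. Malformed
#' values are reported with their row and column.
#'
#' @param path file path.
#' @return panel data.frame.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "line_id")
    stop("first column must be line_id (got '", names(df)[1], "')")
  chr_cols <- grep("^Chr[0-9]+$", names(df), value = TRUE)
  if (!length(chr_cols)) stop("no Chr<k> columns in ", path)
  if (anyDuplicated(df$line_id))
    stop("duplicated line_id: ",
         paste(unique(df$line_id[duplicated(df$line_id)]), collapse = ", "))
  for (cc in chr_cols) {
    bad <- which(!(df[[cc]] %in% .ALLELES))
    if (length(bad))
      stop("invalid allele '", df[[cc]][bad[1]], "' at data row ", bad[1],
           ", column ", cc, " (expected Col or Ler)")
  }
  df
}

#' @rdname read_genotypes
#' @param panel panel data.frame.
#' @export
write_genotypes <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-plant phenotype tables
#'
#' Comma-separated with columns \code{line_id}, \code{block}, \code{row},
#' \code{col}, \code{trait}, \code{value}.
#'
#' @param path file path.
#' @return records data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "block", "row", "col", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.na(df$value) & !is.finite(df$value))
  if (length(bad)) stop("non-finite value at data row ", bad[1])
  dup <- duplicated(df[, c("row", "col", "trait")])
  if (any(dup))
    stop("duplicated grid position at data row ", which(dup)[1])
  df
}

#' @rdname read_phenotypes
#' @param records phenotype records.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker map (CSV: marker, chrom, cM[, bp])
#'
#' @param path file path.
#' @return validated marker map.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_map(df)
}

#' Write an analysis report as stable-ordered JSON
#'
#' @param results a named list (nested lists / data frames allowed).
#' @param path output path.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns", na = "null")
  invisible(path)
}

#' Default run configuration
#'
#' The end-to-end study conditions: a complete 32-line CSL panel in twelve
#' replicates alongside 100 RILs in three replicates on a 12 x 60 grid of
#' three complete blocks, both study traits, spatial trend and block
#' effects, the staged epistasis decomposition thresholds and the composite
#' interval mapping settings.
#'
#' @param seed integer seed controlling every stochastic stage.
#' @param out_dir output directory for stage artefacts.
#' @return a named list, serialisable to JSON and back unchanged.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("cslmap_run_")) {
  list(
    seed = as.integer(seed),
    n_chrom = 5L,
    n_rils = 100L,
    csl_reps_per_block = 4L,
    ril_reps_per_block = 1L,
    n_rows = 12L, n_cols = 60L, n_blocks = 3L,
    traits = c("flowering_time", "main_stem_length"),
    block_sd = list(flowering_time = 1, main_stem_length = 10),
    surface_amplitude = list(flowering_time = 1.5, main_stem_length = 15),
    alpha3 = 5e-5, alpha2 = 5e-5, alpha_bg = 1e-3, alpha_gw = 0.05,
    cim_step = 5, cofactor_window = 50, min_sep = 30, si_drop = 2,
    out_dir = out_dir
  )
}

#' Run the full simulate - adjust - map pipeline
#'
#' Orchestrates the study workflow on synthetic data: simulate the CSL and
#' RIL panels and the phenotyping trial, spatially adjust each trait, run
#' the staged epistasis decomposition (plant-level corrected values) and the
#' composite interval mapping scan (RIL shrunken means), and write all stage
#' artefacts plus a provenance snapshot of the configuration under
#' \code{config$out_dir}.
#'
#' @param config list from \code{\link{default_config}} (fields may be
#'   overridden).
#' @return invisible list with the in-memory results per trait
#'   (\code{adjusted}, \code{epistasis}, \code{background}, \code{cim}) and
#'   the artefact paths.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(is.list(config), !is.null(config$seed))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  panel <- enumerate_panel(config$n_chrom)
  map <- default_marker_map(config$n_chrom)
  rils <- ril_panel(config$n_rils, map)
  write_genotypes(panel, file.path(config$out_dir, "csl_panel.tsv"))

  reps <- default_trial_reps(panel$line_id, rils$line_id,
                             config$csl_reps_per_block,
                             config$ril_reps_per_block)
  layout <- make_layout(reps, config$n_rows, config$n_cols, config$n_blocks)
  pred <- genetic_predictors(rils, map, step_cM = config$cim_step)

  results <- list()
  for (trait in config$traits) {
    model <- default_effect_model(trait)
    csl_vals <- genotype_value(panel, model)
    # RIL genotypic values: three moderate marker QTLs on the trait's scale
    qtl <- data.frame(chrom = c(2L, 5L, 1L),
                      cM = c(40, 30, 60),
                      effect = c(-0.6, -1, 0.25) * stats::sd(csl_vals))
    ril_vals <- simulate_qtl_phenotype(rils, map, qtl, sigma_e = 0)
    surf <- spatial_surface(config$n_rows, config$n_cols,
                            config$surface_amplitude[[trait]])
    records <- simulate_experiment(
      layout, c(csl_vals, ril_vals), sigma_e = model$sigma_e,
      block_sd = config$block_sd[[trait]], surface = surf, trait = trait)
    write_phenotypes(records,
                     file.path(config$out_dir, paste0("phenotypes_", trait, ".csv")))

    pops <- stats::setNames(
      c(rep("CSL", nrow(panel)), rep("RIL", nrow(rils))),
      c(panel$line_id, rils$line_id))
    adj <- fit_spatial(records, pops)
    write_phenotypes(corrected_table(adj, "plant"),
                     file.path(config$out_dir, paste0("corrected_", trait, ".csv")))

    csl_plants <- adj$plants[adj$plants$line_id %in% panel$line_id, ]
    epi <- epistasis_decomposition(csl_plants, panel,
                                   alpha3 = config$alpha3,
                                   alpha2 = config$alpha2)
    cls <- classify_panel(panel)
    scsl_ids <- cls$line_id[cls$label != "multi_substitution"]
    sub <- csl_plants[csl_plants$line_id %in% scsl_ids, ]
    bg <- background_interaction(sub$corrected,
                                 .align_genotypes(sub$line_id, panel),
                                 alpha = config$alpha_bg)

    blups <- corrected_table(adj, "genotype")
    ril_blups <- stats::setNames(blups$shrunken_mean, blups$line_id)
    ril_blups <- ril_blups[names(ril_blups) %in% rils$line_id]
    thr <- li_ji_threshold(rils, map, alpha = config$alpha_gw)
    cim <- cim_iterate(ril_blups, pred, thr$threshold,
                       cofactor_window = config$cofactor_window,
                       min_sep = config$min_sep, drop = config$si_drop)
    utils::write.csv(cim$profile,
                     file.path(config$out_dir, paste0("scan_", trait, ".csv")),
                     row.names = FALSE)
    utils::write.csv(cim$qtls,
                     file.path(config$out_dir, paste0("qtls_", trait, ".csv")),
                     row.names = FALSE)
    write_report(
      list(trait = trait,
           epistasis = list(terms = epi$terms, r2 = epi$r2,
                            r2_main_only = epi$r2_main_only,
                            coefficients = epi$coefficients),
           background = list(selected = bg$selected,
                             coefficients = bg$coefficients),
           qtls = cim$qtls,
           varcomp = adj$varcomp),
      file.path(config$out_dir, paste0("report_", trait, ".json")))
    results[[trait]] <- list(adjusted = adj, epistasis = epi,
                             background = bg, cim = cim)
  }
  write_report(c(config, list(package_version = as.character(utils::packageVersion("cslmap")))),
               file.path(config$out_dir, "config_snapshot.json"))
  invisible(list(results = results, out_dir = config$out_dir,
                 panel = panel, map = map))
}
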