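# Shared fixture builders (all programmatic; no files).

# per-plant chromosome-origin matrix and values for a balanced CSL trial
csl_trial <- function(model, reps = 12, n_chrom = 5) {
  panel <- enumerate_panel(n_chrom)
  geno <- panel_matrix(panel)[rep(seq_len(2^n_chrom), each = reps), , drop = FALSE]
  truth <- genotype_value(panel, model)
  y <- truth[rep(seq_len(2^n_chrom), each = reps)] +
    stats::rnorm(nrow(geno), sd = model$sigma_e)
  list(panel = panel, geno = geno, y = unname(y), truth = truth)
}

# plants for the reciprocal sCSL + parents subset
scsl_trial <- function(model, reps = 12) {
  panel <- enumerate_panel(5)
  cls <- classify_panel(panel)
  keep <- cls$label != "multi_substitution"
  sub <- panel[keep, , drop = FALSE]
  geno <- panel_matrix(sub)[rep(seq_len(nrow(sub)), each = reps), , drop = FALSE]
  truth <- genotype_value(sub, model)
  y <- truth[rep(seq_len(nrow(sub)), each = reps)] +
    stats::rnorm(nrow(geno), sd = model$sigma_e)
  list(panel = sub, geno = geno, y = unname(y))
}

# tiny marker map for fast linkage tests
tiny_map <- function(lengths = c(60, 60), spacing = 10) {
  default_marker_map(length(lengths), lengths, spacing)
}
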