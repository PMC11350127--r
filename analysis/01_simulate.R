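#!/usr/bin/env Rscript
# Stage 1 — simulate the study populations and the phenotyping trial.
#
# Builds the complete 32-line CSL panel, checks how many doubled haploids a
# reverse-breeding programme needs to genotype to recover it, simulates the
# RIL comparison population and reciprocal chromosome-5 NIL sets, and grows
# everything in a simulated 12 x 60 randomised-complete-block trial with
# block effects, a smooth spatial trend and residual noise for the two study
# traits. Outputs go to results/analysis/.

suppressPackageStartupMessages(library(cslmap))
out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(2024)

panel <- enumerate_panel(5)
cls <- classify_panel(panel)
cat("CSL panel:", nrow(panel), "genotypes —",
    sum(cls$label == "parental"), "parental,",
    sum(cls$label == "single_substitution"), "single-substitution,",
    sum(cls$label == "multi_substitution"), "multi-substitution\n")
write_genotypes(panel, file.path(out_dir, "csl_panel.tsv"))
utils::write.csv(cls, file.path(out_dir, "csl_classes.csv"), row.names = FALSE)

# breeding logistics: probability that ~3 * 2^n DH lines complete the panel
for (n_lines in c(32, 64, 96, 128))
  cat(sprintf("  P(complete panel | %3d DH lines) = %.3f\n", n_lines,
              completeness_probability(n_lines, 5)))
sims <- replicate(500, nrow(panel_completeness(dh_panel(96, 5))) == 0L)
cat(sprintf("  Monte-Carlo check at 96 lines: %.3f (closed form %.3f)\n",
            mean(sims), completeness_probability(96, 5)))

map <- default_marker_map(5)
utils::write.csv(map, file.path(out_dir, "marker_map.csv"), row.names = FALSE)
rils <- ril_panel(100, map)
write_genotypes_path <- file.path(out_dir, "ril_panel.tsv")
utils::write.table(rils, write_genotypes_path, sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("RIL panel: 100 lines,", nrow(map), "markers\n")

# reciprocal chromosome-5 NIL sets for fine-mapping
nil_col <- nil_panel(c("Col", "Col", "Col", "Col", "Ler"), rep("Col", 5), 48, map)
nil_ler <- nil_panel(c("Ler", "Ler", "Ler", "Ler", "Col"), rep("Ler", 5), 48, map)
utils::write.table(nil_col, file.path(out_dir, "nil_chr5_col.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(nil_ler, file.path(out_dir, "nil_chr5_ler.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("NIL panels: 48 lines per background, chromosome 5\n")

# phenotyping trial: 32 CSLs x 12 reps + 100 RILs x 3 reps on 12 x 60
lay <- make_layout(default_trial_reps(panel$line_id, rils$line_id))
cat("field layout:", sum(!is.na(lay$line_id)), "plants on a 12 x 60 grid\n")
for (trait in c("flowering_time", "main_stem_length")) {
  model <- default_effect_model(trait)
  csl_vals <- genotype_value(panel, model)
  qtl <- data.frame(chrom = c(2, 5, 1), cM = c(40, 30, 60),
                    effect = c(-0.6, -1, 0.25) * sd(csl_vals))
  ril_vals <- simulate_qtl_phenotype(rils, map, qtl, sigma_e = 0)
  surf <- spatial_surface(12, 60, amplitude = 0.75 * model$sigma_e)
  rec <- simulate_experiment(lay, c(csl_vals, ril_vals),
                             sigma_e = model$sigma_e,
                             block_sd = 0.5 * model$sigma_e,
                             surface = surf, trait = trait)
  write_phenotypes(rec, file.path(out_dir, paste0("phenotypes_", trait, ".csv")))
  truth <- attr(rec, "truth")
  write_report(list(trait = trait, seed = 2024,
                    sigma_e = model$sigma_e,
                    block_effects = truth$block_effects,
                    line_values = as.list(truth$line_values)),
               file.path(out_dir, paste0("truth_", trait, ".json")))
  cat(sprintf("  %s: %d plants, sigma_e = %g\n", trait, nrow(rec), model$sigma_e))
}
cat("stage 1 done\n")
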