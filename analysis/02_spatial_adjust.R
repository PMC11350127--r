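#!/usr/bin/env Rscript
# Stage 2 — spatial adjustment of the trial data.
#
# Fits the REML mixed model (fixed population + block + tensor-polynomial
# surface; random row, column and genotype-within-population with separate
# CSL and RIL genetic variances), removes the environmental part from each
# plant and writes plant-level corrected values (input for the epistasis
# decomposition) and shrunken genotype means (input for linkage mapping).

suppressPackageStartupMessages(library(cslmap))
out_dir <- "results/analysis"
panel <- read_genotypes(file.path(out_dir, "csl_panel.tsv"))
rils <- utils::read.delim(file.path(out_dir, "ril_panel.tsv"),
                          check.names = FALSE)
pops <- setNames(c(rep("CSL", nrow(panel)), rep("RIL", nrow(rils))),
                 c(panel$line_id, rils$line_id))

for (trait in c("flowering_time", "main_stem_length")) {
  rec <- read_phenotypes(file.path(out_dir, paste0("phenotypes_", trait, ".csv")))
  adj <- fit_spatial(rec, pops)
  cat(trait, "variance components:\n")
  cat(sprintf("  genetic CSL = %.3g, genetic RIL = %.3g\n",
              adj$varcomp$genetic[["CSL"]], adj$varcomp$genetic[["RIL"]]))
  cat(sprintf("  row = %.3g, col = %.3g, surface = %.3g, residual = %.3g\n",
              adj$varcomp$row, adj$varcomp$col, adj$varcomp$surface,
              adj$varcomp$residual))
  write_phenotypes(corrected_table(adj, "plant"),
                   file.path(out_dir, paste0("corrected_", trait, ".csv")))
  utils::write.csv(corrected_table(adj, "genotype"),
                   file.path(out_dir, paste0("blups_", trait, ".csv")),
                   row.names = FALSE)
  write_report(adj$varcomp,
               file.path(out_dir, paste0("varcomp_", trait, ".json")))
}
cat("stage 2 done\n")
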