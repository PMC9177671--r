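#!/usr/bin/env Rscript
# Stage 1: simulate the F2 study population.
#
# 179 F2 plants from a cross of a late-flowering, obcordate-leaf parent
# (105 days) and an early-flowering, lanceolate-leaf parent (67 days):
# a major additive days-to-flowering QTL on CcLG03 and a recessive
# leaf-shape locus on CcLG08, markers at ~80 SNPs/Mb, 14x pooled depth.
# Writes the phenotype table, two-bulk read counts per trait (VCF + TSV)
# and the ground-truth JSON under results/simulated_study/.

suppressMessages(library(bulkscan))

SEED <- 1L
out <- "results/simulated_study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = SEED)
sim <- simulate_f2(cfg)

message(sprintf("simulated %d F2s, %d markers on %s",
                cfg$n_individuals, nrow(sim$markers),
                paste(cfg$chromosomes$chrom, collapse = " + ")))
message(sprintf("days to flowering: %.0f-%.0f days (parents %g / %g)",
                min(sim$phenotypes$DF), max(sim$phenotypes$DF),
                cfg$baseline_df + 19, cfg$baseline_df - 19))

cls <- table(sim$phenotypes$leaf_shape)
chi <- segregation_chi_square(c(cls[["lanceolate"]], cls[["obcordate"]]))
message(sprintf("leaf shape %d lanceolate : %d obcordate; 3:1 chi-square %.2f (P = %.2f)",
                cls[["lanceolate"]], cls[["obcordate"]],
                chi$statistic, chi$p_value))

write_phenotypes(sim$phenotypes, file.path(out, "phenotypes.tsv"))

# per-trait extreme bulks and their pooled read counts
for (trait in c("DF", "leaf_shape")) {
  bulks <- if (trait == "DF") {
    select_extreme_bulks(sim$phenotypes, trait, cfg$bulk_size)
  } else {
    select_extreme_bulks(sim$phenotypes, trait, cfg$bulk_size,
                         mode = "categorical", high_class = "obcordate",
                         low_class = "lanceolate",
                         seed = derive_seed(SEED, "leaf_bulks"))
  }
  hi <- sample_bulk_counts(sim, bulks$high, cfg,
                           seed = derive_seed(SEED, paste0(trait, "_high")))
  lo <- sample_bulk_counts(sim, bulks$low, cfg,
                           seed = derive_seed(SEED, paste0(trait, "_low")))
  sites <- make_site_counts(hi, lo)
  tdir <- file.path(out, trait)
  write_sim_dataset(sim, sites, bulks, tdir,
                    high_name = if (trait == "DF") "LF" else "OLS",
                    low_name = if (trait == "DF") "EF" else "LLS")
  message(sprintf("[%s] high bulk n=%d, low bulk n=%d -> %s/", trait,
                  length(bulks$high), length(bulks$low), tdir))
}
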