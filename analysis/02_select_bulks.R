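#!/usr/bin/env Rscript
# Stage 2: extreme-bulk construction from the phenotype table.
#
# Reads results/simulated_study/phenotypes.tsv (stage 1), selects the 15
# lowest- and highest-value plants for days to flowering and 15 plants per
# leaf-shape class, checks 3:1 segregation, and writes bulk membership
# JSON under results/bulks/.

suppressMessages(library(bulkscan))

SEED <- 1L
phen <- read_phenotypes("results/simulated_study/phenotypes.tsv")
dir.create("results/bulks", showWarnings = FALSE, recursive = TRUE)

df_bulks <- select_extreme_bulks(phen, "DF", 15)
lo_rng <- range(phen$DF[phen$id %in% df_bulks$low])
hi_rng <- range(phen$DF[phen$id %in% df_bulks$high])
message(sprintf("DF bulks: early %.0f-%.0f days, late %.0f-%.0f days (disjoint: %s)",
                lo_rng[1], lo_rng[2], hi_rng[1], hi_rng[2],
                lo_rng[2] < hi_rng[1]))

cls <- table(phen$leaf_shape)
chi <- segregation_chi_square(c(cls[["lanceolate"]], cls[["obcordate"]]))
message(sprintf("leaf classes %s; 3:1 P = %.2f", paste(cls, collapse = ":"),
                chi$p_value))
leaf_bulks <- select_extreme_bulks(phen, "leaf_shape", 15,
                                   mode = "categorical",
                                   high_class = "obcordate",
                                   low_class = "lanceolate",
                                   seed = derive_seed(SEED, "leaf_bulks"))

jsonlite::write_json(
  list(DF = df_bulks, leaf_shape = leaf_bulks,
       segregation = list(lanceolate = unname(cls[["lanceolate"]]),
                          obcordate = unname(cls[["obcordate"]]),
                          chi_square = chi$statistic, p = chi$p_value)),
  "results/bulks/bulk_membership.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("wrote results/bulks/bulk_membership.json")
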