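#!/usr/bin/env Rscript
# Stage 3: reference-guided assembly of the sequenced parent.
#
# Builds a pseudo-reference by substituting the parent's confident
# homozygous SNP alleles into a reference sequence, so bulk reads are
# scored against that parent's alleles. The reference and parent variant
# calls here are a small synthetic demonstration pair (deterministic under
# the stage seed); real inputs would be a genome FASTA and a parent VCF.
# Writes the edited FASTA and the substitution report under
# results/pseudo_reference/.

suppressMessages({
  library(bulkscan)
  library(Biostrings)
})

SEED <- 1L
out <- "results/pseudo_reference"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set.seed(derive_seed(SEED, "pseudo_reference_demo"))
len <- 50000L
ref <- DNAStringSet(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                          collapse = ""))
names(ref) <- "CcLG03_demo"

# synthetic parent variant calls: mostly confident homozygous SNPs, plus
# low-depth and heterozygous records the confidence filter must reject
pos <- sort(sample.int(len, 500))
ref_base <- unlist(strsplit(as.character(ref[[1]]), ""))[pos]
alt_base <- vapply(ref_base,
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
depth <- rpois(500, 15)
alt_fr <- sample(c(1, 1, 1, 0.5, 0.1), 500, replace = TRUE)
parent <- data.frame(chrom = "CcLG03_demo", pos = pos, ref = ref_base,
                     alt = unname(alt_base),
                     alt_count = round(depth * alt_fr))
parent$ref_count <- depth - parent$alt_count

subs <- filter_confident_parent_variants(parent, min_depth = 7,
                                         min_alt_fraction = 0.9)
message(sprintf("parent variants: %d called, %d confident homozygous SNPs retained",
                nrow(parent), nrow(subs)))

res <- apply_snp_substitutions(ref, subs)
message(sprintf("substitutions applied: %d, rejected: %d",
                res$n_applied, res$n_rejected))
stopifnot(res$n_applied == nrow(subs))

write_pseudo_reference(res$sequences, file.path(out, "pseudo_reference.fa"))
con <- file(file.path(out, "substitution_report.tsv"), "w")
writeLines("# coordinates: 1-based inclusive", con)
write.table(res$report, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)
message("wrote ", out, "/pseudo_reference.fa and substitution_report.tsv")
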