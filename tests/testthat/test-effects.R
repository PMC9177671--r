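# A small two-gene model set used across tests:
#   geneA (+): exons 101-160 and 181-250, CDS 121-160 + 181-242 (102 bp)
#   geneB (-): exons 301-360 and 401-450, CDS 310-360 + 401-436 (87 bp)
make_test_models <- function(genome_seed = 7) {
  g <- make_test_genome(genome_seed, len = 600)
  gff <- withr::local_tempfile(fileext = ".gff3",
                               .local_envir = parent.frame())
  write_test_gff(
    gff, "chr1",
    genes = data.frame(gene_id = c("geneA", "geneB"),
                       strand = c("+", "-"),
                       start = c(101, 301), end = c(250, 450)),
    exons = list(geneA = rbind(c(101, 160), c(181, 250)),
                 geneB = rbind(c(301, 360), c(401, 450))),
    cds = list(geneA = rbind(c(121, 160), c(181, 242)),
               geneB = rbind(c(310, 360), c(401, 436))))
  list(genome = g, models = read_gene_models(gff))
}

test_that("variants are located as exon, intron or intergenic", {
  tm <- make_test_models()
  loc <- locate_variant(tm$models, rep("chr1", 5),
                        c(130, 170, 50, 260, 420))
  expect_equal(loc$region_class,
               c("exon", "intron", "intergenic", "intergenic", "exon"))
  expect_equal(loc$gene_id, c("geneA", "geneA", NA, NA, "geneB"))
  expect_error(locate_variant(tm$models, "chrZ", 1), "absent")
})

test_that("codon changes reproduce the canonical worked examples", {
  # plus-strand CDS 1-12 spelling ATG ACG CTG TAA
  g <- Biostrings::DNAStringSet(c(chr1 = paste0("ATGACGCTGTAA",
                                                strrep("A", 20))))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff(gff, "chr1",
                 genes = data.frame(gene_id = "g1", strand = "+",
                                    start = 1, end = 12),
                 exons = list(g1 = rbind(c(1, 12))),
                 cds = list(g1 = rbind(c(1, 12))))
  models <- read_gene_models(gff)
  # middle base of codon 2: aCg -> aTg is Thr -> Met, non-synonymous
  cc <- codon_change(g, models, "g1", "chr1", 5, "T")
  expect_equal(cc$codon_ref, "aCg")
  expect_equal(cc$codon_alt, "aTg")
  expect_equal(cc$aa_ref, "T")
  expect_equal(cc$aa_alt, "M")
  expect_equal(cc$effect, "nsSNP")
  # wobble position of codon 3: ctG -> ctA stays Leu, synonymous
  cc2 <- codon_change(g, models, "g1", "chr1", 9, "A")
  expect_equal(cc2$codon_ref, "ctG")
  expect_equal(cc2$codon_alt, "ctA")
  expect_equal(cc2$effect, "sSNP")
})

test_that("minus-strand annotation equals the reverse-complemented twin", {
  # the same transcript ATG ACG CTG TAA planted on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGACGCTGTAA")))
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("G", 100), rc,
                                                strrep("G", 20))))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff(gff, "chr1",
                 genes = data.frame(gene_id = "gm", strand = "-",
                                    start = 101, end = 112),
                 exons = list(gm = rbind(c(101, 112))),
                 cds = list(gm = rbind(c(101, 112))))
  models <- read_gene_models(gff)
  # transcript offset 4 (middle of codon 2) maps to genomic 112 - 4 = 108;
  # transcript C -> T is plus-strand G -> A
  cc <- codon_change(g, models, "gm", "chr1", 108, "A")
  expect_equal(cc$codon_ref, "aCg")
  expect_equal(cc$codon_alt, "aTg")
  expect_equal(cc$effect, "nsSNP")
})

test_that("effect calls match a full-CDS translation oracle on random models", {
  skip_if_not_installed("seqinr")
  tm <- make_test_models()
  models <- tm$models
  g <- tm$genome
  set.seed(41)
  for (gene in c("geneA", "geneB")) {
    cds_tab <- models$cds[models$cds$gene_id == gene, ]
    strand <- cds_tab$strand[1]
    cds_pos <- unlist(lapply(seq_len(nrow(cds_tab)), function(j) {
      cds_tab$start[j]:cds_tab$end[j]
    }))
    ref_prot <- oracle_protein(g, cds_tab, strand)
    for (pos in sample(cds_pos, 25)) {
      ref_base <- as.character(Biostrings::subseq(g[["chr1"]], pos, pos))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
      cc <- codon_change(g, models, gene, "chr1", pos, alt)
      alt_prot <- oracle_protein(g, cds_tab, strand,
                                 variant = list(pos = pos, alt = alt))
      oracle_effect <- if (identical(ref_prot, alt_prot)) "sSNP" else "nsSNP"
      expect_equal(cc$effect, oracle_effect,
                   info = paste(gene, pos, alt))
      # the changed amino acid matches the oracle protein at that codon
      diff_idx <- which(strsplit(ref_prot, "")[[1]] !=
                          strsplit(alt_prot, "")[[1]])
      if (length(diff_idx) == 1) {
        expect_equal(cc$aa_alt, substr(alt_prot, diff_idx, diff_idx))
      }
    }
  }
})

test_that("UTR exon positions are exonic but non-coding", {
  tm <- make_test_models()
  sites <- data.frame(chrom = "chr1", pos = c(105, 130, 245),
                      alt = c("A", "A", "A"))
  eff <- annotate_effects(sites, tm$models, tm$genome)
  expect_equal(eff$region_class, c("exon", "exon", "exon"))
  expect_equal(eff$effect[1], "non-coding")  # 5' UTR of geneA
  expect_equal(eff$effect[3], "non-coding")  # 3' UTR of geneA
  expect_true(eff$effect[2] %in% c("sSNP", "nsSNP"))
})

test_that("region class counts partition the SNPs", {
  tm <- make_test_models()
  set.seed(4)
  sites <- data.frame(chrom = "chr1", pos = sample.int(600, 80),
                      alt = sample(c("A", "C", "G", "T"), 80, replace = TRUE))
  eff <- annotate_effects(sites, tm$models, tm$genome)
  s <- summarize_region_effects(eff)
  expect_equal(s$n_exon + s$n_intron + s$n_intergenic, nrow(sites))
  expect_equal(s$n_genic, s$n_exon + s$n_intron)
  expect_equal(summarize_region_effects(eff[0, ])$n_snps, 0)
})

test_that("published genic-SNP tables summarize to their reported censuses", {
  df_tab <- read_reported_effects(
    system.file("extdata", "df_region_genic_snps.tsv", package = "bulkscan"))
  s_df <- summarize_region_effects(df_tab)
  expect_equal(s_df$n_snps, 9)
  expect_equal(s_df$n_genes, 7)
  expect_equal(s_df$n_exon, 2)
  expect_equal(s_df$n_intron, 7)
  leaf_tab <- read_reported_effects(
    system.file("extdata", "leaf_region_genic_snps.tsv",
                package = "bulkscan"))
  s_lf <- summarize_region_effects(leaf_tab)
  expect_equal(s_lf$n_snps, 39)
  expect_equal(s_lf$n_genes, 20)
  expect_equal(s_lf$n_exon, 8)
  expect_equal(s_lf$n_nssnp, 4)
  expect_equal(s_lf$n_ssnp, 4)
})
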