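# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no binary fixtures.

# --- site-count builders -----------------------------------------------------

toy_sites <- function(high_ref, high_alt, low_ref, low_alt,
                      chrom = "chr1", pos = NULL) {
  n <- length(high_ref)
  out <- data.frame(
    chrom = rep(chrom, n),
    pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
    ref = rep("A", n), alt = rep("G", n),
    high_ref = high_ref, high_alt = high_alt,
    low_ref = low_ref, low_alt = low_alt,
    stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

random_records <- function(n = 200, seed = 42, chroms = c("c1", "c2")) {
  set.seed(seed)
  sites <- toy_sites(
    high_ref = rbinom(n, 20, 0.5), high_alt = rbinom(n, 20, 0.5),
    low_ref = rbinom(n, 20, 0.5), low_alt = rbinom(n, 20, 0.5))
  sites$chrom <- sample(chroms, n, replace = TRUE)
  sites$pos <- sample.int(5e6, n)
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  compute_snp_indices(sites)
}

# --- brute-force sliding-window oracle (naive double loop) -------------------

brute_force_windows <- function(records, window_size, step) {
  out <- list()
  for (ch in unique(records$chrom)) {
    rec <- records[records$chrom == ch, ]
    starts0 <- seq(0, max(rec$pos) - 1, by = step)
    for (s0 in starts0) {
      inw <- rec$pos - 1 >= s0 & rec$pos - 1 < s0 + window_size
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s0 + 1, end = s0 + window_size,
        n_snps = sum(inw),
        mean_index_high = if (any(inw)) mean(rec$snp_index_high[inw]) else NA,
        mean_index_low = if (any(inw)) mean(rec$snp_index_low[inw]) else NA,
        mean_delta = if (any(inw)) mean(rec$delta[inw]) else NA)
    }
  }
  do.call(rbind, out)
}

# --- exact null-delta distribution (no sampling) -----------------------------
# Bulk allele frequency: sum of bulk_size F2 dosages ~ Binomial(2B, 1/2);
# alt count | f ~ Binomial(depth, f). Full pmf by total probability.

exact_null_pmf <- function(depth_high, depth_low, bulk_size) {
  index_pmf <- function(depth) {
    s <- 0:(2 * bulk_size)
    pf <- dbinom(s, 2 * bulk_size, 0.5)
    k <- 0:depth
    p <- vapply(k, function(kk) sum(pf * dbinom(kk, depth, s / (2 * bulk_size))),
                numeric(1))
    list(value = k / depth, p = p)
  }
  ih <- index_pmf(depth_high)
  il <- index_pmf(depth_low)
  d <- outer(ih$value, il$value, `-`)
  p <- outer(ih$p, il$p)
  agg <- tapply(as.vector(p), round(as.vector(d), 10), sum)
  data.frame(delta = as.numeric(names(agg)), p = as.vector(agg))
}

exact_pmf_quantile <- function(pmf, q) {
  pmf <- pmf[order(pmf$delta), ]
  cdf <- cumsum(pmf$p)
  pmf$delta[which(cdf >= q - 1e-12)[1]]
}

# --- tiny genome + GFF3 builders for effect annotation -----------------------

make_test_genome <- function(seed = 7, len = 600, chrom = "chr1") {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom
  g
}

# features: data.frame(gene_id, strand, gene_start, gene_end) plus lists of
# exon and CDS interval matrices per gene
write_test_gff <- function(path, chrom, genes, exons, cds) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, paste(chrom, "test", "gene", g$start, g$end, ".",
                            g$strand, ".", paste0("ID=", g$gene_id),
                            sep = "\t"))
    mrna_id <- paste0(g$gene_id, ".t1")
    lines <- c(lines, paste(chrom, "test", "mRNA", g$start, g$end, ".",
                            g$strand, ".",
                            paste0("ID=", mrna_id, ";Parent=", g$gene_id),
                            sep = "\t"))
    ex <- exons[[g$gene_id]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(chrom, "test", "exon", ex[j, 1], ex[j, 2],
                              ".", g$strand, ".",
                              paste0("Parent=", mrna_id), sep = "\t"))
    }
    cd <- cds[[g$gene_id]]
    if (!is.null(cd)) {
      # phase of successive CDS pieces in transcript order
      widths <- cd[, 2] - cd[, 1] + 1
      ord <- if (g$strand == "-") rev(seq_len(nrow(cd))) else seq_len(nrow(cd))
      phase <- integer(nrow(cd))
      done <- 0
      for (j in ord) {
        phase[j] <- (3 - done %% 3) %% 3
        done <- done + widths[j]
      }
      for (j in seq_len(nrow(cd))) {
        lines <- c(lines, paste(chrom, "test", "CDS", cd[j, 1], cd[j, 2],
                                ".", g$strand, phase[j],
                                paste0("Parent=", mrna_id), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  path
}

# Translate a gene's spliced CDS with seqinr (independent of Biostrings)
# and return the protein string; used as the brute-force effect oracle.
oracle_protein <- function(sequences, cds_tab, strand, variant = NULL) {
  chrom <- cds_tab$chrom[1]
  seq_chars <- strsplit(as.character(sequences[[chrom]]), "")[[1]]
  if (!is.null(variant)) seq_chars[variant$pos] <- variant$alt
  cds_tab <- cds_tab[order(cds_tab$start), ]
  spliced <- unlist(lapply(seq_len(nrow(cds_tab)), function(j) {
    seq_chars[cds_tab$start[j]:cds_tab$end[j]]
  }))
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    spliced <- rev(unname(comp[spliced]))
  }
  paste(seqinr::translate(tolower(spliced)), collapse = "")
}

# small simulation config used widely in tests (fast but same study design
# parameters: 179 F2s, 15-plant bulks, depth 14)
fast_config <- function(seed, n_markers = 800L, length_bp = 10e6,
                        cm_length = 30, additive = 19, dominance = -6,
                        qtl_pos = 5e6, ...) {
  sim_config(
    chromosomes = data.frame(chrom = "c1", length_bp = length_bp,
                             n_markers = n_markers, cm_length = cm_length),
    qtl = data.frame(chrom = "c1", pos = qtl_pos, trait = "DF",
                     additive = additive, dominance = dominance,
                     mendelian = FALSE),
    seed = seed, ...)
}

run_fast_scan <- function(seed, ...) {
  cfg <- fast_config(seed, ...)
  sim <- simulate_f2(cfg)
  b <- select_extreme_bulks(sim$phenotypes, "DF", cfg$bulk_size)
  hi <- sample_bulk_counts(sim, b$high, cfg, seed = derive_seed(seed, "hi"))
  lo <- sample_bulk_counts(sim, b$low, cfg, seed = derive_seed(seed, "lo"))
  rec <- flag_causal(apply_site_filters(compute_snp_indices(
    make_site_counts(hi, lo))))
  list(cfg = cfg, sim = sim, bulks = b, records = rec)
}
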