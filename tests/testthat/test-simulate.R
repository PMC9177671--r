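test_that("Haldane map function matches its closed form", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(50), 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(haldane_r(50), 0.3161, tolerance = 2e-4)
  # monotone, bounded below 1/2
  d <- seq(0, 500, by = 10)
  expect_true(all(diff(haldane_r(d)) > 0))
  expect_true(all(haldane_r(d) < 0.5))
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_individuals = 20, bulk_size = 15),
               "n_individuals")
  expect_error(sim_config(qtl = data.frame(chrom = "nope", pos = 1,
                                           trait = "DF", additive = 1,
                                           dominance = 0,
                                           mendelian = FALSE)),
               "undeclared chromosome")
  expect_error(fast_config(1, qtl_pos = 99e6), "outside")
  expect_error(sim_config(seq_error_rate = 0.7), "seq_error_rate")
})

test_that("marker dosages segregate 1:2:1 and leaf classes 3:1", {
  cfg <- sim_config(n_individuals = 1200,
                    chromosomes = data.frame(chrom = "c1", length_bp = 1e6,
                                             n_markers = 50L,
                                             cm_length = 50),
                    qtl = data.frame(chrom = "c1", pos = 5e5,
                                     trait = "leaf_shape", additive = NA,
                                     dominance = NA, mendelian = TRUE),
                    seed = 3)
  sim <- simulate_f2(cfg)
  n <- cfg$n_individuals
  # per-marker dosage frequencies within 3 binomial SEs of 1/4, 1/2, 1/4
  for (k in 0:2) {
    p <- c(0.25, 0.5, 0.25)[k + 1]
    freq <- colMeans(sim$genotypes == k)
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(freq - p) < 3 * se + 1e-9),
                info = paste("dosage", k))
  }
  # leaf classes: recessive rule, consistent with 3:1
  cls <- table(sim$phenotypes$leaf_shape)
  chi <- segregation_chi_square(c(cls[["lanceolate"]], cls[["obcordate"]]))
  expect_gt(chi$p_value, 0.001)
  # class is a deterministic function of dosage at the causal marker
  mk <- sim$truth$qtl[[1]]$marker_index
  expect_identical(sim$phenotypes$leaf_shape == "obcordate",
                   unname(sim$genotypes[, mk] == 2L))
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_f2(fast_config(9, n_markers = 60L))
  s2 <- simulate_f2(fast_config(9, n_markers = 60L))
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  c1 <- sample_bulk_counts(s1, s1$phenotypes$id[1:15], fast_config(9), seed = 4)
  c2 <- sample_bulk_counts(s2, s2$phenotypes$id[1:15], fast_config(9), seed = 4)
  expect_identical(c1, c2)
  c3 <- sample_bulk_counts(s2, s2$phenotypes$id[1:15], fast_config(9), seed = 5)
  expect_false(identical(c1$alt_count, c3$alt_count))
})

test_that("realized depth tracks the configured mean within 2%", {
  cfg <- fast_config(11, n_markers = 5000L)
  sim <- simulate_f2(cfg)
  cnt <- sample_bulk_counts(sim, sim$phenotypes$id[1:15], cfg, seed = 1)
  cnt2 <- sample_bulk_counts(sim, sim$phenotypes$id[16:30], cfg, seed = 2)
  depth <- c(cnt$ref_count + cnt$alt_count, cnt2$ref_count + cnt2$alt_count)
  expect_gt(length(depth), 1e4)
  expect_lt(abs(mean(depth) - cfg$mean_depth) / cfg$mean_depth, 0.02)
})

test_that("monomorphic and neutral bulks give the expected SNP-index", {
  cfg <- fast_config(13, n_markers = 400L, seq_error_rate = 0)
  sim <- simulate_f2(cfg)
  # force a bulk fixed homozygous for the reference allele at every marker
  sim$genotypes[1:15, ] <- 2L
  cnt <- sample_bulk_counts(sim, sim$phenotypes$id[1:15], cfg, seed = 21)
  expect_true(all(cnt$alt_count == 0))
  # loosely linked neutral markers (10 cM spacing): SNP-index averages 0.5
  # in a random bulk once the genetic draws decorrelate along the map
  cfg2 <- fast_config(14, n_markers = 2000L, cm_length = 20000,
                      additive = 0, dominance = 0)
  sim2 <- simulate_f2(cfg2)
  cnt2 <- sample_bulk_counts(sim2, sim2$phenotypes$id[1:15], cfg2, seed = 8)
  idx <- cnt2$alt_count / (cnt2$ref_count + cnt2$alt_count)
  expect_equal(mean(idx, na.rm = TRUE), 0.5, tolerance = 0.02)
})

test_that("a dominant-class bulk shows 1/3:2/3 allele frequencies at the causal locus", {
  # within the dominant (lanceolate) class AA:Aa = 1:2, so the recessive
  # (reference-parent) allele frequency is 1/3 and the dominant-allele
  # SNP-index 2/3
  cfg <- sim_config(n_individuals = 3000,
                    chromosomes = data.frame(chrom = "c1", length_bp = 1e6,
                                             n_markers = 10L,
                                             cm_length = 10),
                    qtl = data.frame(chrom = "c1", pos = 5e5,
                                     trait = "leaf_shape", additive = NA,
                                     dominance = NA, mendelian = TRUE),
                    mean_depth = 20, seq_error_rate = 0, seed = 17)
  sim <- simulate_f2(cfg)
  mk <- sim$truth$qtl[[1]]$marker_index
  lan <- sim$phenotypes$id[sim$phenotypes$leaf_shape == "lanceolate"]
  dos <- sim$genotypes[lan, mk]
  expect_equal(mean(dos) / 2, 1 / 3, tolerance = 0.03)  # recessive allele
  cnt <- sample_bulk_counts(sim, lan, cfg, seed = 30)
  idx_alt <- cnt$alt_count[mk] / (cnt$ref_count[mk] + cnt$alt_count[mk])
  expect_equal(idx_alt, 2 / 3, tolerance = 0.1)  # dominant-allele index
})

test_that("the planted QTL explains the configured phenotypic variance", {
  cfg <- sim_config(n_individuals = 2000,
                    chromosomes = data.frame(chrom = "c1", length_bp = 5e6,
                                             n_markers = 40L,
                                             cm_length = 20),
                    qtl = data.frame(chrom = "c1", pos = 2.5e6,
                                     trait = "DF", additive = 19,
                                     dominance = -6, mendelian = FALSE),
                    seed = 23)
  sim <- simulate_f2(cfg)
  mk <- sim$truth$qtl[[1]]$marker_index
  dos <- factor(sim$genotypes[, mk])
  r2 <- summary(lm(sim$phenotypes$DF ~ dos))$r.squared
  a <- 19; d <- -6; s2 <- cfg$trait_noise_sd^2
  pve_expected <- (a^2 / 2 + d^2 / 4) / (a^2 / 2 + d^2 / 4 + s2)
  expect_lt(abs(r2 - pve_expected), 0.05)
})

test_that("bulk count sampling rejects bad membership", {
  sim <- simulate_f2(fast_config(31, n_markers = 50L))
  expect_error(sample_bulk_counts(sim, character(0), fast_config(31), seed = 1),
               "empty bulk")
  expect_error(sample_bulk_counts(sim, c("F2_001", "ghost"),
                                  fast_config(31), seed = 1),
               "unknown bulk member")
})

test_that("a simulated dataset round-trips through VCF and TSV", {
  cfg <- fast_config(37, n_markers = 80L)
  sim <- simulate_f2(cfg)
  b <- select_extreme_bulks(sim$phenotypes, "DF", 15)
  hi <- sample_bulk_counts(sim, b$high, cfg, seed = 1)
  lo <- sample_bulk_counts(sim, b$low, cfg, seed = 2)
  sites <- make_site_counts(hi, lo)
  dir <- withr::local_tempdir()
  paths <- write_sim_dataset(sim, sites, b, dir,
                             high_name = "LF", low_name = "EF")
  back_vcf <- read_counts_vcf(paths[["vcf"]], "LF", "EF")
  back_tsv <- read_counts_tsv(paths[["tsv"]])
  for (col in c("chrom", "pos", "ref", "alt", "high_ref", "high_alt",
                "low_ref", "low_alt")) {
    expect_equal(back_vcf[[col]], sites[[col]], info = col)
    expect_equal(back_tsv[[col]], sites[[col]], info = col)
  }
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$qtl[[1]]$causal_pos, 5e6)
  expect_length(truth$bulks$high, 15)
})
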