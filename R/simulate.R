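#' Haldane map function
#'
#' Recombination fraction between two loci separated by a genetic distance,
#' assuming crossovers occur as a Poisson process with no interference:
#' r = (1 - exp(-2 d)) / 2 with d in Morgans.
#'
#' @param d_cm Genetic distance in centimorgans (vectorised).
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
#' @examples
#' haldane_r(0)    # 0
#' haldane_r(50)   # ~0.316
haldane_r <- function(d_cm) {
  stopifnot(all(d_cm >= 0))
  0.5 * (1 - exp(-2 * d_cm / 100))
}

#' Simulation configuration for an F2 bulk-sequencing experiment
#'
#' The defaults reproduce the design of the pigeonpea ICP 5529 x ICP 11605
#' cross this package models: an F2 of 179 individuals from parents differing
#' at a major days-to-flowering (DF) QTL (parental means 105 and 67 days) and
#' at a recessive obcordate leaf-shape locus segregating 3:1, with 15-plant
#' extreme bulks sequenced to ~14x mean depth. Genotype dosage counts the
#' reference-parent (late-flowering, obcordate) allele, so at a trait locus the
#' high bulk carries dosage ~2 and the sequenced ALT allele (the other
#' parent's) has SNP-index ~0 there.
#'
#' @param n_individuals Number of F2 plants.
#' @param chromosomes data.frame with columns `chrom`, `length_bp`,
#'   `n_markers`, `cm_length`.
#' @param qtl data.frame with columns `chrom`, `pos`, `trait`, `additive`,
#'   `dominance`, `mendelian`. For a quantitative trait the phenotype is
#'   `baseline + additive*(dosage-1) + dominance*[dosage==1] + noise` (days);
#'   a `mendelian` locus yields a two-class trait, recessive in the
#'   reference-parent allele (class 2 iff dosage == 2).
#' @param baseline_df Mid-parent days-to-flowering baseline.
#' @param trait_noise_sd Residual standard deviation of the quantitative
#'   trait, in days.
#' @param misclass_prob Probability that a Mendelian phenotype class is
#'   recorded wrongly (0 = noiseless scoring).
#' @param bulk_size Plants per extreme bulk.
#' @param mean_depth Mean sequencing depth per site per bulk.
#' @param depth_model `"poisson"` (default) or `"fixed"` (every site at
#'   exactly `mean_depth`, for exact oracles).
#' @param seq_error_rate Symmetric per-read allele-flip probability.
#' @param seed Master seed for the simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 179L,
                       chromosomes = data.frame(
                         chrom = c("CcLG03", "CcLG08"),
                         length_bp = c(30e6, 30e6),
                         n_markers = c(2400L, 2400L),
                         cm_length = c(90, 90)
                       ),
                       qtl = data.frame(
                         chrom = c("CcLG03", "CcLG08"),
                         pos = c(19.5e6, 7.5e6),
                         trait = c("DF", "leaf_shape"),
                         additive = c(19, NA),
                         dominance = c(-6, NA),
                         mendelian = c(FALSE, TRUE)
                       ),
                       baseline_df = 86,
                       trait_noise_sd = 14,
                       misclass_prob = 0,
                       bulk_size = 15L,
                       mean_depth = 14,
                       depth_model = c("poisson", "fixed"),
                       seq_error_rate = 0.001,
                       seed = 1L) {
  depth_model <- match.arg(depth_model)
  stopifnot(
    n_individuals >= 2L * bulk_size,
    seq_error_rate >= 0, seq_error_rate < 0.5,
    mean_depth > 0,
    misclass_prob >= 0, misclass_prob <= 1,
    all(c("chrom", "length_bp", "n_markers", "cm_length") %in%
          names(chromosomes)),
    all(c("chrom", "pos", "trait", "mendelian") %in% names(qtl))
  )
  off <- !(qtl$chrom %in% chromosomes$chrom)
  if (any(off)) {
    stop("QTL declared on undeclared chromosome(s): ",
         paste(unique(qtl$chrom[off]), collapse = ", "))
  }
  len <- chromosomes$length_bp[match(qtl$chrom, chromosomes$chrom)]
  if (any(qtl$pos < 1 | qtl$pos > len)) {
    stop("QTL position(s) outside the declared chromosome length")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         chromosomes = chromosomes, qtl = qtl,
         baseline_df = baseline_df, trait_noise_sd = trait_noise_sd,
         misclass_prob = misclass_prob,
         bulk_size = as.integer(bulk_size), mean_depth = mean_depth,
         depth_model = depth_model, seq_error_rate = seq_error_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Marker map: evenly spaced positions per chromosome, with causal positions
# forced onto the map so every truth record points at a real marker.
build_marker_map <- function(config) {
  maps <- lapply(seq_len(nrow(config$chromosomes)), function(i) {
    ch <- config$chromosomes[i, ]
    pos <- round(seq(1, ch$length_bp, length.out = ch$n_markers))
    qpos <- config$qtl$pos[config$qtl$chrom == ch$chrom]
    pos <- sort(unique(c(pos, round(qpos))))
    data.frame(chrom = ch$chrom, pos = pos,
               cm = pos / ch$length_bp * ch$cm_length)
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  map
}

#' Simulate an F2 population with seeded meiosis and phenotypes
#'
#' Each F2 plant is formed from two independent F1 gametes. Along each
#' chromosome a gamete's marker alleles follow a Markov chain whose
#' inter-marker switch probability is the Haldane recombination fraction for
#' the inter-marker genetic distance (no crossover interference). Marker
#' dosages therefore segregate 1:2:1 in expectation. Quantitative phenotypes
#' add Gaussian noise to the QTL genetic value; Mendelian phenotypes follow
#' the recessive rule (class 2 only for dosage 2 homozygotes).
#'
#' @param config A [sim_config()].
#' @return A list of class `f2_sim` with elements `markers` (chrom, pos, cm,
#'   ref, alt), `genotypes` (individuals x markers dosage matrix of the
#'   reference-parent allele), `phenotypes` (data.frame `id` plus one column
#'   per trait), and `truth` (causal marker, effects, config echo).
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- build_marker_map(config)
  n <- config$n_individuals
  ids <- sprintf("F2_%03d", seq_len(n))

  local_seed(derive_seed(config$seed, "simulate_f2"), {
    geno <- matrix(0L, nrow = n, ncol = nrow(map))
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      m <- length(idx)
      r <- haldane_r(diff(map$cm[idx]))
      # 2n gametes in parallel; allele 1 = reference-parent allele
      g <- matrix(0L, nrow = 2L * n, ncol = m)
      g[, 1L] <- stats::rbinom(2L * n, 1L, 0.5)
      if (m > 1L) {
        for (j in 2L:m) {
          switch_ <- stats::rbinom(2L * n, 1L, r[j - 1L])
          g[, j] <- bitwXor(g[, j - 1L], switch_)
        }
      }
      geno[, idx] <- g[seq_len(n), , drop = FALSE] +
        g[n + seq_len(n), , drop = FALSE]
    }
    colnames(geno) <- paste(map$chrom, map$pos, sep = ":")
    rownames(geno) <- ids

    # biallelic marker alleles: REF = reference-parent allele base
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nrow(map), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    map$ref <- ref
    map$alt <- unname(alt)

    phen <- data.frame(id = ids, stringsAsFactors = FALSE)
    truth_qtl <- list()
    for (k in seq_len(nrow(config$qtl))) {
      q <- config$qtl[k, ]
      mk <- which(map$chrom == q$chrom & map$pos == round(q$pos))
      stopifnot(length(mk) == 1L)
      dos <- geno[, mk]
      if (isTRUE(q$mendelian)) {
        cls <- ifelse(dos == 2L, "obcordate", "lanceolate")
        if (config$misclass_prob > 0) {
          flip <- stats::runif(n) < config$misclass_prob
          cls[flip] <- ifelse(cls[flip] == "obcordate",
                              "lanceolate", "obcordate")
        }
        phen[[q$trait]] <- cls
        eff <- list(mode = "mendelian_recessive")
      } else {
        val <- config$baseline_df + q$additive * (dos - 1L) +
          q$dominance * (dos == 1L) +
          stats::rnorm(n, 0, config$trait_noise_sd)
        phen[[q$trait]] <- round(val, 2)
        eff <- list(mode = "quantitative", additive = q$additive,
                    dominance = q$dominance,
                    baseline = config$baseline_df,
                    noise_sd = config$trait_noise_sd)
      }
      truth_qtl[[k]] <- c(list(trait = q$trait, chrom = q$chrom,
                               causal_pos = round(q$pos),
                               marker_index = mk), eff)
    }

    structure(
      list(markers = map, genotypes = geno, phenotypes = phen,
           truth = list(qtl = truth_qtl, seed = config$seed,
                        n_individuals = n, bulk_size = config$bulk_size)),
      class = "f2_sim"
    )
  })
}

#' Sample pooled sequencing read counts for a bulk
#'
#' Models equimolar pooling of bulk members (equal contribution per plant):
#' the true ALT-allele frequency at a marker is
#' `1 - sum(dosage) / (2 * bulk size)` (dosage counts the reference-parent
#' allele, ALT is the other parent's allele). Depth is Poisson (or fixed) with
#' the configured mean and the observed alt count is Binomial(depth,
#' f*(1-e) + (1-f)*e) with symmetric sequencing error `e`.
#'
#' @param sim An `f2_sim` object.
#' @param bulk_ids Character ids of the bulk members.
#' @param config The [sim_config()] used (depth model, error rate).
#' @param seed Integer seed; fixed seed gives identical counts.
#' @param mean_depth,depth_model,seq_error_rate Optional overrides of the
#'   config values.
#' @return data.frame: chrom, pos, ref, alt, ref_count, alt_count.
#' @export
sample_bulk_counts <- function(sim, bulk_ids, config, seed,
                               mean_depth = config$mean_depth,
                               depth_model = config$depth_model,
                               seq_error_rate = config$seq_error_rate) {
  stopifnot(inherits(sim, "f2_sim"))
  if (length(bulk_ids) == 0L) stop("empty bulk")
  missing_ids <- setdiff(bulk_ids, rownames(sim$genotypes))
  if (length(missing_ids) > 0L) {
    stop("unknown bulk member(s): ", paste(missing_ids, collapse = ", "))
  }
  dos <- sim$genotypes[bulk_ids, , drop = FALSE]
  f_ref <- colSums(dos) / (2 * length(bulk_ids))
  f_alt <- 1 - f_ref
  e <- seq_error_rate
  p_alt <- f_alt * (1 - e) + (1 - f_alt) * e
  m <- length(p_alt)
  local_seed(seed, {
    depth <- if (identical(depth_model, "fixed")) {
      rep.int(as.integer(round(mean_depth)), m)
    } else {
      stats::rpois(m, mean_depth)
    }
    alt_count <- stats::rbinom(m, depth, p_alt)
    data.frame(chrom = sim$markers$chrom, pos = sim$markers$pos,
               ref = sim$markers$ref, alt = sim$markers$alt,
               ref_count = depth - alt_count, alt_count = alt_count,
               stringsAsFactors = FALSE)
  })
}

#' Combine per-bulk counts into a two-bulk site table
#'
#' @param high,low data.frames from [sample_bulk_counts()] over the same
#'   markers (high = high-trait bulk, low = low-trait bulk).
#' @return data.frame of class `site_counts`: chrom, pos, ref, alt,
#'   high_ref, high_alt, low_ref, low_alt.
#' @export
make_site_counts <- function(high, low) {
  stopifnot(identical(high$chrom, low$chrom), identical(high$pos, low$pos))
  out <- data.frame(chrom = high$chrom, pos = high$pos,
                    ref = high$ref, alt = high$alt,
                    high_ref = high$ref_count, high_alt = high$alt_count,
                    low_ref = low$ref_count, low_alt = low$alt_count,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Write a complete simulated dataset to disk
#'
#' Emits the standard bundle: bulk counts as VCF 4.2 (per-bulk AD field) and
#' TSV, the phenotype table, and the ground-truth JSON used by recovery tests.
#' All file coordinates are 1-based.
#'
#' @param sim An `f2_sim`.
#' @param sites A `site_counts` table (two bulks).
#' @param bulks Named list with `high` and `low` id vectors.
#' @param dir Output directory (created if absent).
#' @param high_name,low_name Sample names used in the VCF.
#' @return Invisibly, the vector of paths written.
#' @export
write_sim_dataset <- function(sim, sites, bulks, dir,
                              high_name = "HIGH", low_name = "LOW") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "bulk_counts.vcf"),
    tsv = file.path(dir, "bulk_counts.tsv"),
    phen = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  chrom_lengths <- tapply(sim$markers$pos, sim$markers$chrom, max)
  write_counts_vcf(sites, paths[["vcf"]], high_name = high_name,
                   low_name = low_name, chrom_lengths = chrom_lengths)
  write_counts_tsv(sites, paths[["tsv"]])
  write_phenotypes(sim$phenotypes, paths[["phen"]])
  truth <- sim$truth
  truth$bulks <- bulks
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
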