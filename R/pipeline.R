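#' Run the full bulked-segregant scan end to end
#'
#' Stages, in order: extreme-bulk selection (when phenotypes are supplied),
#' pseudo-reference construction (when a parent variant table and reference
#' are supplied), per-site SNP-index statistics and filters, sliding
#' windows, null confidence bands and region calling, and (when gene models
#' are supplied) effect annotation of causal SNPs in the called regions.
#' Every stochastic stage draws its seed from the single run seed by stable
#' hashing of the stage name, so runs are fully reproducible and one stage's
#' draws are insensitive to the others.
#'
#' @param sites A `site_counts` table (or path to a counts TSV/VCF written
#'   by this package; VCF paths need `high_name`/`low_name`).
#' @param out_dir Output directory; per-stage TSVs and a summary are
#'   written there (NULL = nothing written).
#' @param phenotypes Optional phenotype table (id + trait columns) from
#'   which bulks are reported.
#' @param trait Trait label for reports (and bulk selection).
#' @param bulk_size Plants per bulk.
#' @param reference,parent_variants Optional FASTA (path or DNAStringSet)
#'   and parent variant table for the pseudo-reference stage.
#' @param models Optional `gene_models` (or GFF3 path) for effect
#'   annotation; requires `reference`.
#' @param min_depth,min_index,hom_threshold Site-filter parameters.
#' @param window_size,step Sliding-window parameters (bp).
#' @param alpha Region-calling level (default 0.05).
#' @param min_causal_snps Causal-SNP rule threshold for regions.
#' @param n_reps Null replicates per confidence band.
#' @param seed Master run seed.
#' @param high_name,low_name Sample names when `sites` is a VCF path.
#' @return list of class `bulkscan_run`: records, windows, regions, bands
#'   implicit in windows, summary (one row per region), plus bulks /
#'   pseudo-reference / effects when their inputs were given.
#' @export
run_pipeline <- function(sites, out_dir = NULL, phenotypes = NULL,
                         trait = NA_character_, bulk_size = 15L,
                         reference = NULL, parent_variants = NULL,
                         models = NULL, min_depth = 7L, min_index = 0.3,
                         hom_threshold = 0.1, window_size = 1e6,
                         step = 1e4, alpha = 0.05, min_causal_snps = 1L,
                         n_reps = 10000L, seed = 1L,
                         high_name = "HIGH", low_name = "LOW") {
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  }
  if (is.character(sites)) {
    sites <- if (grepl("\\.vcf(\\.gz)?$", sites)) {
      read_counts_vcf(sites, high_name, low_name)
    } else {
      read_counts_tsv(sites)
    }
  }
  results <- list(seed = seed, trait = trait)

  if (!is.null(phenotypes)) {
    is_cat <- !is.numeric(phenotypes[[trait]])
    results$bulks <- if (is_cat) {
      cls <- sort(unique(phenotypes[[trait]]))
      select_extreme_bulks(phenotypes, trait, bulk_size, "categorical",
                           high_class = cls[2], low_class = cls[1],
                           seed = derive_seed(seed, "bulking"))
    } else {
      select_extreme_bulks(phenotypes, trait, bulk_size, "quantitative")
    }
    log_stage("bulking", nrow(phenotypes), 2L * bulk_size)
  }

  if (!is.null(reference) && !is.null(parent_variants)) {
    subs <- filter_confident_parent_variants(parent_variants,
                                             min_depth = min_depth)
    ps <- apply_snp_substitutions(reference, subs)
    results$pseudo_reference <- ps
    reference <- ps$sequences
    log_stage("pseudo_reference", nrow(parent_variants), ps$n_applied)
  } else if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }

  records <- compute_snp_indices(sites)
  records <- apply_site_filters(records, min_depth = min_depth,
                                min_index = min_index,
                                hom_threshold = hom_threshold)
  records <- flag_causal(records)
  log_stage("snp_index", nrow(sites), sum(records$pass))
  results$records <- records

  windows <- sliding_window_means(records[records$pass_window, ],
                                  window_size = window_size, step = step)
  called <- call_regions(windows, alpha = alpha, bulk_size = bulk_size,
                         n_reps = n_reps,
                         seed = derive_seed(seed, "null_ci"),
                         step = step, records = records,
                         min_causal_snps = min_causal_snps, trait = trait)
  results$windows <- called$windows
  results$regions <- called$regions
  log_stage("null_ci_regions", nrow(windows), nrow(called$regions))

  if (!is.null(models) && !is.null(reference)) {
    if (is.character(models)) models <- read_gene_models(models)
    reg <- results$regions
    in_region <- rep(FALSE, nrow(records))
    for (i in seq_len(nrow(reg))) {
      in_region <- in_region | (records$chrom == reg$chrom[i] &
                                  records$pos >= reg$start[i] &
                                  records$pos <= reg$end[i])
    }
    cand <- records[in_region & records$causal_flag, ]
    results$effects <- if (nrow(cand) > 0) {
      annotate_effects(cand, models, reference)
    } else {
      NULL
    }
    log_stage("effect_annotation", sum(in_region), nrow(cand))
  }

  results$summary <- summarize_run(results)
  class(results) <- "bulkscan_run"
  if (!is.null(out_dir)) write_report(results, out_dir)
  results
}

summarize_run <- function(results) {
  reg <- results$regions
  if (nrow(reg) == 0L) {
    return(data.frame(trait = character(0), chrom = character(0),
                      start_mb = numeric(0), end_mb = numeric(0),
                      span_mb = numeric(0), n_causal_snps = integer(0),
                      n_genic = integer(0), n_genes = integer(0),
                      n_exon_ns = integer(0), n_exon_s = integer(0)))
  }
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    eff <- results$effects
    s <- if (!is.null(eff)) {
      summarize_region_effects(eff, reg$chrom[i], reg$start[i], reg$end[i])
    } else {
      data.frame(n_genic = NA_integer_, n_genes = NA_integer_,
                 n_nssnp = NA_integer_, n_ssnp = NA_integer_)
    }
    data.frame(trait = reg$trait[i], chrom = reg$chrom[i],
               start_mb = reg$start_mb[i], end_mb = reg$end_mb[i],
               span_mb = reg$span_mb[i],
               n_causal_snps = reg$n_causal_snps[i],
               n_genic = s$n_genic, n_genes = s$n_genes,
               n_exon_ns = s$n_nssnp, n_exon_s = s$n_ssnp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the per-stage outputs and final summary of a run
#'
#' Writes the per-site record TSV, the window TSV, regions (BED + TSV), the
#' effects TSV when present, a summary TSV and a summary JSON. Every table
#' file starts with a comment line declaring its coordinate convention.
#'
#' @param results A `bulkscan_run`.
#' @param out_dir Directory (created if absent).
#' @return Invisibly, the named vector of paths written.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  tsv <- function(d, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines("# coordinates: 1-based inclusive", con)
    utils::write.table(d, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    p
  }
  paths["records"] <- tsv(results$records, "snp_index_records.tsv")
  paths["windows"] <- tsv(results$windows, "window_stats.tsv")
  write_regions(results$regions,
                bed_path = file.path(out_dir, "regions.bed"),
                tsv_path = file.path(out_dir, "regions.tsv"))
  paths["regions"] <- file.path(out_dir, "regions.tsv")
  if (!is.null(results$effects)) {
    paths["effects"] <- tsv(results$effects, "effects.tsv")
  }
  paths["summary"] <- tsv(results$summary, "summary.tsv")
  jsonlite::write_json(
    list(seed = results$seed, trait = results$trait,
         regions = results$regions, summary = results$summary),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  paths["summary_json"] <- file.path(out_dir, "summary.json")
  invisible(paths)
}
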