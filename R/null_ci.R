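# Cache of simulated null bands, keyed by
# (depth_high, depth_low, bulk_size, n_snps, n_reps, seed).
.band_cache <- new.env(parent = emptyenv())

#' Simulate the null distribution of delta SNP-index
#'
#' Under "no QTL", each bulk of `bulk_size` F2 plants contributes marker
#' allele frequencies drawn from the 1:2:1 dosage distribution: the bulk
#' allele frequency is Binomial(2 * bulk_size, 1/2) / (2 * bulk_size).
#' Observed alt counts are Binomial(depth, frequency) per bulk, indices and
#' delta follow. With `n_snps > 1` a replicate is the MEAN delta over
#' `n_snps` sites sharing one bulk-composition draw (markers within a
#' sliding window are in near-complete linkage, so the genetic draw is
#' common while read noise is per-site and averages out) — the null for a
#' window mean rather than a single site.
#'
#' An optional redraw rule mirrors the observed-data spurious-index filter:
#' with `min_index` set, per-site replicates whose index is below it in both
#' bulks are redrawn.
#'
#' @param depth_high,depth_low Read depth per bulk (fixed per draw).
#' @param bulk_size Plants per bulk (default 15).
#' @param n_reps Number of null replicates.
#' @param n_snps Sites per replicate sharing one genetic draw (1 = per-site
#'   null).
#' @param seed Integer seed; fixed seed gives an identical sample.
#' @param min_index Optional both-bulks redraw threshold (default `NULL`,
#'   no redraw).
#' @return Numeric vector of `n_reps` null delta values.
#' @export
simulate_null_delta <- function(depth_high, depth_low, bulk_size = 15L,
                                n_reps = 10000L, n_snps = 1L, seed = 1L,
                                min_index = NULL) {
  stopifnot(depth_high >= 1, depth_low >= 1, n_reps >= 1, n_snps >= 1,
            bulk_size >= 1)
  local_seed(seed, {
    draw <- function(m) {
      f_h <- stats::rbinom(m, 2L * bulk_size, 0.5) / (2 * bulk_size)
      f_l <- stats::rbinom(m, 2L * bulk_size, 0.5) / (2 * bulk_size)
      if (n_snps == 1L) {
        ih <- stats::rbinom(m, depth_high, f_h) / depth_high
        il <- stats::rbinom(m, depth_low, f_l) / depth_low
        if (!is.null(min_index)) {
          bad <- ih < min_index & il < min_index
          while (any(bad)) {
            k <- sum(bad)
            f_h2 <- stats::rbinom(k, 2L * bulk_size, 0.5) / (2 * bulk_size)
            f_l2 <- stats::rbinom(k, 2L * bulk_size, 0.5) / (2 * bulk_size)
            ih[bad] <- stats::rbinom(k, depth_high, f_h2) / depth_high
            il[bad] <- stats::rbinom(k, depth_low, f_l2) / depth_low
            bad[bad] <- ih[bad] < min_index & il[bad] < min_index
          }
        }
        ih - il
      } else {
        # mean over n sites sharing f at common depth d: the summed alt
        # count is Binomial(n*d, f), so one draw per replicate suffices
        ih <- stats::rbinom(m, n_snps * depth_high, f_h) /
          (n_snps * depth_high)
        il <- stats::rbinom(m, n_snps * depth_low, f_l) /
          (n_snps * depth_low)
        ih - il
      }
    }
    draw(n_reps)
  })
}

#' Empirical confidence-interval bounds from a null sample
#'
#' Two-sided bounds at level `alpha`: the empirical `alpha/2` and
#' `1 - alpha/2` quantiles (inverse-ECDF, quantile type 1, so bounds are
#' attained sample values — important for the discrete small-depth null).
#'
#' @param null_sample Numeric sample of null delta values.
#' @param alpha Significance level (e.g. 0.05, 0.01).
#' @return Numeric `c(lower, upper)`.
#' @export
ci_bounds <- function(null_sample, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(null_sample) < 10 / alpha) {
    stop("null sample too small for alpha = ", alpha,
         " (need >= ", ceiling(10 / alpha), ")")
  }
  stats::quantile(null_sample, c(alpha / 2, 1 - alpha / 2),
                  type = 1, names = FALSE)
}

#' Null confidence band for a depth pair (cached)
#'
#' Simulates the null delta distribution once per distinct
#' (depth_high, depth_low, bulk_size, n_snps) and caches the alpha-level
#' bounds, so genome scans touching thousands of windows reuse a small set
#' of bands.
#'
#' @inheritParams simulate_null_delta
#' @param alphas Levels to tabulate (default 0.05 and 0.01).
#' @param cache Reuse cached bands (default TRUE).
#' @return list of class `null_ci_band`: depth_high, depth_low, bulk_size,
#'   n_snps, n_reps, bounds (named list alpha -> c(lower, upper)).
#' @export
null_ci_band <- function(depth_high, depth_low, bulk_size = 15L,
                         n_snps = 1L, n_reps = 10000L,
                         alphas = c(0.05, 0.01), seed = 1L,
                         min_index = NULL, cache = TRUE) {
  key <- paste(depth_high, depth_low, bulk_size, n_snps, n_reps, seed,
               paste(alphas, collapse = "_"),
               if (is.null(min_index)) "nofilter" else min_index,
               sep = "|")
  if (cache && !is.null(.band_cache[[key]])) return(.band_cache[[key]])
  sample_ <- simulate_null_delta(
    depth_high, depth_low, bulk_size = bulk_size, n_reps = n_reps,
    n_snps = n_snps, seed = derive_seed(seed, paste0("band|", key)),
    min_index = min_index)
  bounds <- lapply(alphas, function(a) ci_bounds(sample_, a))
  names(bounds) <- as.character(alphas)
  band <- structure(
    list(depth_high = depth_high, depth_low = depth_low,
         bulk_size = bulk_size, n_snps = n_snps, n_reps = n_reps,
         bounds = bounds),
    class = "null_ci_band")
  if (cache) .band_cache[[key]] <- band
  band
}

#' Clear the in-session null-band cache
#' @export
#' @keywords internal
clear_band_cache <- function() {
  rm(list = ls(.band_cache), envir = .band_cache)
  invisible(NULL)
}

#' Construct a candidate region record
#'
#' Boundaries are reported in Mb rounded to 2 decimals; the span is the
#' difference of the rounded boundaries, matching two-decimal reporting
#' conventions (e.g. 19.22-20.80 Mb spans 1.58 Mb).
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based bp boundaries, start < end.
#' @param alpha Significance level of the calling band.
#' @param n_causal_snps Count of causal-flagged SNPs inside the region.
#' @param trait Trait label.
#' @return One-row data.frame: chrom, start, end, start_mb, end_mb,
#'   span_mb, alpha, n_causal_snps, trait.
#' @export
#' @examples
#' candidate_region("CcLG03", 19220001, 20800000)$span_mb  # 1.58
candidate_region <- function(chrom, start, end, alpha = NA_real_,
                             n_causal_snps = NA_integer_,
                             trait = NA_character_) {
  stopifnot(start < end)
  start_mb <- round(start / 1e6, 2)
  end_mb <- round(end / 1e6, 2)
  data.frame(chrom = chrom, start = start, end = end,
             start_mb = start_mb, end_mb = end_mb,
             span_mb = round(end_mb - start_mb, 2),
             alpha = alpha, n_causal_snps = n_causal_snps, trait = trait,
             stringsAsFactors = FALSE)
}

#' Call candidate regions from sliding windows and null bands
#'
#' Each non-empty window is compared with the null band simulated at its
#' median bulk depths and member-SNP count; a window is significant when its
#' mean delta falls outside the band at `alpha`. Significant windows on one
#' chromosome separated by at most `merge_gap_steps` steps (overlapping
#' windows always) merge into one region spanning the outermost window
#' edges.
#'
#' A merged region is retained only when it contains at least
#' `min_causal_snps` causal-flagged SNPs (default 1, applied when `records`
#' are supplied). This is the delta = -1 causal-SNP rule: windows stray
#' beyond a per-window band somewhere in a null genome quite often, but a
#' fully fixed, opposite-allele SNP pair at filter-passing depth
#' essentially never arises without a linked locus, so the rule controls
#' genome-wise false positives without touching band calibration.
#'
#' @param windows Output of [sliding_window_means()].
#' @param alpha Calling level (default 0.05; both the 0.05 and 0.01 bands
#'   are simulated and cached either way).
#' @param bulk_size Plants per bulk used for the null.
#' @param n_reps Null replicates per band.
#' @param seed Band-simulation seed.
#' @param step Window step in bp (for gap merging); inferred from the
#'   windows when NULL.
#' @param merge_gap_steps Merge significant windows separated by at most
#'   this many steps (default 1).
#' @param records Optional causal-flagged per-site records; supplies
#'   per-region causal-SNP counts and enables the causal-SNP rule.
#' @param min_causal_snps Minimum causal SNPs for a region to be kept
#'   (only enforced when `records` carry a `causal_flag` column).
#' @param trait Trait label attached to regions.
#' @param min_snps Windows with fewer member SNPs are never significant.
#' @return list(regions = data.frame as [candidate_region()], windows =
#'   input windows with `lower`, `upper`, `significant` columns).
#' @export
call_regions <- function(windows, alpha = 0.05, bulk_size = 15L,
                         n_reps = 10000L, seed = 1L, step = NULL,
                         merge_gap_steps = 1L, records = NULL,
                         min_causal_snps = 1L, trait = NA_character_,
                         min_snps = 1L) {
  if (is.null(step)) {
    steps <- diff(windows$start[windows$chrom == windows$chrom[1]])
    step <- if (length(steps) > 0) min(steps) else 1e4
  }
  lower <- upper <- rep(NA_real_, nrow(windows))
  eligible <- which(windows$n_snps >= min_snps)
  for (i in eligible) {
    band <- null_ci_band(
      depth_high = max(1L, as.integer(round(windows$median_depth_high[i]))),
      depth_low = max(1L, as.integer(round(windows$median_depth_low[i]))),
      bulk_size = bulk_size, n_snps = windows$n_snps[i],
      n_reps = n_reps, seed = seed)
    b <- band$bounds[[as.character(alpha)]]
    if (is.null(b)) {
      b <- ci_bounds(simulate_null_delta(
        band$depth_high, band$depth_low, bulk_size, n_reps,
        band$n_snps, seed = derive_seed(seed, "adhoc_band")), alpha)
    }
    lower[i] <- b[1]
    upper[i] <- b[2]
  }
  windows$lower <- lower
  windows$upper <- upper
  windows$significant <- !is.na(windows$mean_delta) &
    !is.na(lower) &
    (windows$mean_delta < lower | windows$mean_delta > upper)

  regions <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch & windows$significant, ]
    if (nrow(w) == 0L) next
    w <- w[order(w$start), ]
    # windows merge when they overlap or are within merge_gap_steps steps
    grp <- cumsum(!c(TRUE, w$start[-1] <= w$end[-nrow(w)] +
                       merge_gap_steps * step))
    for (g in unique(grp)) {
      wg <- w[grp == g, ]
      start <- min(wg$start)
      end <- max(wg$end)
      n_causal <- if (!is.null(records) && "causal_flag" %in% names(records)) {
        sum(records$chrom == ch & records$pos >= start &
              records$pos <= end & records$causal_flag)
      } else NA_integer_
      regions[[length(regions) + 1L]] <-
        candidate_region(ch, start, end, alpha = alpha,
                         n_causal_snps = n_causal, trait = trait)
    }
  }
  regions <- if (length(regions) > 0) {
    do.call(rbind, regions)
  } else {
    candidate_region("x", 1, 2)[0, ]
  }
  if (!is.null(records) && "causal_flag" %in% names(records) &&
      nrow(regions) > 0) {
    regions <- regions[regions$n_causal_snps >= min_causal_snps, ]
    rownames(regions) <- NULL
  }
  list(regions = regions, windows = windows)
}

#' Write candidate regions as BED (0-based half-open) and TSV (1-based)
#'
#' @param regions Region table from [call_regions()].
#' @param bed_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  written <- character(0)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                      end = regions$end,
                      name = ifelse(is.na(regions$trait), ".",
                                    regions$trait))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, bed_path)
  }
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    writeLines("# coordinates: 1-based inclusive; spans in Mb (2 dp)", con)
    utils::write.table(regions, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
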