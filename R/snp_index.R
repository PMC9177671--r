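#' SNP-index: fraction of reads carrying the alternate allele
#'
#' `SNP-index = alt_count / depth` at a site; 0 means every read matches the
#' reference parent, 1 means every read carries the other parent's allele.
#' Zero-depth sites have no defined index and return `NA` (they are removed
#' by the depth filter, which flags them `LOW_DEPTH`).
#'
#' @param alt_count Alternate-allele read count(s).
#' @param depth Total read count(s) at the site.
#' @return Numeric in `[0, 1]`, `NA` where depth is 0.
#' @export
#' @examples
#' snp_index(0, 12)   # 0
#' snp_index(12, 12)  # 1
snp_index <- function(alt_count, depth) {
  stopifnot(all(alt_count >= 0), all(depth >= 0),
            all(alt_count <= depth | depth == 0))
  ifelse(depth > 0, alt_count / depth, NA_real_)
}

#' Delta SNP-index: high-trait bulk minus low-trait bulk
#'
#' A locus where the high bulk matches the reference parent (index 0) and
#' the low bulk is fully alternate (index 1) has delta = -1; unlinked loci
#' have delta near 0.
#'
#' @param index_high,index_low SNP-index of the high- and low-trait bulks.
#' @return delta in `[-1, 1]`.
#' @export
#' @examples
#' delta_snp_index(0, 1)  # -1
delta_snp_index <- function(index_high, index_low) {
  stopifnot(all(index_high >= 0 & index_high <= 1, na.rm = TRUE),
            all(index_low >= 0 & index_low <= 1, na.rm = TRUE))
  as.numeric(index_high) - as.numeric(index_low)
}

#' Compute per-site SNP-index records for two bulks
#'
#' @param sites A `site_counts` table.
#' @return The table with added columns `depth_high`, `depth_low`,
#'   `snp_index_high`, `snp_index_low`, `delta`.
#' @export
compute_snp_indices <- function(sites) {
  sites$depth_high <- sites$high_ref + sites$high_alt
  sites$depth_low <- sites$low_ref + sites$low_alt
  sites$snp_index_high <- snp_index(sites$high_alt, sites$depth_high)
  sites$snp_index_low <- snp_index(sites$low_alt, sites$depth_low)
  sites$delta <- sites$snp_index_high - sites$snp_index_low
  sites
}

classify_zygosity <- function(index, hom_threshold = 0.1) {
  out <- rep(NA_character_, length(index))
  out[!is.na(index) & index <= hom_threshold] <- "hom-ref"
  out[!is.na(index) & index >= 1 - hom_threshold] <- "hom-alt"
  out[!is.na(index) & index > hom_threshold &
        index < 1 - hom_threshold] <- "het"
  out
}

#' Apply the QTL-seq site filters and record removal reasons
#'
#' Three rules, each recorded as a flag; a site passes when no flag is set.
#' Filtering never alters counts and is order-invariant.
#'
#' * `LOW_DEPTH` — read depth below `min_depth`. Default `depth_rule =
#'   "require_both"` demands depth >= `min_depth` in BOTH bulks (the
#'   standard QTL-seq convention); `"require_either"` is the literal
#'   both-bulks-below reading (a site is removed only when thin in both).
#' * `LOW_INDEX` — the spurious-SNP rule. Default `index_rule =
#'   "both_below"` removes sites whose index is below `min_index` in BOTH
#'   bulks (a site with indices 0 and 1 survives); `"either_below"` is the
#'   literal reading that removes a site low in either bulk (note it also
#'   removes every delta = -1 site).
#' * `NOT_HOMOZYGOUS` — a bulk call is homozygous when its index is at most
#'   `hom_threshold` or at least `1 - hom_threshold`; both bulks must be
#'   homozygous.
#'
#' @param records Output of [compute_snp_indices()].
#' @param min_depth Minimum depth (default 7).
#' @param min_index Spurious-index threshold (default 0.3).
#' @param depth_rule,index_rule See above.
#' @param hom_threshold Homozygosity index margin (default 0.1).
#' @return `records` with `zygosity_high`, `zygosity_low`, `filter_flags`
#'   (comma-joined, "" when clean), and logicals `pass` (all rules) and
#'   `pass_window` (depth + index rules only; the set used for sliding
#'   windows, where heterozygous bulk calls are informative).
#' @export
apply_site_filters <- function(records, min_depth = 7L, min_index = 0.3,
                               depth_rule = c("require_both",
                                              "require_either"),
                               index_rule = c("both_below", "either_below"),
                               hom_threshold = 0.1) {
  depth_rule <- match.arg(depth_rule)
  index_rule <- match.arg(index_rule)
  stopifnot(all(c("depth_high", "depth_low", "snp_index_high",
                  "snp_index_low") %in% names(records)))

  low_depth <- if (depth_rule == "require_both") {
    records$depth_high < min_depth | records$depth_low < min_depth
  } else {
    records$depth_high < min_depth & records$depth_low < min_depth
  }
  ih <- records$snp_index_high
  il <- records$snp_index_low
  below_h <- !is.na(ih) & ih < min_index
  below_l <- !is.na(il) & il < min_index
  low_index <- if (index_rule == "both_below") {
    below_h & below_l
  } else {
    below_h | below_l
  }
  records$zygosity_high <- classify_zygosity(ih, hom_threshold)
  records$zygosity_low <- classify_zygosity(il, hom_threshold)
  not_hom <- is.na(ih) | is.na(il) |
    records$zygosity_high == "het" | records$zygosity_low == "het"

  flags <- character(nrow(records))
  add_flag <- function(flags, which, flag) {
    ifelse(which, ifelse(flags == "", flag, paste(flags, flag, sep = ",")),
           flags)
  }
  flags <- add_flag(flags, low_depth, "LOW_DEPTH")
  flags <- add_flag(flags, low_index, "LOW_INDEX")
  flags <- add_flag(flags, not_hom, "NOT_HOMOZYGOUS")
  records$filter_flags <- flags
  records$pass <- flags == ""
  records$pass_window <- !low_depth & !low_index
  records
}

#' Flag candidate causal SNPs
#'
#' A filtered site is flagged causal when its delta SNP-index meets the
#' criterion — by default exactly -1, i.e. the high-trait bulk carries only
#' the reference parent's allele and the low-trait bulk only the other
#' parent's. Sites carrying any filter flag are never flagged.
#'
#' @param records Output of [apply_site_filters()].
#' @param criterion Target delta (default -1).
#' @param mode `"exact"` (delta == criterion), `"abs"` (|delta| ==
#'   |criterion|) or `"threshold"` (|delta| >= |criterion|).
#' @return `records` with a logical `causal_flag` column.
#' @export
flag_causal <- function(records, criterion = -1,
                        mode = c("exact", "abs", "threshold")) {
  mode <- match.arg(mode)
  d <- records$delta
  hit <- switch(mode,
    exact = !is.na(d) & abs(d - criterion) < 1e-12,
    abs = !is.na(d) & abs(abs(d) - abs(criterion)) < 1e-12,
    threshold = !is.na(d) & abs(d) >= abs(criterion) - 1e-12
  )
  records$causal_flag <- hit & records$pass
  records
}

#' Sliding-window means of SNP-index and delta
#'
#' Windows of `window_size` bp advance by `step` bp along each chromosome.
#' Internally a SNP at 1-based position p belongs to the half-open 0-based
#' window `[start0, start0 + window_size)` iff `start0 <= p - 1 <
#' start0 + window_size`; windows are reported 1-based inclusive. Means are
#' arithmetic over member SNPs and absent (`NA`) for empty windows. Median
#' member depths per bulk are attached for confidence-band lookup.
#'
#' @param records Per-site records (typically the `pass_window` subset).
#' @param window_size Window width in bp (default 1 Mb).
#' @param step Step in bp (default 10 kb).
#' @param chrom_lengths Optional named lengths; defaults to the last SNP
#'   position per chromosome.
#' @return data.frame: chrom, start, end (1-based inclusive), n_snps,
#'   mean_index_high, mean_index_low, mean_delta, median_depth_high,
#'   median_depth_low.
#' @export
sliding_window_means <- function(records, window_size = 1e6, step = 1e4,
                                 chrom_lengths = NULL) {
  stopifnot(window_size >= step)
  out <- lapply(unique(records$chrom), function(ch) {
    rec <- records[records$chrom == ch, ]
    rec <- rec[order(rec$pos), ]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(rec$pos)
    }
    starts0 <- seq(0, max(0, len - 1), by = step)
    # member index range per window via binary search on sorted positions
    p0 <- rec$pos - 1
    i1 <- findInterval(starts0 - 0.5, p0) + 1L
    i2 <- findInterval(starts0 + window_size - 0.5, p0)
    n <- pmax(i2 - i1 + 1L, 0L)
    csum <- function(x) cumsum(ifelse(is.na(x), 0, x))
    ch_ <- csum(rec$snp_index_high)
    cl_ <- csum(rec$snp_index_low)
    cd_ <- csum(rec$delta)
    seg <- function(cs, i1, i2, n) {
      ifelse(n > 0, (cs[pmax(i2, 1L)] - c(0, cs)[pmax(i1, 1L)]) / n, NA_real_)
    }
    med <- function(x) {
      vapply(seq_along(starts0), function(j) {
        if (n[j] > 0) stats::median(x[i1[j]:i2[j]]) else NA_real_
      }, numeric(1))
    }
    data.frame(chrom = ch, start = starts0 + 1,
               end = starts0 + window_size, n_snps = n,
               mean_index_high = seg(ch_, i1, i2, n),
               mean_index_low = seg(cl_, i1, i2, n),
               mean_delta = seg(cd_, i1, i2, n),
               median_depth_high = med(rec$depth_high),
               median_depth_low = med(rec$depth_low),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
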