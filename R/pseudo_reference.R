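#' Select confident homozygous parent SNPs for substitution
#'
#' Retains biallelic SNPs with depth at or above `min_depth` and an
#' alternate-allele read fraction at or above `min_alt_fraction`
#' (homozygous-alternate calls). When a `gt` column is present (e.g. "1/1"),
#' the genotype call is used as the homozygosity rule instead of the
#' fraction threshold.
#'
#' @param variants data.frame: chrom, pos, ref, alt, ref_count, alt_count,
#'   optionally gt.
#' @param min_depth Minimum read depth (default 7, mirroring the bulk-side
#'   depth filter).
#' @param min_alt_fraction Minimum alt read fraction for a homozygous-alt
#'   call (default 0.9).
#' @return A `substitution_set` data.frame: chrom, pos, ref, alt, with a
#'   `provenance` attribute.
#' @export
filter_confident_parent_variants <- function(variants, min_depth = 7L,
                                             min_alt_fraction = 0.9) {
  need <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  stopifnot(all(need %in% names(variants)))
  snp <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T")
  depth <- variants$ref_count + variants$alt_count
  deep <- depth >= min_depth
  hom <- if ("gt" %in% names(variants)) {
    variants$gt %in% c("1/1", "1|1")
  } else {
    depth > 0 & variants$alt_count / pmax(depth, 1L) >= min_alt_fraction
  }
  keep <- snp & deep & hom
  out <- variants[keep, c("chrom", "pos", "ref", "alt")]
  rownames(out) <- NULL
  attr(out, "provenance") <- sprintf(
    "homozygous-alt biallelic SNPs, depth>=%d, alt_fraction>=%g",
    min_depth, min_alt_fraction)
  class(out) <- c("substitution_set", "data.frame")
  out
}

#' Substitute parent SNP alleles into a reference sequence
#'
#' Builds the pseudo-reference (reference-guided assembly) of the sequenced
#' parent: every confident homozygous SNP allele replaces the public
#' reference base at its position. Sequence lengths are preserved; a record
#' whose stated reference base does not match the sequence is rejected and
#' reported, never silently applied.
#'
#' @param reference A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param subs A `substitution_set` (chrom, pos 1-based, ref, alt).
#' @return list(sequences = DNAStringSet, report = data.frame(chrom, pos,
#'   ref, alt, status, reason), n_applied, n_rejected).
#' @export
apply_snp_substitutions <- function(reference, subs) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(subs)))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(reference)))
  names(seqs) <- names(reference)

  n <- nrow(subs)
  status <- rep("applied", n)
  reason <- rep("", n)
  if (n > 0) {
    if (anyDuplicated(subs[c("chrom", "pos")])) {
      stop("more than one substitution at a single position")
    }
    bad_chrom <- !(subs$chrom %in% names(seqs))
    if (any(bad_chrom)) {
      stop("unknown chromosome(s): ",
           paste(unique(subs$chrom[bad_chrom]), collapse = ", "))
    }
    lens <- Biostrings::width(seqs)[match(subs$chrom, names(seqs))]
    if (any(subs$pos < 1 | subs$pos > lens)) {
      stop("substitution position outside sequence length")
    }
    indel <- nchar(subs$ref) != 1L | nchar(subs$alt) != 1L
    status[indel] <- "rejected"
    reason[indel] <- "indel"

    for (ch in unique(subs$chrom)) {
      i <- which(subs$chrom == ch & status == "applied")
      if (length(i) == 0L) next
      at_base <- strsplit(as.character(
        Biostrings::extractAt(seqs[[ch]], IRanges::IRanges(
          subs$pos[i], subs$pos[i]))), "")
      at_base <- vapply(at_base, `[`, character(1), 1L)
      mism <- at_base != toupper(subs$ref[i])
      status[i[mism]] <- "rejected"
      reason[i[mism]] <- sprintf("ref mismatch: sequence has %s",
                                 at_base[mism])
      ok <- i[!mism]
      if (length(ok) > 0L) {
        at <- rep(FALSE, length(seqs[[ch]]))
        at[subs$pos[ok]] <- TRUE
        seqs[[ch]] <- Biostrings::replaceLetterAt(
          seqs[[ch]], at, toupper(subs$alt[ok]))
      }
    }
  }
  report <- data.frame(chrom = subs$chrom, pos = subs$pos, ref = subs$ref,
                       alt = subs$alt, status = status, reason = reason,
                       stringsAsFactors = FALSE)
  list(sequences = seqs, report = report,
       n_applied = sum(status == "applied"),
       n_rejected = sum(status == "rejected"))
}

#' Write a pseudo-reference FASTA (uppercase, 60-column lines)
#'
#' @param sequences A DNAStringSet.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_pseudo_reference <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path, width = 60L)
  invisible(path)
}
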