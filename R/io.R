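#' Write two-bulk allele counts as VCF 4.2
#'
#' One sample column per bulk, carrying the AD (ref,alt) FORMAT field the
#' SNP-index statistics consume. Positions are 1-based per the VCF standard.
#'
#' @param sites A `site_counts` table.
#' @param path Output file.
#' @param high_name,low_name Sample names for the high- and low-trait bulks.
#' @param chrom_lengths Optional named vector for `##contig` headers.
#' @return Invisibly, `path`.
#' @export
write_counts_vcf <- function(sites, path, high_name = "HIGH",
                             low_name = "LOW", chrom_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkscan",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">")
  )
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths),
                          as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", high_name, low_name, sep = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "AD",
                paste0(sites$high_ref, ",", sites$high_alt),
                paste0(sites$low_ref, ",", sites$low_alt),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read two-bulk allele counts from a VCF with AD fields
#'
#' Multi-allelic records are dropped (with a message) by default, matching
#' the biallelic-only contract of the SNP-index statistics.
#'
#' @param path VCF file (plain or bgzipped).
#' @param high_name,low_name Sample names of the high- and low-trait bulks.
#' @param drop_multiallelic Drop records whose ALT contains a comma.
#' @return A `site_counts` table.
#' @export
read_counts_vcf <- function(path, high_name, low_name,
                            drop_multiallelic = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in c(high_name, low_name)) {
    if (!s %in% colnames(ad)) stop("sample not in VCF: ", s)
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (!drop_multiallelic) stop("multi-allelic records present")
    message(sum(multi), " multi-allelic record(s) dropped")
  }
  keep <- !multi
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, character(1), 1L)),
         alt = as.integer(vapply(parts, `[`, character(1), 2L)))
  }
  hi <- split_ad(ad[keep, high_name])
  lo <- split_ad(ad[keep, low_name])
  out <- data.frame(chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    high_ref = hi$ref, high_alt = hi$alt,
                    low_ref = lo$ref, low_alt = lo$alt,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

#' @rdname write_counts_vcf
#' @export
write_counts_tsv <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  utils::write.table(sites, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_vcf
#' @export
read_counts_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Read / write the phenotype table
#'
#' Plain TSV with an `id` column plus one column per trait (days to
#' flowering in days; leaf class as `lanceolate`/`obcordate`).
#'
#' @param phenotypes data.frame with an `id` column.
#' @param path File path.
#' @return The table (read) or invisibly the path (write).
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot("id" %in% names(phenotypes))
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
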