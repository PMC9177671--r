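#' Read gene models from GFF3
#'
#' Keeps, per gene, the canonical transcript only (the first mRNA by sorted
#' id), with its exon and CDS intervals; genes without an mRNA feature use
#' their directly attached exons/CDS. Models whose total CDS length is not
#' divisible by 3 are flagged incomplete.
#'
#' @param path GFF3 file.
#' @return list of class `gene_models`: `genes` (data.frame gene_id, chrom,
#'   strand, start, end, incomplete), `exons`, `cds` (data.frames with
#'   gene_id), and prebuilt GRanges for overlap queries.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  get_id <- function(d) as.character(d$ID)
  get_parent <- function(d) {
    vapply(d$Parent, function(p) if (length(p)) as.character(p[1]) else NA,
           character(1))
  }

  genes <- df[df$type == "gene", ]
  mrna <- df[df$type %in% c("mRNA", "transcript"), ]
  exon <- df[df$type == "exon", ]
  cds <- df[df$type == "CDS", ]

  if (nrow(mrna) > 0) {
    mrna$gene_id <- get_parent(mrna)
    mrna <- mrna[order(mrna$gene_id, get_id(mrna)), ]
    canon <- mrna[!duplicated(mrna$gene_id), ]
    tx2gene <- stats::setNames(canon$gene_id, get_id(canon))
    exon$gene_id <- tx2gene[get_parent(exon)]
    cds$gene_id <- tx2gene[get_parent(cds)]
  } else {
    exon$gene_id <- get_parent(exon)
    cds$gene_id <- get_parent(cds)
  }
  exon <- exon[!is.na(exon$gene_id), ]
  cds <- cds[!is.na(cds$gene_id), ]

  gene_tab <- data.frame(gene_id = get_id(genes),
                         chrom = as.character(genes$seqnames),
                         strand = as.character(genes$strand),
                         start = genes$start, end = genes$end,
                         stringsAsFactors = FALSE)
  cds_len <- tapply(cds$end - cds$start + 1, cds$gene_id, sum)
  gene_tab$incomplete <- FALSE
  hit <- match(names(cds_len), gene_tab$gene_id)
  gene_tab$incomplete[hit] <- (cds_len %% 3) != 0

  slim <- function(d) {
    data.frame(gene_id = d$gene_id, chrom = as.character(d$seqnames),
               strand = as.character(d$strand), start = d$start,
               end = d$end,
               phase = if ("phase" %in% names(d)) d$phase else NA,
               stringsAsFactors = FALSE)
  }
  exon_tab <- slim(exon)
  cds_tab <- slim(cds)
  mk_gr <- function(d) {
    GenomicRanges::GRanges(d$chrom,
                           IRanges::IRanges(d$start, d$end),
                           gene_id = d$gene_id)
  }
  structure(
    list(genes = gene_tab, exons = exon_tab, cds = cds_tab,
         gene_gr = mk_gr(gene_tab), exon_gr = mk_gr(exon_tab),
         cds_gr = mk_gr(cds_tab)),
    class = "gene_models")
}

#' Locate variants relative to gene models
#'
#' exon: within any exon of a gene; intron: within a gene span but in no
#' exon; intergenic otherwise. When genes overlap, all hits are found and
#' the first by sorted gene id is reported as primary.
#'
#' @param models A `gene_models` object.
#' @param chrom,pos Vectors of site coordinates (1-based).
#' @return data.frame: chrom, pos, gene_id (NA if intergenic),
#'   region_class in {exon, intron, intergenic}.
#' @export
locate_variant <- function(models, chrom, pos) {
  stopifnot(inherits(models, "gene_models"), length(chrom) == length(pos))
  known <- unique(c(models$genes$chrom, models$exons$chrom))
  bad <- setdiff(unique(chrom), known)
  if (length(bad) > 0) {
    stop("site(s) on chromosome(s) absent from the gene models: ",
         paste(bad, collapse = ", "))
  }
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  gene_id <- rep(NA_character_, length(pos))
  region <- rep("intergenic", length(pos))

  hit_g <- GenomicRanges::findOverlaps(sites, models$gene_gr)
  if (length(hit_g) > 0) {
    qh <- S4Vectors::queryHits(hit_g)
    ids <- models$gene_gr$gene_id[S4Vectors::subjectHits(hit_g)]
    first <- tapply(ids, qh, function(v) sort(v)[1])
    gene_id[as.integer(names(first))] <- unname(first)
    region[as.integer(names(first))] <- "intron"
  }
  hit_e <- GenomicRanges::findOverlaps(sites, models$exon_gr)
  if (length(hit_e) > 0) {
    qh <- S4Vectors::queryHits(hit_e)
    ids <- models$exon_gr$gene_id[S4Vectors::subjectHits(hit_e)]
    first <- tapply(ids, qh, function(v) sort(v)[1])
    i <- as.integer(names(first))
    # an exon hit overrides intron; keep the primary (lowest-id) gene
    region[i] <- "exon"
    gene_id[i] <- ifelse(is.na(gene_id[i]), unname(first),
                         pmin(gene_id[i], unname(first)))
  }
  data.frame(chrom = chrom, pos = pos, gene_id = gene_id,
             region_class = region, stringsAsFactors = FALSE)
}

format_codon <- function(codon, highlight) {
  s <- strsplit(tolower(codon), "")[[1]]
  s[highlight] <- toupper(s[highlight])
  paste(s, collapse = "")
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Codon change induced by a SNP within a CDS
#'
#' Extracts the codon containing the site in transcript orientation (for
#' minus-strand genes the spliced CDS is reverse-complemented and the
#' alternate base complemented before substitution), substitutes the
#' alternate base, and translates both codons with the standard nuclear
#' genetic code. The variant base is upper-cased inside the returned codon
#' strings (e.g. "aCg" -> "aTg").
#'
#' @param sequences Reference DNAStringSet (the pseudo-reference the
#'   variants were called against).
#' @param models A `gene_models` object.
#' @param gene_id Gene containing the site.
#' @param chrom,pos Site coordinate (1-based).
#' @param alt Alternate base on the plus strand.
#' @return list(codon_ref, codon_alt, aa_ref, aa_alt, effect) where effect
#'   is "nsSNP", "sSNP", or "non-coding" (site outside CDS or in an
#'   incomplete terminal codon).
#' @export
codon_change <- function(sequences, models, gene_id, chrom, pos, alt) {
  cds <- models$cds[models$cds$gene_id == gene_id &
                      models$cds$chrom == chrom, ]
  none <- list(codon_ref = NA_character_, codon_alt = NA_character_,
               aa_ref = NA_character_, aa_alt = NA_character_,
               effect = "non-coding")
  if (nrow(cds) == 0L) return(none)
  inside <- pos >= cds$start & pos <= cds$end
  if (!any(inside)) return(none)
  strand <- cds$strand[1]
  cds <- cds[order(cds$start), ]

  seq <- sequences[[chrom]]
  pieces <- Biostrings::extractAt(
    seq, IRanges::IRanges(cds$start, cds$end))
  spliced <- Biostrings::DNAString(
    paste(as.character(pieces), collapse = ""))

  # 0-based offset of the site within the plus-strand spliced CDS
  k <- which(pos >= cds$start & pos <= cds$end)[1]
  before <- if (k > 1) sum(cds$end[1:(k - 1)] - cds$start[1:(k - 1)] + 1) else 0
  off_plus <- before + (pos - cds$start[k])

  if (strand == "-") {
    spliced <- Biostrings::reverseComplement(spliced)
    off <- length(spliced) - 1 - off_plus
    alt_tx <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt)))
  } else {
    off <- off_plus
    alt_tx <- toupper(alt)
  }

  codon_idx <- off %/% 3
  within <- off %% 3 + 1
  c_start <- codon_idx * 3 + 1
  if (c_start + 2 > length(spliced)) {
    warning("site falls in an incomplete terminal codon of ", gene_id)
    return(none)
  }
  codon_ref <- as.character(Biostrings::subseq(spliced, c_start,
                                               c_start + 2))
  codon_alt_vec <- strsplit(codon_ref, "")[[1]]
  codon_alt_vec[within] <- alt_tx
  codon_alt <- paste(codon_alt_vec, collapse = "")
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  list(codon_ref = format_codon(codon_ref, within),
       codon_alt = format_codon(codon_alt, within),
       aa_ref = aa_ref, aa_alt = aa_alt,
       effect = if (identical(aa_ref, aa_alt)) "sSNP" else "nsSNP")
}

#' Annotate the effects of SNPs against gene models
#'
#' Combines [locate_variant()] and [codon_change()]: exonic sites inside a
#' CDS are classified sSNP/nsSNP via their codon pair; exonic sites outside
#' the CDS (UTR) and intronic/intergenic sites are "non-coding".
#'
#' @param sites data.frame with chrom, pos, alt (plus any carried columns,
#'   e.g. indices and delta).
#' @param models A `gene_models` object.
#' @param sequences Reference DNAStringSet.
#' @return `sites` with gene_id, region_class, codon_ref, codon_alt,
#'   aa_ref, aa_alt, effect columns.
#' @export
annotate_effects <- function(sites, models, sequences) {
  loc <- locate_variant(models, sites$chrom, sites$pos)
  sites$gene_id <- loc$gene_id
  sites$region_class <- loc$region_class
  sites$codon_ref <- sites$codon_alt <- NA_character_
  sites$aa_ref <- sites$aa_alt <- NA_character_
  sites$effect <- "non-coding"
  ex <- which(sites$region_class == "exon")
  for (i in ex) {
    cc <- codon_change(sequences, models, sites$gene_id[i],
                       sites$chrom[i], sites$pos[i], sites$alt[i])
    sites$codon_ref[i] <- cc$codon_ref
    sites$codon_alt[i] <- cc$codon_alt
    sites$aa_ref[i] <- cc$aa_ref
    sites$aa_alt[i] <- cc$aa_alt
    sites$effect[i] <- cc$effect
  }
  sites
}

#' Summarize SNP effects in a candidate region
#'
#' @param effects Effects table with gene_id, region_class, effect (either
#'   from [annotate_effects()] or [read_reported_effects()]).
#' @param chrom,start,end Optional region restriction (1-based inclusive).
#' @return One-row data.frame: n_snps, n_genic, n_genes, n_exon, n_intron,
#'   n_intergenic, n_nssnp, n_ssnp.
#' @export
summarize_region_effects <- function(effects, chrom = NULL, start = NULL,
                                     end = NULL) {
  if (!is.null(chrom)) {
    keep <- effects$chrom == chrom
    if (!is.null(start)) keep <- keep & effects$pos >= start
    if (!is.null(end)) keep <- keep & effects$pos <= end
    effects <- effects[keep, ]
  }
  data.frame(
    n_snps = nrow(effects),
    n_genic = sum(effects$region_class %in% c("exon", "intron")),
    n_genes = length(unique(stats::na.omit(effects$gene_id))),
    n_exon = sum(effects$region_class == "exon"),
    n_intron = sum(effects$region_class == "intron"),
    n_intergenic = sum(effects$region_class == "intergenic"),
    n_nssnp = sum(effects$effect == "nsSNP"),
    n_ssnp = sum(effects$effect == "sSNP")
  )
}

#' Read a published genic-SNP table (region, gene, effect per SNP)
#'
#' Parses the tab-separated transcription of a reported candidate-gene SNP
#' table: the `snp_effect` column strings "Intron", "Exon (nsSNP)",
#' "Exon (sSNP)" become `region_class` and `effect` columns, and the bulk
#' SNP-index columns are kept so delta can be recomputed.
#'
#' @param path TSV with columns chrom, gene, pos, ref, high_allele,
#'   snp_index_high, low_allele, snp_index_low, delta, snp_effect,
#'   annotation.
#' @return data.frame usable by [summarize_region_effects()].
#' @export
read_reported_effects <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE)
  tab$gene_id <- tab$gene
  tab$region_class <- ifelse(grepl("^Exon", tab$snp_effect), "exon",
                             ifelse(tab$snp_effect == "Intron", "intron",
                                    "intergenic"))
  tab$effect <- ifelse(grepl("nsSNP", tab$snp_effect), "nsSNP",
                       ifelse(grepl("sSNP", tab$snp_effect), "sSNP",
                              "non-coding"))
  tab
}
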