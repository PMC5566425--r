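## File interchange: VCF genotypes, phenotype tables, annotated VCF copy.
##
## VCFs are read through VariantAnnotation; writing uses a minimal text
## emitter (fixed 9-column + GT layout) whose output round-trips through
## the same reader.

gt_strings <- c("0/0", "0/1", "1/1")

#' Write a genotype matrix as a VCF 4.2 file
#'
#' Biallelic SNVs only, GT field only; missing calls become "./.".
#'
#' @param gm a `genotype_matrix`.
#' @param path output file (plain text, uncompressed).
#' @param contig_length optional contig length for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_length = NULL) {
  v <- gm$variants
  contigs <- unique(v$contig)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ereseq",
    if (!is.null(contig_length))
      sprintf("##contig=<ID=%s,length=%d>", contigs, contig_length)
    else sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$subject_ids), collapse = "\t")), con)
  gt <- matrix(gt_strings[t(gm$calls) + 1L], ncol(gm$calls),
               nrow(gm$calls))
  gt[is.na(gt)] <- "./."
  body <- paste(v$contig, v$pos, v$rsid %||% v$id, v$ref, v$alt, ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read VCF genotypes into a genotype matrix
#'
#' Reads GT calls via [VariantAnnotation::readVcf()], keeping biallelic
#' SNVs; multi-allelic records are expanded upstream by readVcf and
#' non-SNV alleles are skipped with a warning. Unphased or phased diploid
#' GT strings become alt-allele counts; any GT containing "." is missing.
#'
#' @param path VCF file path.
#' @return a `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
  snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% BASES & alt %in% BASES
  if (any(!snv)) {
    warning(sum(!snv), " non-SNV record(s) skipped")
  }
  vcf <- vcf[snv, ]
  rr <- rr[snv, ]
  gt <- VariantAnnotation::geno(vcf)$GT     # variants x subjects
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  rrdf <- as.data.frame(rr)
  variants <- data.frame(
    contig = as.character(rrdf$seqnames),
    pos = as.integer(rrdf$start),
    ref = ref[snv], alt = alt[snv],
    rsid = names(rr), stringsAsFactors = FALSE)
  genotype_matrix(t(dosage), variants, colnames(gt))
}

#' Read a phenotype / design table
#'
#' TSV with columns subject_id, status, g_index1, g_index2 and optionally
#' stratum and weight (as written by [emit_study()]).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write a VCF copy annotated with motif-proximity INFO keys
#'
#' Adds `ERE_DIST` (closest qualifying motif distance), `ERE_REL`
#' (within/near) and `ERE_EFF` (allele effect) to the INFO column of an
#' existing VCF for every variant present in `annotations`; other
#' records pass through unchanged.
#'
#' @param vcf_in input VCF path.
#' @param annotations data.frame from [annotate_proximity()].
#' @param vcf_out output VCF path.
#' @return `vcf_out`, invisibly.
#' @export
annotate_vcf <- function(vcf_in, annotations, vcf_out) {
  lines <- readLines(vcf_in)
  hdr <- grepl("^##", lines)
  chrom_line <- which(grepl("^#CHROM", lines))
  info_hdr <- c(
    '##INFO=<ID=ERE_DIST,Number=1,Type=Integer,Description="Distance to closest qualifying ERE motif (bp)">',
    '##INFO=<ID=ERE_REL,Number=1,Type=String,Description="Relation to closest ERE motif">',
    '##INFO=<ID=ERE_EFF,Number=1,Type=String,Description="Allele-level motif effect">')
  body <- lines[(chrom_line + 1):length(lines)]
  if (nrow(annotations) > 0) {
    best <- do.call(rbind, lapply(split(annotations, annotations$rsid),
                                  function(g) g[which.min(g$distance_bp), ]))
    fields <- strsplit(body, "\t", fixed = TRUE)
    body <- vapply(fields, function(f) {
      hit <- match(f[3], best$rsid)
      if (!is.na(hit)) {
        tag <- sprintf("ERE_DIST=%d;ERE_REL=%s;ERE_EFF=%s",
                       best$distance_bp[hit], best$relation[hit],
                       best$allele_effect[hit])
        f[8] <- if (f[8] %in% c(".", "")) tag else paste0(f[8], ";", tag)
      }
      paste(f, collapse = "\t")
    }, character(1))
  }
  writeLines(c(lines[hdr], info_hdr, lines[chrom_line], body), vcf_out)
  invisible(vcf_out)
}
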