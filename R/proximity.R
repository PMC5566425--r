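## SNP-to-motif proximity and allele-aware motif effect classification.
##
## Coordinate conventions: motif occurrences are 0-based half-open
## [start, end) (BED-like); SNP positions are 1-based (VCF-like). The
## distance between a SNP outside a motif and the motif is the number of
## bases strictly between the SNP base and the nearest motif base.

#' Distance from a SNP to a motif interval
#'
#' Returns 0 when the 1-based SNP position lies inside the motif's 1-based
#' inclusive span `[start + 1, end]`, otherwise the count of bases strictly
#' between the SNP base and the nearest motif base: `start - pos` upstream,
#' `pos - end - 1` downstream.
#'
#' @param pos 1-based SNP position(s).
#' @param motif_start 0-based motif start.
#' @param motif_end exclusive motif end.
#' @return non-negative integer distance(s) in bp, vectorized over `pos`.
#' @export
snp_motif_distance <- function(pos, motif_start, motif_end) {
  if (any(motif_start >= motif_end)) stop("motif_start must be < motif_end")
  if (any(pos < 1)) stop("pos must be >= 1")
  ifelse(pos >= motif_start + 1 & pos <= motif_end, 0L,
         ifelse(pos <= motif_start, motif_start - pos,
                pos - motif_end - 1L))
}

#' Annotate variants with nearby motif occurrences
#'
#' Emits one annotation per (variant, occurrence) pair on the same contig
#' with distance at most `window` (all qualifying motifs per SNP, not only
#' the nearest). Relation is "within" at distance 0 and "near" otherwise.
#' When `sequence` and `model` are supplied, within-motif variants
#' additionally get an allele-level motif effect from
#' [classify_allele_effect()]; variants outside every motif get effect
#' "none" (a SNP outside all scoring windows cannot change a window's
#' score).
#'
#' @param variants data.frame with columns contig, pos (1-based), ref, alt
#'   and optionally rsid.
#' @param occurrences occurrence data.frame from [scan_sequence()] (needs
#'   contig, start, end, strand; matched_seq optional).
#' @param window inclusive proximity window in bp (default 500).
#' @param sequence optional named character vector of contig sequences for
#'   allele-effect calls.
#' @param model optional `motif_model` for allele-effect calls.
#' @param alpha occurrence threshold used for allele-effect calls.
#' @return data.frame: rsid, contig, pos, ref, alt, motif_seq, motif_start,
#'   motif_end, strand, distance_bp, relation, allele_effect.
#' @export
annotate_proximity <- function(variants, occurrences, window = 500,
                               sequence = NULL, model = NULL, alpha = 1e-4) {
  empty <- data.frame(rsid = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      motif_seq = character(), motif_start = integer(),
                      motif_end = integer(), strand = character(),
                      distance_bp = integer(), relation = character(),
                      allele_effect = character(), stringsAsFactors = FALSE)
  if (is.null(variants) || nrow(variants) == 0 ||
      is.null(occurrences) || nrow(occurrences) == 0) return(empty)
  if (is.null(variants$rsid)) variants$rsid <- paste0("var", seq_len(nrow(variants)))

  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    occ <- occurrences[occurrences$contig == v$contig, , drop = FALSE]
    if (nrow(occ) == 0) next
    d <- snp_motif_distance(v$pos, occ$start, occ$end)
    sel <- which(d <= window)
    if (length(sel) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = v$rsid, contig = v$contig, pos = v$pos, ref = v$ref,
      alt = v$alt,
      motif_seq = occ$matched_seq[sel] %||% NA_character_,
      motif_start = occ$start[sel], motif_end = occ$end[sel],
      strand = occ$strand[sel], distance_bp = as.integer(d[sel]),
      relation = ifelse(d[sel] == 0, "within", "near"),
      allele_effect = "none", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||% empty
  if (nrow(out) == 0) return(empty)

  if (!is.null(sequence) && !is.null(model)) {
    within_idx <- which(out$relation == "within")
    for (j in within_idx) {
      seq_j <- if (length(sequence) == 1 && is.null(names(sequence)))
        sequence else sequence[[out$contig[j]]]
      out$allele_effect[j] <- classify_allele_effect(
        seq_j,
        list(pos = out$pos[j], ref = out$ref[j], alt = out$alt[j]),
        model, alpha = alpha)
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify the motif-level effect of a variant's alleles
#'
#' Scores every motif-width window overlapping the variant position, on
#' both strands, once with the reference allele and once with the
#' alternate allele, and compares the best (smallest) occurrence p-values
#' `p_ref` and `p_alt` against `alpha`:
#' \itemize{
#'   \item "creates": `p_alt <= alpha < p_ref` (alt gains an occurrence)
#'   \item "disrupts": `p_ref <= alpha < p_alt` (alt loses an occurrence)
#'   \item "changes": both pass and the best scores differ by more than
#'     `change_tol` bits
#'   \item "none": otherwise
#' }
#'
#' @param sequence reference nucleotide string for the variant's contig.
#' @param variant list/row with `pos` (1-based), `ref`, `alt`.
#' @param model a `motif_model`.
#' @param alpha occurrence p-value threshold (default 1e-4).
#' @param change_tol score difference (bits) needed to call "changes"
#'   (default 0.5).
#' @param dist optional precomputed [score_distribution()].
#' @return one of "creates", "disrupts", "changes", "none".
#' @export
classify_allele_effect <- function(sequence, variant, model, alpha = 1e-4,
                                   change_tol = 0.5, dist = NULL) {
  stopifnot_prob(alpha, "alpha")
  pos <- as.integer(variant$pos)
  w <- model$width
  L <- nchar(sequence)
  if (pos < 1 || pos > L) stop("variant position ", pos, " outside sequence")
  obs <- toupper(substring(sequence, pos, pos))
  if (obs != toupper(variant$ref)) {
    stop("reference mismatch at position ", pos, ": sequence has ", obs,
         ", variant claims ", variant$ref)
  }
  if (is.null(dist)) dist <- score_distribution(model)
  model_rc <- reverse_complement_model(model)
  dist_rc <- score_distribution(model_rc, dist$granularity)

  best <- function(allele) {
    seq_a <- sequence
    substring(seq_a, pos, pos) <- toupper(allele)
    lo <- max(1L, pos - w + 1L)
    hi <- min(L - w + 1L, pos)
    if (hi < lo) return(list(p = 1, score = -Inf))
    codes <- seq_codes(substring(seq_a, lo, hi + w - 1L))
    p <- min(pvalue_of_bin(dist, scan_scores(codes, model,
                                             dist$granularity)),
             pvalue_of_bin(dist_rc, scan_scores(codes, model_rc,
                                                dist_rc$granularity)))
    sc <- c(scan_scores(codes, model), scan_scores(codes, model_rc))
    list(p = p, score = max(sc))
  }
  r <- best(variant$ref)
  a <- best(variant$alt)
  if (a$p <= alpha && r$p > alpha) return("creates")
  if (r$p <= alpha && a$p > alpha) return("disrupts")
  if (r$p <= alpha && a$p <= alpha &&
      abs(a$score - r$score) > change_tol) return("changes")
  "none"
}

#' Write proximity annotations as TSV
#'
#' Column layout mirrors the published candidate tables: rsid, position,
#' motif sequence, motif start/end (0-based half-open), strand, distance,
#' relation, allele effect.
#'
#' @param annotations data.frame from [annotate_proximity()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  data.table::fwrite(data.table::as.data.table(annotations), path, sep = "\t")
  invisible(path)
}
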