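## Position-weight-matrix motif model with exact score p-values.
##
## The model is the standard log-odds PWM: a window of the motif's width
## scores sum_i log2(p_i(base_i) / bg(base_i)) with a pseudocount fold into
## the ratio. Occurrence p-values are exact: a dynamic program over
## positions computes the full null score distribution for a window drawn
## i.i.d. from the background, on a discretized score grid.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Build an ERE-style motif model
#'
#' Constructs a log-odds position weight matrix either from an IUPAC
#' consensus string (each letter expands to a uniform distribution over its
#' IUPAC set) or from a numeric matrix with 4 rows (A, C, G, T) and one
#' column per motif position holding counts or probabilities.
#'
#' The log-odds entry for base \eqn{b} at position \eqn{i} is
#' \deqn{\log_2\frac{p_{ib} + c\,q_b}{(1 + c)\,q_b}}
#' where \eqn{p_{ib}} is the position probability, \eqn{q_b} the background
#' probability and \eqn{c} the pseudocount.
#'
#' @param motif_spec consensus string (IUPAC codes) or a 4 x width numeric
#'   matrix of counts/probabilities with rows in A, C, G, T order.
#' @param pseudocount non-negative smoothing constant (default 0.1). With
#'   pseudocount 0, any structurally-zero position probability would give a
#'   non-finite log-odds entry and the call is rejected.
#' @param background 4 probabilities (A, C, G, T), all > 0, summing to 1.
#'   Default uniform.
#' @param name identifier carried into scan output (default "ERE").
#' @return object of class `motif_model` with elements `width`, `prob`
#'   (width x 4), `log_odds` (width x 4), `background`, `pseudocount`,
#'   `name`, `source`.
#' @export
build_motif_model <- function(motif_spec, pseudocount = 0.1,
                              background = rep(0.25, 4), name = "ERE") {
  if (!is.numeric(background) || length(background) != 4 ||
      any(background <= 0) || abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  background <- stats::setNames(as.numeric(background), BASES)

  if (is.character(motif_spec)) {
    if (length(motif_spec) != 1 || nchar(motif_spec) == 0) {
      stop("consensus must be a single non-empty string")
    }
    chars <- strsplit(toupper(motif_spec), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), names(IUPAC_SETS))
    if (length(bad) > 0) {
      stop("non-IUPAC character(s) in consensus: ", paste(bad, collapse = ", "))
    }
    prob <- t(vapply(chars, function(ch) {
      p <- stats::setNames(numeric(4), BASES)
      p[IUPAC_SETS[[ch]]] <- 1 / length(IUPAC_SETS[[ch]])
      p
    }, numeric(4)))
    src <- paste0("consensus:", motif_spec)
  } else if (is.matrix(motif_spec) && is.numeric(motif_spec)) {
    if (nrow(motif_spec) != 4 || ncol(motif_spec) < 1) {
      stop("matrix spec must have 4 rows (A,C,G,T) and >= 1 column")
    }
    if (any(motif_spec < 0) || any(colSums(motif_spec) <= 0)) {
      stop("matrix spec must be non-negative with positive column sums")
    }
    prob <- t(sweep(motif_spec, 2, colSums(motif_spec), "/"))
    src <- "matrix"
  } else {
    stop("motif_spec must be a consensus string or a 4-row numeric matrix")
  }
  colnames(prob) <- BASES
  rownames(prob) <- NULL

  if (pseudocount == 0 && any(prob == 0)) {
    stop("pseudocount 0 with zero position probabilities would give ",
         "non-finite log-odds; use pseudocount > 0")
  }
  log_odds <- log2(sweep(prob, 2, pseudocount * background, "+")) -
    matrix(log2((1 + pseudocount) * background), nrow(prob), 4, byrow = TRUE)

  structure(
    list(width = nrow(prob), prob = prob, log_odds = log_odds,
         background = background, pseudocount = pseudocount,
         name = name, source = src),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s': width %d, pseudocount %g, source %s\n",
              x$name, x$width, x$pseudocount, x$source))
  invisible(x)
}

#' Default ERE motif model
#'
#' The 13-bp palindromic estrogen response element consensus GGTCAnnnTGACC
#' padded with flanking N columns to 17 bp, the width of the motif
#' instances this package's reference candidate table prints. A stand-in
#' for laboratory-curated ERE matrices; swap in your own with
#' [build_motif_model()].
#'
#' @inheritParams build_motif_model
#' @return a `motif_model` of width 17.
#' @export
default_ere_model <- function(pseudocount = 0.1, background = rep(0.25, 4)) {
  build_motif_model("NNGGTCANNNTGACCNN", pseudocount = pseudocount,
                    background = background, name = "ERE_consensus")
}

## Per-position score lookup including the N column: row i gives
## c(expected score under background, A, C, G, T). Indexed by code + 1.
score_lookup <- function(model) {
  expected <- as.numeric(model$log_odds %*% model$background)
  cbind(N = expected, model$log_odds)
}

#' Score a single window against a motif model
#'
#' Sum of per-position log-odds. N contributes the background-expected
#' score of its column, so masked references remain scannable.
#'
#' @param model a `motif_model`.
#' @param window string of length `model$width` over A/C/G/T/N.
#' @return numeric log-odds score (bits).
#' @export
score_window <- function(model, window) {
  codes <- seq_codes(window)
  if (length(codes) != model$width) {
    stop("window length ", length(codes), " != model width ", model$width)
  }
  lk <- score_lookup(model)
  sum(lk[cbind(seq_len(model$width), codes + 1L)])
}

## Model whose plus-strand scores equal the original model's scores of the
## reverse-complemented window.
reverse_complement_model <- function(model) {
  rc <- model
  flip <- function(m) m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
  rc$prob <- flip(model$prob)
  rc$log_odds <- flip(model$log_odds)
  colnames(rc$prob) <- colnames(rc$log_odds) <- BASES
  rc
}

#' Exact null score distribution of a motif model
#'
#' Dynamic program over motif positions giving the probability mass
#' function of the window score for a random sequence drawn i.i.d. from
#' the model's background, with per-position scores discretized to
#' multiples of `granularity`.
#'
#' @param model a `motif_model`.
#' @param granularity positive score bin size; default spans the score
#'   support in 10,000 bins.
#' @return object of class `score_distribution`: `granularity`, integer
#'   `bins`, numeric `pmf` (sums to 1), `support_min`, `support_max` (on
#'   the discretized scale).
#' @export
score_distribution <- function(model, granularity = NULL) {
  lo <- model$log_odds
  if (is.null(granularity)) {
    rng <- sum(apply(lo, 1, max)) - sum(apply(lo, 1, min))
    granularity <- if (rng > 0) rng / 10000 else 1e-4
  }
  if (!is.numeric(granularity) || length(granularity) != 1 || granularity <= 0) {
    stop("granularity must be a single positive number")
  }
  colbins <- matrix(as.integer(round(lo / granularity)), nrow(lo), 4)
  bg <- model$background

  ## pmf over integer bin values, tracked as a vector with an offset
  pmf <- 1
  lo_bin <- 0L
  for (i in seq_len(model$width)) {
    b <- colbins[i, ]
    new_lo <- lo_bin + min(b)
    new_hi <- lo_bin + length(pmf) - 1L + max(b)
    new <- numeric(new_hi - new_lo + 1L)
    for (k in 1:4) {
      idx <- seq_along(pmf) + (lo_bin + b[k] - new_lo)
      new[idx] <- new[idx] + pmf * bg[k]
    }
    pmf <- new
    lo_bin <- new_lo
  }
  keep <- pmf > 0
  bins <- (lo_bin + seq_along(pmf) - 1L)[keep]
  pmf <- pmf[keep]
  structure(
    list(granularity = granularity, bins = bins, pmf = pmf,
         support_min = min(bins) * granularity,
         support_max = max(bins) * granularity),
    class = "score_distribution"
  )
}

#' Exact p-value of a motif score
#'
#' Tail probability P(null score >= score) under the discretized null
#' distribution; monotone non-increasing in `score`.
#'
#' @param dist a `score_distribution`.
#' @param score numeric score(s).
#' @return probabilities in `[0, 1]`, vectorized over `score`.
#' @export
pvalue_of_score <- function(dist, score) {
  ## reverse cumulative mass indexed by bin
  ord <- order(dist$bins)
  bins <- dist$bins[ord]
  tail_mass <- rev(cumsum(rev(dist$pmf[ord])))
  ## comparisons happen on the rounded bin scale, so a score equal to the
  ## attained maximum (up to discretization error) gets the top bin's
  ## mass, never a spurious zero
  k <- as.integer(round(score / dist$granularity))
  out <- numeric(length(score))
  for (j in seq_along(score)) {
    if (k[j] > bins[length(bins)]) {
      out[j] <- 0
    } else if (k[j] <= bins[1]) {
      out[j] <- 1
    } else {
      i <- findInterval(k[j], bins)
      ## k falls between bins[i] and bins[i+1]; tail starts at the first
      ## bin >= k
      out[j] <- if (bins[i] == k[j]) tail_mass[i] else tail_mass[i + 1]
    }
  }
  out
}

## Vectorized window scores at every start of `codes` (0-based starts
## 0..L-w), for a given model, using the N-aware lookup. With a
## granularity, per-column scores are rounded to integer bins first so
## window scores live on the same grid as the null DP (FIMO-style);
## otherwise raw bit scores are returned.
scan_scores <- function(codes, model, granularity = NULL) {
  w <- model$width
  L <- length(codes)
  n_win <- L - w + 1L
  if (n_win <= 0) return(numeric(0))
  lk <- score_lookup(model)
  if (!is.null(granularity)) lk <- round(lk / granularity)
  scores <- numeric(n_win)
  for (i in seq_len(w)) {
    scores <- scores + lk[i, codes[i:(i + n_win - 1L)] + 1L]
  }
  scores
}

## Tail mass of integer bin sums under a score_distribution.
pvalue_of_bin <- function(dist, k) {
  ord <- order(dist$bins)
  bins <- dist$bins[ord]
  tail_mass <- rev(cumsum(rev(dist$pmf[ord])))
  vapply(k, function(kj) {
    if (kj > bins[length(bins)]) return(0)
    if (kj <= bins[1]) return(1)
    i <- findInterval(kj, bins)
    if (bins[i] == kj) tail_mass[i] else tail_mass[i + 1]
  }, numeric(1))
}

#' Scan a sequence for motif occurrences
#'
#' FIMO-style scan: every window of the model's width on both strands
#' whose exact p-value is at most `alpha` is reported. Coordinates are
#' 0-based half-open; the matched sequence of a '-' occurrence is the
#' reverse complement of the reference slice.
#'
#' @param contig_id contig name carried into the output.
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param model a `motif_model`.
#' @param alpha per-window p-value threshold in (0, 1]; default 1e-4.
#' @param dist optional precomputed [score_distribution()] for `model`.
#' @param dedupe if TRUE, keep only the best-p occurrence per
#'   `[start, end)` interval (palindromic double hits collapse).
#' @return data.frame of occurrences: contig, start, end, strand, score,
#'   pvalue, matched_seq, motif_id; sorted by (start, strand).
#' @export
scan_sequence <- function(contig_id, sequence, model, alpha = 1e-4,
                          dist = NULL, dedupe = FALSE) {
  stopifnot_prob(alpha, "alpha")
  codes <- seq_codes(sequence)
  w <- model$width
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), pvalue = numeric(),
                      matched_seq = character(), motif_id = character(),
                      stringsAsFactors = FALSE)
  if (length(codes) < w) return(empty)
  if (is.null(dist)) dist <- score_distribution(model)

  ## an asymmetric background gives the '-' strand its own null
  dist_rc <- score_distribution(reverse_complement_model(model),
                                dist$granularity)
  hits <- list()
  for (strand in c("+", "-")) {
    m <- if (strand == "+") model else reverse_complement_model(model)
    d <- if (strand == "+") dist else dist_rc
    scores <- scan_scores(codes, m)
    pvals <- pvalue_of_bin(d, scan_scores(codes, m, d$granularity))
    keep <- which(pvals <= alpha)
    if (length(keep) == 0) next
    starts <- keep - 1L
    slices <- substring(sequence, keep, keep + w - 1L)
    hits[[strand]] <- data.frame(
      contig = contig_id, start = starts, end = starts + w,
      strand = strand, score = scores[keep], pvalue = pvals[keep],
      matched_seq = if (strand == "+") toupper(slices) else revcomp(toupper(slices)),
      motif_id = model$name, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(hits)) %||% empty
  if (nrow(out) == 0) return(empty)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  if (dedupe && nrow(out) > 1) {
    key <- paste(out$start, out$end)
    out <- do.call(rbind, lapply(split(out, key), function(g) {
      g[which.min(g$pvalue), , drop = FALSE]
    }))
    out <- out[order(out$start, out$strand), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Scan every record of a FASTA file
#'
#' @param fasta_path path to a (multi-record) FASTA file.
#' @inheritParams scan_sequence
#' @return row-bound occurrence data.frame across records.
#' @export
scan_fasta <- function(fasta_path, model, alpha = 1e-4, dedupe = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  dist <- score_distribution(model)
  out <- lapply(seq_along(seqs), function(i) {
    scan_sequence(sub("\\s.*$", "", names(seqs)[i]), as.character(seqs[[i]]),
                  model, alpha = alpha, dist = dist, dedupe = dedupe)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write motif occurrences as BED6+2
#'
#' Columns: contig, start, end, name, score, strand, p-value, matched
#' sequence. Coordinates 0-based half-open per BED.
#'
#' @param occurrences occurrence data.frame from [scan_sequence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(occurrences, path) {
  bed <- data.table::data.table(
    chrom = occurrences$contig, start = occurrences$start,
    end = occurrences$end, name = occurrences$motif_id,
    score = sprintf("%.4f", occurrences$score), strand = occurrences$strand,
    pvalue = sprintf("%.3e", occurrences$pvalue),
    matched_seq = occurrences$matched_seq)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED6+2 occurrence file written by [write_occurrences_bed()]
#'
#' @param path BED file path.
#' @return occurrence data.frame as produced by [scan_sequence()].
#' @export
read_occurrences_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "pvalue",
                                         "matched_seq"))
  data.frame(contig = bed$chrom, start = as.integer(bed$start),
             end = as.integer(bed$end), strand = bed$strand,
             score = as.numeric(bed$score), pvalue = as.numeric(bed$pvalue),
             matched_seq = bed$matched_seq, motif_id = bed$name,
             stringsAsFactors = FALSE)
}

#' Read a 4-row count matrix motif definition
#'
#' Minimal MEME-like dialect: a tab-separated file with 4 rows (A, C, G, T)
#' and one column per motif position; an optional leading column of row
#' labels is detected and dropped. Lines starting with '#' are ignored.
#'
#' @param path file path.
#' @return 4 x width numeric matrix suitable for [build_motif_model()].
#' @export
read_motif_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) != 4) stop("motif matrix file must have 4 data rows")
  fields <- strsplit(lines, "\\s+")
  if (all(vapply(fields, function(f) f[1] %in% c(BASES, paste0(BASES, ":")),
                 logical(1)))) {
    fields <- lapply(fields, function(f) f[-1])
  }
  n <- unique(lengths(fields))
  if (length(n) != 1) stop("ragged motif matrix rows")
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(m)) stop("non-numeric entries in motif matrix")
  rownames(m) <- BASES
  m
}
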