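## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors (IUPAC codes allowed).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Map a sequence string to integer codes: A=1 C=2 G=3 T=4, N=0.
## Any other character is an error (callers validate IUPAC separately).
seq_codes <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(chars, BASES)
  codes[chars == "N"] <- 0L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes) & chars != "N"])
    stop("sequence contains non-ACGTN characters: ", paste(bad, collapse = ", "))
  }
  codes
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## state. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## 0-order base composition of a sequence, pseudo-counted so no entry is 0.
#' Estimate a 0-order background model from a sequence
#'
#' Returns the base composition (A, C, G, T) of `sequence`, with one
#' pseudo-observation per base so that no probability is exactly zero.
#' N characters are ignored.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @return named numeric vector of 4 probabilities summing to 1.
#' @export
estimate_background <- function(sequence) {
  codes <- seq_codes(sequence)
  counts <- tabulate(codes, nbins = 4L) + 1
  stats::setNames(counts / sum(counts), BASES)
}

## Stable hash of an arbitrary config-like object (canonical JSON -> md5).
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x > 1) {
    stop(name, " must be a probability in (0, 1]")
  }
}
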