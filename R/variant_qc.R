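## Variant QC cascade for dual-caller targeted resequencing data:
## drop variants discordant between two calling workflows, then variants
## missing in more than a threshold fraction of subjects, then
## monomorphic variants; summarize the site-frequency spectrum of what
## survives.

#' Construct a genotype matrix container
#'
#' @param calls subjects x variants integer matrix of alt-allele counts
#'   (0/1/2), NA for missing.
#' @param variants data.frame describing columns of `calls`: contig, pos,
#'   ref, alt, and optionally rsid / id.
#' @param subject_ids character vector naming the rows of `calls`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, subject_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(variants) != ncol(calls)) {
    stop("variants rows (", nrow(variants), ") != calls columns (",
         ncol(calls), ")")
  }
  vals <- calls[!is.na(calls)]
  if (length(vals) > 0 && !all(vals %in% 0:2)) {
    stop("non-missing calls must be in {0, 1, 2}")
  }
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(calls)))
  if (is.null(variants$id)) {
    variants$id <- if (!is.null(variants$rsid)) variants$rsid else
      paste0(variants$contig, ":", variants$pos)
  }
  rownames(calls) <- subject_ids
  colnames(calls) <- variants$id
  structure(list(subject_ids = subject_ids, variants = variants,
                 calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a$calls), dim(b$calls)) ||
      !identical(a$subject_ids, b$subject_ids) ||
      !identical(a$variants$id, b$variants$id)) {
    stop("genotype matrices must share subjects and variants")
  }
}

#' Variants discordant between two calling workflows
#'
#' A variant is discordant iff any subject has non-missing calls in both
#' matrices that differ. A call missing in exactly one workflow is not
#' discordance (it contributes to missingness downstream).
#'
#' @param calls_a,calls_b `genotype_matrix` objects over the same
#'   subjects and variants.
#' @return character vector of discordant variant ids.
#' @export
concordance_filter <- function(calls_a, calls_b) {
  check_same_shape(calls_a, calls_b)
  both <- !is.na(calls_a$calls) & !is.na(calls_b$calls)
  disagree <- both & (calls_a$calls != calls_b$calls)
  calls_a$variants$id[colSums(disagree, na.rm = TRUE) > 0]
}

#' Per-variant concordance rates between two workflows
#'
#' Agreement fraction among jointly non-missing calls (NA when a variant
#' has no jointly-called genotypes).
#'
#' @inheritParams concordance_filter
#' @return named numeric vector of rates in `[0, 1]`.
#' @export
concordance_rates <- function(calls_a, calls_b) {
  check_same_shape(calls_a, calls_b)
  both <- !is.na(calls_a$calls) & !is.na(calls_b$calls)
  agree <- both & (calls_a$calls == calls_b$calls)
  n <- colSums(both)
  stats::setNames(ifelse(n > 0, colSums(agree) / n, NA_real_),
                  calls_a$variants$id)
}

#' Variants exceeding a missingness threshold
#'
#' Strictly-greater-than comparison: a variant is flagged when its
#' missing fraction exceeds `threshold` ("missing in more than 10% of
#' participants" at the default).
#'
#' @param calls a `genotype_matrix`.
#' @param threshold missing-fraction threshold in `[0, 1]` (default 0.10).
#' @return character vector of flagged variant ids.
#' @export
missingness_filter <- function(calls, threshold = 0.10) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  frac <- colMeans(is.na(calls$calls))
  calls$variants$id[frac > threshold]
}

#' Monomorphic variants
#'
#' Variants whose non-missing calls take zero or one distinct value
#' (all-missing columns are vacuously monomorphic and flagged with a
#' message).
#'
#' @param calls a `genotype_matrix`.
#' @return character vector of flagged variant ids.
#' @export
monomorphic_filter <- function(calls) {
  n_distinct <- apply(calls$calls, 2, function(g) length(unique(g[!is.na(g)])))
  if (any(n_distinct == 0)) {
    message(sum(n_distinct == 0),
            " variant(s) with all calls missing flagged as monomorphic")
  }
  calls$variants$id[n_distinct <= 1]
}

#' Minor allele frequency of one variant
#'
#' Unweighted: `min(f, 1 - f)` with `f` = alt-allele count over twice the
#' non-missing subject count. With `weights` (positive reals, e.g.
#' inverse-probability sampling weights), allele counts are weighted, the
#' estimator for the frequency in the cohort the subsample was drawn from.
#'
#' @param g vector of 0/1/2 calls, NA missing.
#' @param weights optional positive per-subject weights.
#' @return minor allele frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(g, weights = NULL) {
  ok <- !is.na(g)
  if (!any(ok)) stop("all calls missing; MAF undefined")
  if (is.null(weights)) weights <- rep(1, length(g))
  if (length(weights) != length(g) || any(weights[ok] <= 0)) {
    stop("weights must be positive and match the call vector")
  }
  f <- sum(weights[ok] * g[ok]) / (2 * sum(weights[ok]))
  min(f, 1 - f)
}

maf_spectrum <- function(mafs, breaks = c(0.005, 0.01)) {
  n <- length(mafs)
  s <- c(rare = NA_real_, low = NA_real_, common = NA_real_)
  if (n > 0) {
    s["rare"] <- mean(mafs <= breaks[1])
    s["low"] <- mean(mafs > breaks[1] & mafs <= breaks[2])
    s["common"] <- mean(mafs > breaks[2])
  }
  s
}

#' Run the variant QC cascade
#'
#' With two callers: flag discordant variants (100%-agreement rule), merge
#' calls (the concordant value, else the single non-missing value, else
#' missing), then flag high-missingness and monomorphic variants on the
#' merged matrix. Each removed variant gets one primary reason with
#' precedence discordant > high-missing > monomorphic. The retained
#' matrix's MAF spectrum is summarized in bins MAF <= 0.005,
#' (0.005, 0.01], > 0.01.
#'
#' @param calls_a a `genotype_matrix` (primary caller).
#' @param calls_b optional second caller's `genotype_matrix`.
#' @param miss_threshold missingness threshold (default 0.10, strict >).
#' @return list with `genotypes` (filtered merged `genotype_matrix`) and
#'   `report` (class `qc_report`): n_input, n_discordant, n_high_missing,
#'   n_monomorphic, n_retained, spectrum, removal reason per variant, and
#'   per-variant concordance rates when two callers were given.
#' @export
qc_pipeline <- function(calls_a, calls_b = NULL, miss_threshold = 0.10) {
  ids <- calls_a$variants$id
  if (!is.null(calls_b)) {
    discordant <- concordance_filter(calls_a, calls_b)
    rates <- concordance_rates(calls_a, calls_b)
    merged_calls <- ifelse(!is.na(calls_a$calls), calls_a$calls, calls_b$calls)
    rownames(merged_calls) <- calls_a$subject_ids
    merged <- genotype_matrix(merged_calls, calls_a$variants,
                              calls_a$subject_ids)
  } else {
    discordant <- character(0)
    rates <- NULL
    merged <- calls_a
  }
  high_missing <- missingness_filter(merged, miss_threshold)
  mono <- suppressMessages(monomorphic_filter(merged))

  reason <- stats::setNames(rep(NA_character_, length(ids)), ids)
  reason[mono] <- "monomorphic"
  reason[high_missing] <- "high_missing"
  reason[discordant] <- "discordant"

  keep <- ids[is.na(reason)]
  kept_idx <- match(keep, merged$variants$id)
  filtered <- genotype_matrix(merged$calls[, kept_idx, drop = FALSE],
                              merged$variants[kept_idx, , drop = FALSE],
                              merged$subject_ids)
  mafs <- if (length(kept_idx) > 0)
    apply(filtered$calls, 2, compute_maf) else numeric(0)

  report <- structure(list(
    n_input = length(ids),
    n_discordant = sum(reason == "discordant", na.rm = TRUE),
    n_high_missing = sum(reason == "high_missing", na.rm = TRUE),
    n_monomorphic = sum(reason == "monomorphic", na.rm = TRUE),
    n_retained = length(keep),
    spectrum = maf_spectrum(mafs),
    maf = mafs,
    removal_reason = reason[!is.na(reason)],
    concordance_rates = rates
  ), class = "qc_report")

  list(genotypes = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d variants in; removed %d discordant, ",
                     "%d high-missing, %d monomorphic; %d retained\n"),
              x$n_input, x$n_discordant, x$n_high_missing, x$n_monomorphic,
              x$n_retained))
  if (x$n_retained > 0) {
    cat(sprintf("  MAF spectrum: %.3f <=0.005 | %.3f (0.005,0.01] | %.3f >0.01\n",
                x$spectrum["rare"], x$spectrum["low"], x$spectrum["common"]))
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a `qc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  out <- list(
    n_input = report$n_input, n_discordant = report$n_discordant,
    n_high_missing = report$n_high_missing,
    n_monomorphic = report$n_monomorphic, n_retained = report$n_retained,
    spectrum = as.list(report$spectrum),
    removal_reason = as.list(report$removal_reason))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
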