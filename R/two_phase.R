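## Outcome-dependent two-phase stratified sampling and association.
##
## Phase 1 is a case-control cohort with two genotyped index SNPs; phase 2
## draws a subsample for resequencing by simple random sampling within the
## 18 strata defined by case status x joint index-SNP genotypes. Sampling
## weights N/n per stratum correct the outcome- and genotype-dependent
## selection; association uses either an inverse-probability-weighted
## marginal logistic model with a sandwich variance, or an unweighted
## logistic model adjusted for the index-SNP genotype.

#' Enumerate two-phase sampling strata
#'
#' Cross-tabulates case status with the joint genotypes of two index SNPs
#' into the full 2 x 3 x 3 = 18 stratum grid (empty strata retained with
#' `N_cohort` 0). Subjects with missing index genotypes are excluded from
#' the sampling frame with a message.
#'
#' @param status per-subject case status: "case"/"control" (or a logical /
#'   0-1 vector, TRUE or 1 = case).
#' @param g1,g2 per-subject genotypes (0/1/2) at the two index SNPs.
#' @param subject_ids optional subject identifiers.
#' @param index_snp_ids length-2 names of the index SNPs.
#' @return object of class `cohort_design`: `strata` (data.frame
#'   stratum, case_status, g1, g2, N_cohort), `assignment` (data.frame
#'   subject_id, status, g1, g2, stratum), `index_snp_ids`.
#' @export
assign_strata <- function(status, g1, g2, subject_ids = NULL,
                          index_snp_ids = c("index1", "index2")) {
  if (is.logical(status)) status <- ifelse(status, "case", "control")
  if (is.numeric(status)) status <- ifelse(status == 1, "case", "control")
  if (!all(status %in% c("case", "control"))) {
    stop("status must code case/control")
  }
  n <- length(status)
  if (length(g1) != n || length(g2) != n) stop("status/g1/g2 length mismatch")
  ok <- !is.na(g1) & !is.na(g2)
  if (any(!ok)) {
    message(sum(!ok), " subject(s) with missing index genotypes excluded ",
            "from the sampling frame")
  }
  gv <- c(g1[ok], g2[ok])
  if (!all(gv %in% 0:2)) stop("index genotypes must be biallelic 0/1/2 codes")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))

  grid <- expand.grid(g2 = 0:2, g1 = 0:2,
                      case_status = c("case", "control"),
                      stringsAsFactors = FALSE)[, c("case_status", "g1", "g2")]
  grid$stratum <- paste0(grid$case_status, "_g1.", grid$g1, "_g2.", grid$g2)
  assignment <- data.frame(
    subject_id = subject_ids[ok], status = status[ok],
    g1 = g1[ok], g2 = g2[ok],
    stratum = paste0(status[ok], "_g1.", g1[ok], "_g2.", g2[ok]),
    stringsAsFactors = FALSE)
  counts <- table(factor(assignment$stratum, levels = grid$stratum))
  grid$N_cohort <- as.integer(counts[grid$stratum])

  structure(list(strata = grid[, c("stratum", "case_status", "g1", "g2",
                                   "N_cohort")],
                 assignment = assignment,
                 index_snp_ids = index_snp_ids),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("cohort_design: %d subjects in %d/%d occupied strata (index SNPs %s, %s)\n",
              nrow(x$assignment), sum(x$strata$N_cohort > 0),
              nrow(x$strata), x$index_snp_ids[1], x$index_snp_ids[2]))
  invisible(x)
}

## Proportional-to-N allocation with largest remainders, within one
## case-status margin; respects per-stratum capacity N.
proportional_allocation <- function(N, target) {
  if (sum(N) < target) stop("margin total ", sum(N), " < target ", target)
  quota <- target * N / sum(N)
  n <- pmin(floor(quota), N)
  left <- target - sum(n)
  while (left > 0) {
    room <- which(n < N)
    pick <- room[order(-(quota[room] - n[room]))][seq_len(min(left, length(room)))]
    n[pick] <- n[pick] + 1L
    left <- target - sum(n)
  }
  as.integer(n)
}

#' Balanced per-stratum allocation
#'
#' Targets an equal number of subjects per stratum within each case-status
#' margin, capped at the stratum's cohort count, redistributing any excess
#' to strata with room (smallest current allocation first). This is the
#' classic efficient two-phase choice: it deliberately oversamples rare
#' index-genotype strata, which is exactly the selection the
#' inverse-probability weights must undo.
#'
#' @param design a `cohort_design`.
#' @param n_cases,n_controls margin totals.
#' @return named integer vector usable as `allocation` in
#'   [sample_subphase()].
#' @export
balanced_allocation <- function(design, n_cases = 199, n_controls = 201) {
  st <- design$strata
  alloc <- integer(nrow(st))
  for (cs in c("case", "control")) {
    m <- which(st$case_status == cs)
    target <- if (cs == "case") n_cases else n_controls
    N <- st$N_cohort[m]
    if (sum(N) < target) stop(cs, " margin smaller than target")
    a <- pmin(N, rep(floor(target / length(m)), length(m)))
    while (sum(a) < target) {
      room <- which(a < N)
      pick <- room[order(a[room])[1]]
      a[pick] <- a[pick] + 1L
    }
    alloc[m] <- a
  }
  stats::setNames(alloc, st$stratum)
}

#' Draw the phase-2 subsample
#'
#' Simple random sampling without replacement within each stratum.
#' Per-subject sampling weight is the stratum's `N_cohort / n_sampled`.
#'
#' @param design a `cohort_design` from [assign_strata()].
#' @param n_cases,n_controls subsample sizes (defaults 199 and 201).
#' @param allocation optional named integer vector of per-stratum targets
#'   (names matching `design$strata$stratum`); default allocates
#'   proportional-to-N within the case and control margins.
#' @param seed RNG seed for reproducible draws.
#' @return list: `subjects` (data.frame subject_id, status, g1, g2,
#'   stratum, weight), `strata` (design strata with n_sampled and weight
#'   columns).
#' @export
sample_subphase <- function(design, n_cases = 199, n_controls = 201,
                            allocation = NULL, seed = NULL) {
  st <- design$strata
  if (is.null(allocation)) {
    alloc <- integer(nrow(st))
    for (cs in c("case", "control")) {
      m <- st$case_status == cs
      alloc[m] <- proportional_allocation(
        st$N_cohort[m], if (cs == "case") n_cases else n_controls)
    }
  } else {
    if (is.null(names(allocation)) || !all(st$stratum %in% names(allocation))) {
      stop("allocation must be named by stratum")
    }
    alloc <- as.integer(allocation[st$stratum])
    bad <- which(alloc > st$N_cohort)
    if (length(bad) > 0) {
      stop("allocation exceeds cohort count in stratum ",
           st$stratum[bad[1]], " (", alloc[bad[1]], " > ",
           st$N_cohort[bad[1]], ")")
    }
    for (cs in c("case", "control")) {
      m <- st$case_status == cs
      target <- if (cs == "case") n_cases else n_controls
      if (sum(alloc[m]) != target) {
        stop(cs, " allocation sums to ", sum(alloc[m]), ", expected ", target)
      }
    }
  }
  st$n_sampled <- alloc
  st$weight <- ifelse(alloc > 0, st$N_cohort / alloc, NA_real_)

  asg <- design$assignment
  picked <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(st)), function(i) {
      if (st$n_sampled[i] == 0) return(character(0))
      pool <- asg$subject_id[asg$stratum == st$stratum[i]]
      if (length(pool) == 1 && st$n_sampled[i] == 1) pool else
        sample(pool, st$n_sampled[i])
    }), use.names = FALSE)
  })
  subjects <- asg[match(picked, asg$subject_id), , drop = FALSE]
  subjects$weight <- st$weight[match(subjects$stratum, st$stratum)]
  rownames(subjects) <- NULL
  list(subjects = subjects, strata = st)
}

## Shared result assembler.
association_result <- function(variant, model, beta, se, p, maf_s, maf_w,
                               estimable = TRUE, note = NA_character_) {
  data.frame(variant = variant, model = model, beta = beta, se = se,
             p_value = p, maf_sampled = maf_s, maf_weighted = maf_w,
             estimable = estimable, note = note, stringsAsFactors = FALSE)
}

fit_logistic_wald <- function(y, X, w = NULL, robust = FALSE) {
  if (is.null(w)) w <- rep(1, length(y))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = w,
                   family = stats::quasibinomial("logit")))
  if (!fit$converged) return(NULL)
  p_hat <- fit$fitted.values
  ## (quasi-)separation: fitted probabilities at the boundary or a
  ## diverging coefficient; Wald machinery is meaningless there
  if (any(p_hat < 1e-6) || any(p_hat > 1 - 1e-6) ||
      max(abs(fit$coefficients), na.rm = TRUE) > 15) return(NULL)
  keep <- !is.na(fit$coefficients)
  Xk <- X[, keep, drop = FALSE]
  beta <- fit$coefficients[keep]
  info <- crossprod(Xk, Xk * (w * p_hat * (1 - p_hat)))
  Ainv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(Ainv)) return(NULL)
  V <- if (robust) {
    B <- crossprod(Xk, Xk * (w^2 * (y - p_hat)^2))
    Ainv %*% B %*% Ainv
  } else Ainv
  list(beta = beta, vcov = V, vcov_model = Ainv, names = colnames(Xk))
}

#' Weighted marginal association of one variant
#'
#' Inverse-probability-weighted logistic regression of case status on the
#' additive genotype, with a robust (sandwich) variance accounting for the
#' weighting; two-sided Wald p. This is the marginal (cohort-level)
#' estimator for an outcome-dependent two-phase sample.
#'
#' @param g 0/1/2 genotype vector (NA missing) for the sampled subjects.
#' @param status case status vector (as in [assign_strata()]).
#' @param weights positive per-subject sampling weights (stratum N/n).
#' @param variant variant identifier carried into the result.
#' @return one-row data.frame (an `AssociationResult`): variant, model,
#'   beta, se, p_value, maf_sampled, maf_weighted, estimable, note.
#' @export
weighted_association <- function(g, status, weights, variant = "variant") {
  y <- if (is.numeric(status)) status else as.integer(status == "case")
  ok <- !is.na(g) & !is.na(y) & !is.na(weights)
  g2 <- g[ok]; y2 <- y[ok]; w2 <- weights[ok]
  maf_s <- compute_maf(g[ok])
  maf_w <- compute_maf(g[ok], weights[ok])
  if (stats::var(g2) == 0 || stats::var(y2) == 0) {
    return(association_result(variant, "weighted_marginal", NA_real_,
                              NA_real_, NA_real_, maf_s, maf_w,
                              estimable = FALSE, note = "zero variance"))
  }
  fit <- fit_logistic_wald(y2, cbind(`(Intercept)` = 1, g = g2), w2,
                           robust = TRUE)
  if (is.null(fit) || !"g" %in% fit$names) {
    return(association_result(variant, "weighted_marginal", NA_real_,
                              NA_real_, NA_real_, maf_s, maf_w,
                              estimable = FALSE,
                              note = "separation or singular fit"))
  }
  i <- match("g", fit$names)
  beta <- fit$beta[i]; se <- sqrt(fit$vcov[i, i])
  ## near-separation leaves a huge model SE with a collapsed sandwich SE;
  ## the Wald statistic is meaningless there
  if (se < 0.1 * sqrt(fit$vcov_model[i, i])) {
    return(association_result(variant, "weighted_marginal", NA_real_,
                              NA_real_, NA_real_, maf_s, maf_w,
                              estimable = FALSE,
                              note = "unstable robust variance"))
  }
  association_result(variant, "weighted_marginal", unname(beta), se,
                     2 * stats::pnorm(-abs(beta / se)), maf_s, maf_w)
}

#' Index-SNP-adjusted association of one variant
#'
#' Unweighted logistic regression of case status on the additive genotype
#' plus the additive index-SNP genotype covariate; two-sided Wald p. A
#' constant covariate is dropped (the fit reduces to the unadjusted
#' model).
#'
#' @param g 0/1/2 genotype vector for the sampled subjects.
#' @param status case status vector.
#' @param index_g 0/1/2 genotype at the index SNP (adjustment covariate).
#' @param variant variant identifier carried into the result.
#' @return one-row `AssociationResult` data.frame (model
#'   "adjusted_conditional").
#' @export
adjusted_association <- function(g, status, index_g, variant = "variant") {
  y <- if (is.numeric(status)) status else as.integer(status == "case")
  ok <- !is.na(g) & !is.na(y) & !is.na(index_g)
  g2 <- g[ok]; y2 <- y[ok]; x2 <- index_g[ok]
  maf_s <- compute_maf(g2)
  if (stats::var(g2) == 0 || stats::var(y2) == 0) {
    return(association_result(variant, "adjusted_conditional", NA_real_,
                              NA_real_, NA_real_, maf_s, NA_real_,
                              estimable = FALSE, note = "zero variance"))
  }
  X <- cbind(`(Intercept)` = 1, g = g2, index = x2)
  if (stats::var(x2) == 0) X <- X[, c("(Intercept)", "g"), drop = FALSE]
  fit <- fit_logistic_wald(y2, X)
  if (is.null(fit) || !"g" %in% fit$names) {
    return(association_result(variant, "adjusted_conditional", NA_real_,
                              NA_real_, NA_real_, maf_s, NA_real_,
                              estimable = FALSE,
                              note = "separation or singular fit"))
  }
  i <- match("g", fit$names)
  beta <- fit$beta[i]; se <- sqrt(fit$vcov[i, i])
  association_result(variant, "adjusted_conditional", unname(beta), se,
                     2 * stats::pnorm(-abs(beta / se)), maf_s, NA_real_)
}

#' Genotype correlation (composite LD r)
#'
#' Pearson correlation of additive genotype codes over pairwise-complete
#' subjects; usable without phase information.
#'
#' @param gx,gy 0/1/2 genotype vectors.
#' @return correlation in `[-1, 1]`.
#' @export
ld_r <- function(gx, gy) {
  ok <- !is.na(gx) & !is.na(gy)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete subjects")
  if (stats::var(gx[ok]) == 0 || stats::var(gy[ok]) == 0) {
    stop("zero genotype variance; LD r undefined")
  }
  stats::cor(gx[ok], gy[ok])
}

#' Run both association models across a genotype matrix
#'
#' @param gm a `genotype_matrix` over the sampled subjects.
#' @param status per-subject case status aligned with `gm$subject_ids`.
#' @param weights per-subject sampling weights (weighted model).
#' @param index_g per-subject index-SNP genotypes (adjusted model).
#' @return data.frame with two rows (one per model) per variant, plus
#'   contig/pos columns from `gm$variants`.
#' @export
association_scan <- function(gm, status, weights, index_g) {
  res <- lapply(seq_len(ncol(gm$calls)), function(j) {
    g <- gm$calls[, j]
    id <- gm$variants$id[j]
    if (all(is.na(g)) || stats::var(g, na.rm = TRUE) == 0) {
      return(rbind(
        association_result(id, "weighted_marginal", NA_real_, NA_real_,
                           NA_real_, NA_real_, NA_real_, FALSE,
                           "zero variance"),
        association_result(id, "adjusted_conditional", NA_real_, NA_real_,
                           NA_real_, NA_real_, NA_real_, FALSE,
                           "zero variance")))
    }
    rbind(weighted_association(g, status, weights, id),
          adjusted_association(g, status, index_g, id))
  })
  out <- do.call(rbind, res)
  meta <- gm$variants[match(out$variant, gm$variants$id), ]
  out$contig <- meta$contig
  out$pos <- meta$pos
  rownames(out) <- NULL
  out
}
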