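## Truth-tagged synthetic study generator.
##
## Emulates the structure the analysis assumes: a ~500 kb reference
## segment with planted ERE motif instances; a phase-1 cohort of ~1763
## subjects with ~4000 biallelic SNVs whose site-frequency spectrum is
## rare-skewed; local LD from a founder-haplotype block-copying model
## plus explicitly planted high-r pairs; case status from a logistic
## model with planted effects; and a two-caller emission step that
## injects per-call discordance and missingness into the second caller.

#' Simulation configuration
#'
#' Defaults state the emulated study design: a 500 kb region with 4,000
#' SNVs; spectrum fractions 0.55 / 0.04 / 0.41 for MAF <= 0.005 /
#' (0.005, 0.01] / > 0.01 (the midpoint of the two published regional
#' spectra); a cohort of 1,763 with 199 cases + 201 controls resequenced;
#' one planted LD pair at r 0.99; two index SNPs and one motif-proximal
#' risk variant with odds ratio 1.8.
#'
#' @param seed integer RNG seed.
#' @param region_length reference length in bp.
#' @param n_variants number of biallelic SNVs.
#' @param spectrum length-3 fractions (rare, low, common) summing to 1.
#' @param ld_block_length haplotype block length in bp.
#' @param pool_size founder haplotypes per block.
#' @param planted_pairs list of `list(r = , freq = , with_index = )`
#'   high-LD pair specs; `with_index = TRUE` ties the pair's first member
#'   to index SNP 1.
#' @param n_cohort phase-1 cohort size.
#' @param n_cases_sampled,n_controls_sampled phase-2 subsample sizes.
#' @param index_freq allele frequency of the two index SNPs.
#' @param index_or odds ratios (length 2) of the index SNPs.
#' @param planted_effects list of `list(role = "near_motif", or = ,
#'   freq = )` additional risk variants (freq defaults to 0.30); role
#'   "near_motif" places the variant within 500 bp of a planted motif.
#' @param motif_plants data.frame (offset, strand, seq) of motif
#'   instances embedded in the reference (offsets 0-based).
#' @param caller_a list(missing_rate) for the primary caller's injected
#'   per-call missingness.
#' @param caller_b list(discordance_rate, missing_rate,
#'   discordant_variant_fraction): the second caller disagrees with the
#'   first at `discordance_rate` per call, but only at a designated
#'   `discordant_variant_fraction` of variants — dual-caller discordance
#'   in practice is concentrated in a minority of problem sites (the
#'   published filter found the discordant sites at 80-99% concordance,
#'   not diffuse call noise).
#' @param high_missing list(fraction, rate): a small fraction of variants
#'   is hard to call in both workflows and gets `rate` per-call
#'   missingness in each, driving them over the >10% missingness filter.
#' @param baseline_prevalence case probability at mean genotype (0.5:
#'   the phase-1 study is itself case-control).
#' @param background reference base composition (A, C, G, T).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              region_length = 500000L,
                              n_variants = 4000L,
                              spectrum = c(rare = 0.55, low = 0.04,
                                           common = 0.41),
                              ld_block_length = 20000L,
                              pool_size = 40L,
                              planted_pairs = list(list(r = 0.99,
                                                        freq = 0.30,
                                                        with_index = FALSE)),
                              n_cohort = 1763L,
                              n_cases_sampled = 199L,
                              n_controls_sampled = 201L,
                              index_freq = c(0.30, 0.30),
                              index_or = c(1.5, 1.4),
                              planted_effects = list(list(role = "near_motif",
                                                          or = 1.8)),
                              motif_plants = NULL,
                              caller_a = list(missing_rate = 0.01),
                              caller_b = list(discordance_rate = 0.05,
                                              missing_rate = 0.01,
                                              discordant_variant_fraction = 0.08),
                              high_missing = list(fraction = 0.02,
                                                  rate = 0.40),
                              baseline_prevalence = 0.5,
                              background = rep(0.25, 4)) {
  if (is.null(motif_plants)) {
    motif_plants <- data.frame(
      offset = as.integer(round(region_length * c(0.15, 0.35, 0.60, 0.85))),
      strand = c("+", "-", "+", "-"),
      ## 17-mers carrying the palindromic ERE core GGTCAnnnTGACC at the
      ## offsets the default width-17 model expects
      seq = c("AAGGTCACGATGACCTT", "CTGGTCATTGTGACCAG",
              "TGGGTCAGCATGACCCA", "GAGGTCAAAATGACCTC"),
      stringsAsFactors = FALSE)
  }
  cfg <- list(seed = as.integer(seed), region_length = as.integer(region_length),
              n_variants = as.integer(n_variants), spectrum = spectrum,
              ld_block_length = as.integer(ld_block_length),
              pool_size = as.integer(pool_size),
              planted_pairs = planted_pairs, n_cohort = as.integer(n_cohort),
              n_cases_sampled = as.integer(n_cases_sampled),
              n_controls_sampled = as.integer(n_controls_sampled),
              index_freq = index_freq, index_or = index_or,
              planted_effects = planted_effects,
              motif_plants = motif_plants, caller_a = caller_a,
              caller_b = caller_b, high_missing = high_missing,
              baseline_prevalence = baseline_prevalence,
              background = background)
  if (abs(sum(cfg$spectrum) - 1) > 1e-9) stop("spectrum must sum to 1")
  rates <- c(cfg$caller_a$missing_rate, cfg$caller_b$discordance_rate,
             cfg$caller_b$missing_rate,
             cfg$caller_b$discordant_variant_fraction,
             cfg$high_missing$fraction, cfg$high_missing$rate)
  if (any(rates < 0 | rates > 1)) stop("caller error rates must be in [0, 1]")
  if (any(cfg$motif_plants$offset < 0 |
          cfg$motif_plants$offset + nchar(cfg$motif_plants$seq) >
          cfg$region_length)) {
    stop("motif plant outside the region")
  }
  stopifnot_prob(cfg$baseline_prevalence, "baseline_prevalence")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate the reference segment with planted motifs
#'
#' i.i.d. background sequence of `region_length` with each motif plant
#' written at its 0-based offset ('-' plants are embedded as the reverse
#' complement of their motif sequence). Deterministic under the config
#' seed; overlapping plants are rejected.
#'
#' @param config a `simulation_config`.
#' @param contig_id contig name (default "synth_region").
#' @return list: `contig_id`, `sequence` (character), `plants`
#'   (data.frame start, end, strand, seq — 0-based half-open truth
#'   intervals).
#' @export
generate_reference <- function(config, contig_id = "synth_region") {
  mp <- config$motif_plants
  w <- nchar(mp$seq)
  plants <- data.frame(start = mp$offset, end = mp$offset + w,
                       strand = mp$strand, seq = toupper(mp$seq),
                       stringsAsFactors = FALSE)
  plants <- plants[order(plants$start), , drop = FALSE]
  if (nrow(plants) > 1 &&
      any(plants$start[-1] < plants$end[-nrow(plants)])) {
    stop("overlapping motif plants")
  }
  seq <- with_seed(config$seed, {
    paste(sample(BASES, config$region_length, replace = TRUE,
                 prob = config$background), collapse = "")
  })
  for (i in seq_len(nrow(plants))) {
    payload <- if (plants$strand[i] == "+") plants$seq[i] else
      revcomp(plants$seq[i])
    substring(seq, plants$start[i] + 1L, plants$end[i]) <- payload
  }
  rownames(plants) <- NULL
  list(contig_id = contig_id, sequence = seq, plants = plants)
}

## log-uniform draw on (lo, hi)
rlogunif <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

## Correlated Bernoulli: y with the same marginal freq p as x and
## Pearson correlation r (per chromosome).
correlated_bernoulli <- function(x, p, r) {
  p1 <- p + r * (1 - p)   # P(y=1 | x=1)
  p0 <- p * (1 - r)       # P(y=1 | x=0)
  as.integer(stats::runif(length(x)) < ifelse(x == 1, p1, p0))
}

#' Generate the phase-1 cohort
#'
#' Haplotype structure: variants with target frequency > 0.01 are drawn
#' through a per-block founder-haplotype pool (block copying induces LD
#' within `ld_block_length` blocks); rarer variants are independent
#' Bernoulli per chromosome (rare alleles carry essentially no pairwise
#' LD). Planted pairs and index SNPs override the block machinery at the
#' haplotype level. Case status follows a logistic model with the
#' configured planted effects, centered so the case fraction tracks
#' `baseline_prevalence`.
#'
#' @param config a `simulation_config`.
#' @param reference output of [generate_reference()].
#' @return list: `genotypes` (cohort `genotype_matrix`), `phenotypes`
#'   (data.frame subject_id, status, g_index1, g_index2), `truth` (per
#'   variant true frequency and role; planted pair/effect/motif records).
#' @export
generate_cohort <- function(config, reference) {
  with_seed(config$seed + 1L, {
    nv <- config$n_variants
    N <- config$n_cohort
    n_chrom <- 2L * N

    positions <- sort(sample.int(config$region_length, nv))
    ref_base <- vapply(positions, function(p)
      substring(reference$sequence, p, p), character(1))
    alt_base <- vapply(ref_base, function(b)
      sample(setdiff(BASES, b), 1), character(1), USE.NAMES = FALSE)

    bin <- sample(c("rare", "low", "common"), nv, replace = TRUE,
                  prob = config$spectrum)
    freq <- numeric(nv)
    freq[bin == "rare"] <- rlogunif(sum(bin == "rare"), 0.0003, 0.005)
    freq[bin == "low"] <- rlogunif(sum(bin == "low"), 0.005, 0.01)
    freq[bin == "common"] <- rlogunif(sum(bin == "common"), 0.02, 0.5)

    ## roles: two index SNPs, optional near-motif effect variants, pairs
    common_idx <- which(bin == "common")
    role <- rep(NA_character_, nv)
    pick_common <- function(k) {
      free <- setdiff(common_idx, which(!is.na(role)))
      if (length(free) < k) stop("not enough common variants for roles")
      sample(free, k)
    }
    idx_index <- pick_common(2)
    role[idx_index] <- c("index1", "index2")
    freq[idx_index] <- config$index_freq

    effect_idx <- integer(0)
    effect_or <- numeric(0)
    for (pe in config$planted_effects) {
      j <- if (identical(pe$role, "near_motif")) {
        ## move a free common variant next to a planted motif
        j0 <- pick_common(1)
        target <- reference$plants$end[1] + 150L  # 1-based pos ~150 bp downstream
        positions[j0] <- target + 1L
        ref_base[j0] <- substring(reference$sequence, positions[j0],
                                  positions[j0])
        alt_base[j0] <- sample(setdiff(BASES, ref_base[j0]), 1)
        role[j0] <- "near_motif"
        j0
      } else {
        j0 <- pick_common(1)
        role[j0] <- pe$role %||% "risk"
        j0
      }
      freq[j] <- pe$freq %||% 0.30
      effect_idx <- c(effect_idx, j)
      effect_or <- c(effect_or, pe$or)
    }

    pair_idx <- matrix(integer(0), ncol = 2)
    pair_r <- numeric(0)
    for (pp in config$planted_pairs) {
      a <- if (isTRUE(pp$with_index)) idx_index[1] else {
        j0 <- pick_common(1); role[j0] <- "pair_a"; j0
      }
      b <- pick_common(1)
      role[b] <- "pair_b"
      if (!isTRUE(pp$with_index)) freq[c(a, b)] <- pp$freq %||% 0.30
      else freq[b] <- config$index_freq[1]
      pair_idx <- rbind(pair_idx, c(a, b))
      pair_r <- c(pair_r, pp$r)
    }

    ## haplotypes
    hapA <- matrix(0L, N, nv)
    hapB <- matrix(0L, N, nv)
    indep <- which(freq <= 0.01)
    if (length(indep) > 0) {
      hapA[, indep] <- matrix(
        as.integer(stats::runif(N * length(indep)) <
                     rep(freq[indep], each = N)), N)
      hapB[, indep] <- matrix(
        as.integer(stats::runif(N * length(indep)) <
                     rep(freq[indep], each = N)), N)
    }
    blockcov <- which(freq > 0.01)
    if (length(blockcov) > 0) {
      K <- config$pool_size
      block_of <- (positions[blockcov] - 1L) %/% config$ld_block_length
      for (blk in unique(block_of)) {
        js <- blockcov[block_of == blk]
        ## founder alleles: quantized count m/K in [1, K-1]
        founders <- vapply(js, function(j) {
          m <- max(1L, min(K - 1L, as.integer(round(freq[j] * K))))
          f <- integer(K); f[sample.int(K, m)] <- 1L; f
        }, integer(config$pool_size))
        zA <- sample.int(K, N, replace = TRUE)
        zB <- sample.int(K, N, replace = TRUE)
        hapA[, js] <- founders[zA, , drop = FALSE]
        hapB[, js] <- founders[zB, , drop = FALSE]
      }
    }
    ## overrides: index SNPs and pair members at exact Bernoulli freqs
    override <- unique(c(idx_index, as.vector(pair_idx)))
    for (j in override) {
      hapA[, j] <- as.integer(stats::runif(N) < freq[j])
      hapB[, j] <- as.integer(stats::runif(N) < freq[j])
    }
    for (k in seq_along(pair_r)) {
      a <- pair_idx[k, 1]; b <- pair_idx[k, 2]
      hapA[, b] <- correlated_bernoulli(hapA[, a], freq[a], pair_r[k])
      hapB[, b] <- correlated_bernoulli(hapB[, a], freq[a], pair_r[k])
    }

    G <- hapA + hapB
    storage.mode(G) <- "integer"

    ## the near-motif override may have broken position order; re-sort
    ord <- order(positions)
    if (!identical(ord, seq_len(nv))) {
      remap <- match(seq_len(nv), ord)   # old index -> new index
      positions <- positions[ord]; ref_base <- ref_base[ord]
      alt_base <- alt_base[ord]; bin <- bin[ord]; freq <- freq[ord]
      role <- role[ord]; G <- G[, ord, drop = FALSE]
      idx_index <- remap[idx_index]; effect_idx <- remap[effect_idx]
      if (nrow(pair_idx) > 0) pair_idx[] <- remap[pair_idx]
    }

    ## phenotype
    betas <- c(log(config$index_or), log(effect_or))
    eff <- c(idx_index, effect_idx)
    eta <- stats::qlogis(config$baseline_prevalence)
    if (length(eff) > 0) {
      Gc <- sweep(G[, eff, drop = FALSE], 2,
                  colMeans(G[, eff, drop = FALSE]))
      eta <- eta + as.numeric(Gc %*% betas)
    }
    y <- as.integer(stats::runif(N) < stats::plogis(eta))
    subject_ids <- sprintf("S%04d", seq_len(N))

    variants <- data.frame(
      contig = reference$contig_id, pos = positions, ref = ref_base,
      alt = alt_base,
      rsid = sprintf("sv%05d", seq_len(nv)),
      stringsAsFactors = FALSE)
    gm <- genotype_matrix(G, variants, subject_ids)
    phen <- data.frame(subject_id = subject_ids,
                       status = ifelse(y == 1, "case", "control"),
                       g_index1 = G[, idx_index[1]],
                       g_index2 = G[, idx_index[2]],
                       stringsAsFactors = FALSE)
    truth <- list(
      variant_id = variants$rsid,
      freq_target = freq,
      maf_cohort = apply(G, 2, compute_maf),
      role = role,
      index_ids = variants$rsid[idx_index],
      effects = data.frame(variant = variants$rsid[eff],
                           beta = betas, stringsAsFactors = FALSE),
      pairs = if (nrow(pair_idx) > 0)
        data.frame(a = variants$rsid[pair_idx[, 1]],
                   b = variants$rsid[pair_idx[, 2]],
                   r_target = pair_r, stringsAsFactors = FALSE)
      else NULL,
      plants = reference$plants)
    list(genotypes = gm, phenotypes = phen, truth = truth)
  })
}

#' Emit the synthetic study bundle to disk
#'
#' Writes the reference FASTA, a caller-A VCF holding the sampled
#' subjects' true genotypes, a caller-B VCF with discordance and
#' missingness injected per call at the configured rates, a phenotype TSV
#' (subject_id, status, g_index1, g_index2, stratum, weight), and a truth
#' JSON sidecar. Every file is re-readable by the package's own readers.
#'
#' @param config a `simulation_config`.
#' @param reference output of [generate_reference()].
#' @param cohort output of [generate_cohort()].
#' @param sampled output of [sample_subphase()] (the phase-2 subset).
#' @param dir output directory (created if needed).
#' @return named list of file paths (fasta, vcf_a, vcf_b, phenotypes,
#'   truth).
#' @export
emit_study <- function(config, reference, cohort, sampled, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "reference.fa"),
                vcf_a = file.path(dir, "caller_a.vcf"),
                vcf_b = file.path(dir, "caller_b.vcf"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                truth = file.path(dir, "truth.json"))

  dna <- Biostrings::DNAStringSet(reference$sequence)
  names(dna) <- reference$contig_id
  Biostrings::writeXStringSet(dna, paths$fasta, width = 80)

  ids <- sampled$subjects$subject_id
  sub_idx <- match(ids, cohort$genotypes$subject_ids)
  truth_calls <- cohort$genotypes$calls[sub_idx, , drop = FALSE]
  nv <- ncol(truth_calls)

  masks <- with_seed(config$seed + 2L, {
    discordant_vars <- sort(sample.int(
      nv, round(config$caller_b$discordant_variant_fraction * nv)))
    hm_pool <- setdiff(seq_len(nv), discordant_vars)
    high_missing_vars <- sort(sample(
      hm_pool, min(length(hm_pool),
                   round(config$high_missing$fraction * nv))))
    miss_mat <- function(base_rate) {
      r <- matrix(base_rate, nrow(truth_calls), nv)
      r[, high_missing_vars] <- config$high_missing$rate
      matrix(stats::runif(length(r)) < r, nrow(r))
    }
    calls_a <- truth_calls
    calls_a[miss_mat(config$caller_a$missing_rate)] <- NA_integer_
    calls_b <- truth_calls
    flip <- matrix(FALSE, nrow(truth_calls), nv)
    flip[, discordant_vars] <-
      stats::runif(nrow(truth_calls) * length(discordant_vars)) <
      config$caller_b$discordance_rate
    if (any(flip)) {
      calls_b[flip] <- (calls_b[flip] +
                          sample(1:2, sum(flip), replace = TRUE)) %% 3L
    }
    calls_b[miss_mat(config$caller_b$missing_rate)] <- NA_integer_
    list(calls_a = calls_a, calls_b = calls_b,
         discordant_vars = discordant_vars,
         high_missing_vars = high_missing_vars)
  })

  gm_a <- genotype_matrix(masks$calls_a, cohort$genotypes$variants, ids)
  write_vcf(gm_a, paths$vcf_a, contig_length = config$region_length)
  gm_b <- genotype_matrix(masks$calls_b, cohort$genotypes$variants, ids)
  write_vcf(gm_b, paths$vcf_b, contig_length = config$region_length)

  phen <- sampled$subjects
  phen_out <- data.frame(
    subject_id = phen$subject_id, status = phen$status,
    g_index1 = phen$g1, g_index2 = phen$g2,
    stratum = phen$stratum, weight = phen$weight,
    stringsAsFactors = FALSE)
  data.table::fwrite(phen_out, paths$phenotypes, sep = "\t")

  truth <- cohort$truth
  jsonlite::write_json(
    list(seed = config$seed,
         variant_id = truth$variant_id,
         freq_target = truth$freq_target,
         maf_cohort = unname(truth$maf_cohort),
         role = truth$role,
         index_ids = truth$index_ids,
         effects = truth$effects,
         pairs = truth$pairs,
         plants = truth$plants,
         discordant_variants = truth$variant_id[masks$discordant_vars],
         high_missing_variants = truth$variant_id[masks$high_missing_vars],
         strata = sampled$strata),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null")
  paths
}

#' Generate and emit a complete synthetic study
#'
#' Convenience wrapper: reference, cohort, strata, phase-2 sample, files.
#'
#' @param config a `simulation_config`.
#' @param dir output directory.
#' @return list: `paths`, `config`, `reference`, `cohort`, `design`,
#'   `sampled`.
#' @export
simulate_study <- function(config = simulation_config(), dir = tempfile("study")) {
  reference <- generate_reference(config)
  cohort <- generate_cohort(config, reference)
  design <- assign_strata(cohort$phenotypes$status,
                          cohort$phenotypes$g_index1,
                          cohort$phenotypes$g_index2,
                          subject_ids = cohort$phenotypes$subject_id,
                          index_snp_ids = cohort$truth$index_ids)
  sampled <- sample_subphase(design, config$n_cases_sampled,
                             config$n_controls_sampled,
                             seed = config$seed + 3L)
  paths <- emit_study(config, reference, cohort, sampled, dir)
  list(paths = paths, config = config, reference = reference,
       cohort = cohort, design = design, sampled = sampled)
}
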