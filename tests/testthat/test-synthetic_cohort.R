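quiet_cfg <- function(...) {
  simulation_config(caller_a = list(missing_rate = 0),
                    caller_b = list(discordance_rate = 0, missing_rate = 0,
                                    discordant_variant_fraction = 0),
                    high_missing = list(fraction = 0, rate = 0), ...)
}

test_that("generate_reference embeds plants and is deterministic", {
  cfg <- simulation_config(seed = 3, region_length = 5000,
                           motif_plants = data.frame(
                             offset = c(1000L, 3000L), strand = c("+", "-"),
                             seq = c("GTTGGTCTGGATGACTC", "AAGGTCACGATGACCTT"),
                             stringsAsFactors = FALSE))
  ref <- generate_reference(cfg)
  expect_equal(nchar(ref$sequence), 5000L)
  expect_equal(substring(ref$sequence, 1001, 1017), "GTTGGTCTGGATGACTC")
  # '-' plant: reference slice is the reverse complement of the motif
  expect_equal(substring(ref$sequence, 3001, 3017),
               revcomp("AAGGTCACGATGACCTT"))
  expect_equal(ref$plants$start, c(1000L, 3000L))
  expect_equal(ref$plants$end, c(1017L, 3017L))

  ref2 <- generate_reference(cfg)
  expect_identical(ref$sequence, ref2$sequence)

  cfg_bad <- simulation_config(seed = 3, region_length = 5000,
                               motif_plants = data.frame(
                                 offset = c(1000L, 1010L),
                                 strand = c("+", "+"),
                                 seq = c("GTTGGTCTGGATGACTC",
                                         "AAGGTCACGATGACCTT"),
                                 stringsAsFactors = FALSE))
  expect_error(generate_reference(cfg_bad), "overlap")
})

test_that("cohort spectrum, LD pair and strata structure match the config", {
  cfg <- simulation_config(seed = 11, region_length = 200000,
                           n_variants = 4000)
  ref <- generate_reference(cfg)
  cohort <- generate_cohort(cfg, ref)
  maf <- cohort$truth$maf_cohort

  # realized MAF bin fractions near the configured spectrum
  expect_equal(mean(maf <= 0.005), 0.55, tolerance = 0.05 / 0.55)
  expect_equal(mean(maf > 0.01), 0.41, tolerance = 0.05 / 0.41)

  # planted r = 0.99 pair realizes >= 0.95 at cohort size
  pr <- cohort$truth$pairs
  G <- cohort$genotypes$calls
  expect_gte(ld_r(G[, pr$a], G[, pr$b]), 0.95)

  # index SNPs occupy all 18 strata at n = 1763
  des <- assign_strata(cohort$phenotypes$status, cohort$phenotypes$g_index1,
                       cohort$phenotypes$g_index2)
  expect_equal(sum(des$strata$N_cohort > 0), 18L)

  # determinism of the whole cohort under the seed
  cohort2 <- generate_cohort(cfg, ref)
  expect_identical(cohort$genotypes$calls, cohort2$genotypes$calls)
  expect_identical(cohort$phenotypes, cohort2$phenotypes)
})

test_that("null configuration leaves case status independent of genotype", {
  cfg <- simulation_config(seed = 23, region_length = 20000, n_variants = 60,
                           index_or = c(1, 1), planted_effects = list())
  ref <- generate_reference(cfg)
  cohort <- generate_cohort(cfg, ref)
  y <- as.integer(cohort$phenotypes$status == "case")
  G <- cohort$genotypes$calls
  poly <- which(apply(G, 2, var) > 0)
  r <- vapply(poly, function(j) abs(cor(G[, j], y)), numeric(1))
  # no correlation should exceed ~4/sqrt(n)
  expect_lt(max(r), 4 / sqrt(nrow(G)))
})

test_that("emit_study round-trips and injects configured caller errors", {
  # zero-error config: both caller VCFs identical, genotypes exact
  cfg0 <- quiet_cfg(seed = 5, region_length = 20000, n_variants = 80)
  st0 <- simulate_study(cfg0, dir = tempfile())
  expect_identical(readLines(st0$paths$vcf_a)[-(1:3)],
                   readLines(st0$paths$vcf_b)[-(1:3)])
  gm <- read_vcf_genotypes(st0$paths$vcf_a)
  sidx <- match(st0$sampled$subjects$subject_id,
                st0$cohort$genotypes$subject_ids)
  expect_equal(unname(gm$calls),
               unname(st0$cohort$genotypes$calls[sidx, ]))
  expect_equal(gm$variants$pos, st0$cohort$genotypes$variants$pos)

  # discordance injected at every variant at per-call rate 0.02
  cfg2 <- simulation_config(seed = 5, region_length = 20000, n_variants = 80,
                            caller_a = list(missing_rate = 0),
                            caller_b = list(discordance_rate = 0.02,
                                            missing_rate = 0,
                                            discordant_variant_fraction = 1),
                            high_missing = list(fraction = 0, rate = 0))
  st2 <- simulate_study(cfg2, dir = tempfile())
  a <- read_vcf_genotypes(st2$paths$vcf_a)$calls
  b <- read_vcf_genotypes(st2$paths$vcf_b)$calls
  both <- !is.na(a) & !is.na(b)
  frac <- mean(a[both] != b[both])
  # binomial tolerance at 400 x 80 calls
  expect_equal(frac, 0.02, tolerance = 3 * sqrt(0.02 * 0.98 / sum(both)) / 0.02)

  # phenotype table carries strata and weights consistent with the design
  ph <- read_phenotypes(st0$paths$phenotypes)
  expect_setequal(colnames(ph), c("subject_id", "status", "g_index1",
                                  "g_index2", "stratum", "weight"))
  expect_equal(nrow(ph), 400L)
  expect_true(all(ph$weight >= 1))
})

test_that("pipeline on a generated bundle recovers the planted truth", {
  st <- small_study()
  out <- tempfile()
  res <- run_pipeline(st$paths$fasta, st$paths$vcf_a, st$paths$vcf_b,
                      st$paths$phenotypes, out_dir = out)
  tr <- jsonlite::read_json(st$paths$truth, simplifyVector = TRUE)

  # (ii) every planted motif is found at its exact interval and strand
  occ_key <- paste(res$occurrences$start, res$occurrences$end,
                   res$occurrences$strand)
  plant_key <- paste(tr$plants$start, tr$plants$end, tr$plants$strand)
  expect_true(all(plant_key %in% occ_key))

  # (i) retained set equals an independent recomputation from the raw VCFs
  a <- read_vcf_genotypes(st$paths$vcf_a)
  b <- read_vcf_genotypes(st$paths$vcf_b)
  expected_retained <- character(0)
  for (j in seq_len(ncol(a$calls))) {
    x <- a$calls[, j]; y <- b$calls[, j]
    both <- !is.na(x) & !is.na(y)
    if (any(x[both] != y[both])) next               # discordant
    m <- ifelse(!is.na(x), x, y)
    if (mean(is.na(m)) > 0.10) next                 # high missing
    if (length(unique(m[!is.na(m)])) <= 1) next     # monomorphic
    expected_retained <- c(expected_retained, a$variants$id[j])
  }
  expect_setequal(res$qc$genotypes$variants$id, expected_retained)

  # every realized-discordant variant was one the generator designated
  removed_disc <- names(res$qc$report$removal_reason)[
    res$qc$report$removal_reason == "discordant"]
  expect_true(all(removed_disc %in% tr$discordant_variants))

  # (iii) the planted motif-proximal risk variant is annotated near a motif
  nm <- tr$variant_id[which(tr$role == "near_motif")]
  ann_nm <- res$annotations[res$annotations$rsid == nm, ]
  expect_gt(nrow(ann_nm), 0)
  expect_true(all(ann_nm$relation %in% c("near", "within")))

  # (iv) candidate table contains every planted causal motif-proximal
  # variant whose p beat the threshold, per the truth sidecar
  aw <- res$associations[res$associations$model == "weighted_marginal", ]
  for (v in tr$effects$variant) {
    pv <- aw$p_value[aw$variant == v]
    if (length(pv) == 1 && !is.na(pv) && pv < 0.01 &&
        v %in% res$annotations$rsid[res$annotations$relation == "near"]) {
      expect_true(v %in% res$candidates$rsid)
    }
  }
})

test_that("planted causal variants outrank null variants across seeds", {
  # weighted p of the planted near-motif variant should fall below the
  # median null p in >= 90% of seeds
  hits <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    cfg <- quiet_cfg(seed = 100 + s, region_length = 30000, n_variants = 80)
    ref <- generate_reference(cfg)
    cohort <- generate_cohort(cfg, ref)
    des <- assign_strata(cohort$phenotypes$status,
                         cohort$phenotypes$g_index1,
                         cohort$phenotypes$g_index2,
                         subject_ids = cohort$phenotypes$subject_id)
    smp <- sample_subphase(des, 199, 201, seed = cfg$seed)
    sidx <- match(smp$subjects$subject_id, cohort$genotypes$subject_ids)
    nm <- which(cohort$truth$role == "near_motif")
    gm <- genotype_matrix(cohort$genotypes$calls[sidx, , drop = FALSE],
                          cohort$genotypes$variants)
    null_idx <- which(is.na(cohort$truth$role) &
                      cohort$truth$maf_cohort > 0.05)
    ps <- vapply(c(nm, null_idx), function(j) {
      weighted_association(gm$calls[, j], smp$subjects$status,
                           smp$subjects$weight)$p_value
    }, numeric(1))
    if (!is.na(ps[1]) && ps[1] < stats::median(ps[-1], na.rm = TRUE)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})
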