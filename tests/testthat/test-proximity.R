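test_that("snp_motif_distance reproduces every published candidate row", {
  tab <- ref_candidates()
  expect_equal(nrow(tab), 21L)
  got <- snp_motif_distance(tab$pos, tab$motif_start, tab$motif_end)
  expect_equal(got, tab$distance_bp)
})

test_that("snp_motif_distance conventions and edge cases", {
  # inside the 1-based inclusive span [start+1, end]
  expect_equal(snp_motif_distance(49592980, 49592974, 49592991), 0L)
  expect_equal(snp_motif_distance(49592975, 49592974, 49592991), 0L)  # first base
  expect_equal(snp_motif_distance(49592991, 49592974, 49592991), 0L)  # last base
  # immediately adjacent bases: zero bases strictly between
  expect_equal(snp_motif_distance(49592974, 49592974, 49592991), 0L)
  expect_equal(snp_motif_distance(49592992, 49592974, 49592991), 0L)
  expect_error(snp_motif_distance(5, 10, 10), "motif_start")
  expect_error(snp_motif_distance(0, 10, 20), "pos")
})

test_that("distance agrees with a brute-force per-base minimum", {
  set.seed(21)
  for (i in 1:50) {
    s <- sample.int(1000, 1)
    e <- s + sample.int(30, 1)
    pos <- sample.int(1100, 1)
    brute <- min(vapply((s + 1):e, function(b) {
      if (pos == b) 0L else abs(pos - b) - 1L
    }, integer(1)))
    expect_equal(snp_motif_distance(pos, s, e), brute)
  }
})

test_that("annotate_proximity windows, boundaries and multiplicity", {
  occ <- data.frame(contig = "c1", start = c(1000L, 2000L),
                    end = c(1017L, 2017L), strand = c("+", "-"),
                    score = 10, pvalue = 1e-6,
                    matched_seq = "AAGGTCACGATGACCTT", motif_id = "ERE",
                    stringsAsFactors = FALSE)
  # distance 500 kept (pos = start - 500), 501 excluded
  v <- data.frame(contig = "c1", pos = c(500L, 499L), ref = "A", alt = "G",
                  rsid = c("in", "out"), stringsAsFactors = FALSE)
  ann <- annotate_proximity(v, occ, window = 500)
  expect_equal(ann$rsid, "in")
  expect_equal(ann$distance_bp, 500L)
  expect_equal(ann$relation, "near")

  # a SNP flanked by both motifs gets two annotations
  v2 <- data.frame(contig = "c1", pos = 1500L, ref = "A", alt = "G",
                   rsid = "mid", stringsAsFactors = FALSE)
  ann2 <- annotate_proximity(v2, occ, window = 500)
  expect_equal(nrow(ann2), 2L)
  expect_setequal(ann2$motif_start, c(1000L, 2000L))

  # strand independence of distance
  occ_flip <- occ
  occ_flip$strand <- c("-", "+")
  ann3 <- annotate_proximity(v2, occ_flip, window = 500)
  expect_equal(ann3$distance_bp, ann2$distance_bp)

  # within: distance 0 and relation within
  v4 <- data.frame(contig = "c1", pos = 1005L, ref = "A", alt = "G",
                   rsid = "inside", stringsAsFactors = FALSE)
  ann4 <- annotate_proximity(v4, occ, window = 500)
  expect_equal(ann4$relation[ann4$motif_start == 1000], "within")
  expect_equal(ann4$distance_bp[ann4$motif_start == 1000], 0L)

  expect_equal(nrow(annotate_proximity(v[0, ], occ)), 0L)
  expect_equal(nrow(annotate_proximity(v, occ[0, ])), 0L)
})

test_that("the published chr16 SNPs are all near but not within their motifs", {
  tab <- ref_candidates()
  chr16 <- tab[tab$region == "chr16", ]
  v <- data.frame(contig = "chr16", pos = chr16$pos, ref = "A", alt = "G",
                  rsid = chr16$rsid, stringsAsFactors = FALSE)
  occ <- unique(data.frame(contig = "chr16", start = chr16$motif_start,
                           end = chr16$motif_end, strand = chr16$strand,
                           score = 0, pvalue = 1e-5,
                           matched_seq = chr16$motif_seq, motif_id = "ERE",
                           stringsAsFactors = FALSE))
  ann <- annotate_proximity(v, occ, window = 500)
  # each printed (SNP, motif) pair is recovered with relation "near"
  printed <- paste(chr16$rsid, chr16$motif_start)
  found <- paste(ann$rsid, ann$motif_start)
  expect_true(all(printed %in% found))
  expect_true(all(ann$relation[found %in% printed] == "near"))
})

test_that("classify_allele_effect calls creates/disrupts/changes/none", {
  motif <- "GTTGGTCTGGATGACTC"
  m <- build_motif_model(motif, pseudocount = 0.1)
  seq0 <- random_seq(300, seed = 31)
  seq_cons <- seq0
  substring(seq_cons, 101, 117) <- motif

  # perfect match p = 0.25^17 ~ 5.8e-11; one mismatch ~ 3e-9: alpha
  # between the two separates the alleles
  alpha <- 1e-10

  # ref breaks the consensus at motif position 6, alt restores it
  seq_broken <- seq_cons
  broken_base <- setdiff(BASES4, substring(motif, 6, 6))[1]
  substring(seq_broken, 106, 106) <- broken_base
  v_creates <- list(pos = 106, ref = broken_base,
                    alt = substring(motif, 6, 6))
  expect_equal(classify_allele_effect(seq_broken, v_creates, m, alpha),
               "creates")

  # mirror fixture: ref is the consensus, alt breaks it
  v_disrupts <- list(pos = 106, ref = substring(motif, 6, 6),
                     alt = broken_base)
  expect_equal(classify_allele_effect(seq_cons, v_disrupts, m, alpha),
               "disrupts")

  # both alleles pass a looser alpha but scores differ by > 0.5 bits
  expect_equal(classify_allele_effect(seq_cons, v_disrupts, m, alpha = 1e-6),
               "changes")

  # background-only sequence far from any qualifying window
  v_none <- list(pos = 250, ref = substring(seq0, 250, 250),
                 alt = setdiff(BASES4, substring(seq0, 250, 250))[1])
  expect_equal(classify_allele_effect(seq0, v_none, m, alpha), "none")

  # reference mismatch is an error naming position and base
  expect_error(classify_allele_effect(seq_cons, list(pos = 106, ref = "N",
                                                     alt = "A"), m, alpha),
               "position 106")
})

test_that("allele swap maps creates <-> disrupts and fixes none", {
  motif <- "GTTGGTCTGGATGACTC"
  m <- build_motif_model(motif, pseudocount = 0.1)
  alpha <- 1e-10
  set.seed(77)
  for (i in 1:10) {
    seq_cons <- random_seq(200)
    substring(seq_cons, 51, 67) <- motif
    p <- sample(1:17, 1)
    ref <- substring(motif, p, p)
    alt <- sample(setdiff(BASES4, ref), 1)
    v <- list(pos = 50 + p, ref = ref, alt = alt)
    eff <- classify_allele_effect(seq_cons, v, m, alpha)
    seq_alt <- seq_cons
    substring(seq_alt, 50 + p, 50 + p) <- alt
    eff_sw <- classify_allele_effect(seq_alt, list(pos = 50 + p, ref = alt,
                                                   alt = ref), m, alpha)
    expected <- c(creates = "disrupts", disrupts = "creates",
                  changes = "changes", none = "none")[eff]
    expect_equal(eff_sw, unname(expected))
  }
})
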