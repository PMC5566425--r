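---
title: "Methods: ERE motif annotation and two-phase association in ereseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERE motif annotation and two-phase association in ereseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ereseq)
```

## The problem

Targeted deep resequencing of regulatory regions — here, the ~500 kb
segments around *ZNF423* (chr16) and *CTSO* (chr4) that carry breast-cancer
risk signals under SERM chemoprevention — produces thousands of SNVs whose
interest lies in their relationship to estrogen response elements (EREs):
short palindromic motifs (core `GGTCAnnnTGACC`) bound by ERα. `ereseq`
implements the computational arm of such a study as a reusable pipeline:

1. **Motif scanning** (`build_motif_model`, `scan_sequence`): a log-odds
   position weight matrix is evaluated over every window on both strands,
   and each window receives an *exact* p-value — the probability that an
   i.i.d. background sequence of the motif's width scores at least as
   high — computed by dynamic programming over positions on a discretized
   score grid, as FIMO does.
2. **Proximity annotation** (`snp_motif_distance`, `annotate_proximity`):
   each variant is related to each motif occurrence within a window
   (default ±500 bp) and, when it falls *inside* a motif, its alleles are
   compared (`classify_allele_effect`) to call `creates` / `disrupts` /
   `changes` / `none`.
3. **Variant QC** (`qc_pipeline`): dual-caller concordance (100%-agreement
   rule), missingness (> 10% strict), monomorphism; site-frequency-spectrum
   summary of survivors in bins MAF ≤ 0.005, (0.005, 0.01], > 0.01.
4. **Two-phase association** (`assign_strata`, `sample_subphase`,
   `weighted_association`, `adjusted_association`): the resequenced
   subsample (199 cases + 201 controls) is drawn from 18 strata defined by
   case status × joint genotypes at two index SNPs; analysis is either an
   inverse-probability-weighted (IPW) marginal logistic regression with a
   sandwich variance, or an unweighted logistic regression adjusted for
   the index-SNP genotype.
5. **Reporting** (`build_candidate_table`, `count_distinct_motifs`): the
   near-ERE candidate table (distance ≤ 500 bp, p < 1E-02), one row per
   (SNP, motif) pair, sorted by p then position, with distinct-motif
   counts.
6. **Synthetic cohort** (`simulation_config`, `simulate_study`): a
   truth-tagged generator emulating the study's structure so every stage
   is testable without subject-level data.

## Coordinate conventions

Motif occurrences are 0-based half-open `[start, end)` (BED-like); SNP
positions are 1-based (VCF-like). The distance between a SNP outside a
motif and the motif is the number of bases *strictly between* the SNP base
and the nearest motif base: `start - pos` upstream, `pos - end - 1`
downstream; inside the motif's 1-based inclusive span the distance is 0.
This is the only convention that reproduces all 21 rows of the published
candidate table shipped in `extdata` (e.g. position 49614038 against motif
`[49613770, 49613787)` gives 250; 49688324 against `[49688371, 49688388)`
gives 47), which the test suite asserts row by row. "±500 bp" is read
inclusively (distance ≤ 500), consistent with a published row at 499.

## The motif model and its numerics

The log-odds entry for base $b$ at position $i$ is

$$\mathrm{LO}_{ib} = \log_2 \frac{p_{ib} + c\,q_b}{(1 + c)\,q_b},$$

with position probability $p_{ib}$, background $q_b$, pseudocount $c$
(default 0.1). A consensus letter expands to a uniform distribution over
its IUPAC set; `N` columns therefore score 0 everywhere, and an `N` *base*
in the scanned sequence contributes its column's background expectation,
so masked references remain scannable.

Exact p-values discretize each column to integer bins of size
`granularity` (default: score support / 10,000) and convolve the column
distributions under the background. Windows are scored **on the same
grid** when p-values are looked up — otherwise a window equal to the
attained maximum could land a rounding-error above the DP support and
receive a spurious p of 0. Because a background need not be
complement-symmetric, the minus strand gets its own null distribution
(the reverse-complemented model under the same background). Both strands
of a palindromic hit are reported, as FIMO does; `dedupe = TRUE` keeps
the better p per interval.

The shipped default model (`default_ere_model()`) is the 13-bp palindromic
ERE consensus `GGTCAnnnTGACC` padded with flanking `N` columns to width
17, the width of every published motif instance in the candidate table.
The curated ERE matrix used by the original analysis is not public, so the
default is a documented stand-in and any consensus or 4-row count matrix
can be swapped in. The default per-window threshold is `alpha = 1e-4`
(the FIMO default); the original study's threshold is unstated.

### Allele effects

For a variant inside a motif, every width-length window overlapping the
position is scored on both strands with the reference and alternate
allele; with best p-values $p_{\mathrm{ref}}, p_{\mathrm{alt}}$ and
threshold $\alpha$:
`creates` iff $p_{\mathrm{alt}} \le \alpha < p_{\mathrm{ref}}$;
`disrupts` iff $p_{\mathrm{ref}} \le \alpha < p_{\mathrm{alt}}$;
`changes` iff both pass and the best scores differ by more than 0.5 bits
(the 0.5-bit tolerance is this package's choice; no quantitative criterion
was published); otherwise `none`. Swapping ref and alt exchanges
`creates`/`disrupts` and fixes `changes`/`none`, a property the tests
exercise.

## QC design choices

Removal reasons are attributed with precedence **discordant >
high-missing > monomorphic** (an order the original description does not
fix; totals are order-invariant and per-reason counts are reported so
either reading is comparable). When two callers are given, analysis
proceeds on merged calls: the concordant value, else the single
non-missing value, else missing — missing-in-one-workflow is explicitly
*not* discordance. Per-variant concordance rates are computed over
jointly-called genotypes. MAF uses the $2n$-chromosome denominator
(`MAF(400)` is a multiple of 1/800 for fully-called variants); the
"all samples" MAF is estimated by inverse-probability weighting with the
stratum $N/n$ weights — the original column's definition is unstated, so
this estimator is a documented stand-in.

## Two-phase design and estimators

Strata are the full 2 × 3 × 3 grid (case status × two additive index-SNP
genotypes); empty strata are retained with $N = 0$. Sampling is simple
random sampling without replacement within strata; the per-subject weight
is the stratum's $N/n$. Two allocations ship: proportional-to-$N$ within
the case and control margins (the default; equivalent to simple
case-control sampling, so weights are then nearly constant) and
`balanced_allocation()`, the classic efficient two-phase choice that
deliberately oversamples rare index-genotype strata. The published
per-stratum allocation is in an unavailable supplement, so the package
treats allocation as user-supplied with these two presets.

The original analysis names no test statistic. This package uses the
standard machinery for outcome-dependent two-phase samples:

- **weighted_marginal** — IPW logistic regression of case status on the
  additive genotype, Wald p from a robust (sandwich) variance
  $A^{-1} B A^{-1}$ with $A = X^\top W R X$, $B = X^\top W^2 (y-\hat p)^2 X$.
  For the stratification SNP itself the IPW likelihood telescopes exactly
  to the phase-1 cohort likelihood (strata are homogeneous in genotype ×
  outcome), so the weighted estimate reproduces the cohort MLE — the
  cleanest possible demonstration of why weighting matters, which the
  acceptance suite verifies against a deliberately biased unweighted fit
  under balanced allocation.
- **adjusted_conditional** — unweighted logistic regression with the
  index-SNP genotype as an additive covariate; a constant covariate
  degrades gracefully to the unadjusted fit.

Degenerate inputs are flagged, never silently dropped: zero-variance
genotypes, non-converged or separated fits (fitted probabilities within
1e-6 of the boundary or a coefficient beyond ±15), and weighted fits whose
sandwich SE collapses below a tenth of the model SE — the signature of
quasi-separation at very low minor-allele counts, where a Wald statistic
is meaningless — all return `estimable = FALSE` with a reason. LD is
reported as the Pearson correlation of allele counts (`ld_r`), the
phase-free composite measure.

## What the generator emulates — and what it does not

Defaults state the emulated world: 500 kb, 4,000 SNVs, cohort 1,763,
subsample 199 + 201, spectrum fractions 0.55 / 0.04 / 0.41 (midpoint of
the two published regional spectra, 50–60% at MAF ≤ 0.005), one planted
r = 0.99 LD pair, two index SNPs at frequency 0.30 with odds ratios
1.5/1.4, one motif-proximal risk variant with OR 1.8 at frequency 0.30,
and four planted 17-bp ERE instances. Within-bin frequencies are drawn
log-uniformly (the neutral-spectrum-like choice that keeps boundary
leakage between bins small). Baseline prevalence is 0.5 because phase 1
is itself a case-control study.

LD comes from a founder-haplotype block-copying model: variants with
target frequency > 0.01 are drawn through a per-block pool of 40 founder
haplotypes (block length 20 kb), giving tunable within-block correlation;
rarer variants are independent Bernoulli per chromosome, since rare
alleles carry essentially no pairwise LD at these sample sizes. Planted
pairs use an exact conditional-probability construction
($P(y{=}1|x{=}1) = p + r(1-p)$, $P(y{=}1|x{=}0) = p(1-r)$) that hits the
target correlation in expectation. Caller errors are heterogeneous on
purpose: a designated fraction of variants (default 8%) carries per-call
discordance (default 5%) in the second workflow and a small fraction
(default 2%) is hard to call in both — diffuse per-call noise would flag
*every* variant under the 100%-agreement rule at n = 400, which is not
what the published filter counts show.

The generator does **not** model coalescent genealogies, recombination
gradients, mutation-rate variation, population structure, genotype
uncertainty from read depth, or the matching factors of the parent trial
(age, Gail risk, time on study) — so a green test establishes that the
pipeline's arithmetic and estimators behave as specified under the stated
structure, not that they are robust to every real-data pathology.

## Known limitations

- The default ERE model is a consensus stand-in; results depend on the
  matrix supplied.
- The IPW "all samples" MAF and the weighted/adjusted model pair are
  defensible readings of an under-specified published analysis, labeled as
  such in the output (`model` column).
- The `changes` call depends on the 0.5-bit tolerance and on `alpha`;
  both are configurable and should be reported with results.
- p-values carry no multiple-testing correction, matching the published
  usage of a raw 1E-02 screen; a BH-FDR column can be added downstream.
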