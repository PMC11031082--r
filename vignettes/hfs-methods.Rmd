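---
title: "Haplotype function scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype function scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Classical association studies regress a trait on genotype dosages one
variant at a time. `hfstools` instead works at the level of 4096-bp loci: at
each locus every individual carries two haplotype sequences, each haplotype
sequence is mapped by a scorer to 39 sequence-class activities (promoter,
enhancer subtypes, transcribed regions, transcription-factor-binding
classes, polycomb and heterochromatin states), and the locus's signal is the
*haplotype function score*

HFS_i = (s(h_i1) + s(h_i2)) / 2 − s(h_ref),

the additive-model mean of the individual's two haplotype scores in the
locus's *reference sequence class* (the argmax class of the reference
haplotype), centered on the reference haplotype's score and rounded to two
decimals. The centering makes a homozygous-reference individual exactly 0;
the rounding removes scorer noise, because a variant with no real
functional-genomics impact still moves a learned scorer's output by a small
amount, and those sub-0.005 wobbles should not enter association tests.

Working on HFS rather than dosages has two consequences that drive the whole
design. First, neighboring loci are nearly uncorrelated (squared Pearson
correlation of adjacent HFS columns has a median near 0.01 in cohort-scale
data), because most linked variation does not move functional scores; this
makes per-locus fine-mapping much better conditioned than SNP fine-mapping
under linkage disequilibrium. Second, rare variants contribute on equal
footing: a singleton that disrupts a promoter moves the haplotype's score
just as a common variant does.

## Pipeline stages and their assumptions

1. **Segmentation** (`derive_active_regions`, `tile_genome`,
   `sliding_shift`). Chromatin-state BEDs from several samples per tissue
   are reduced to consensus active regions by per-base counting (a base is
   active when at least `ceil(min_fraction * n_samples)` samples of a tissue
   call it TSS/transcribed/enhancer/promoter; default `min_fraction` 0.5),
   unioned across tissues, and cleared of assembly gaps. Active regions
   shorter than 4096 bp get one locus centered on `floor((start+end)/2)`;
   longer regions are tiled with 4096-bp windows outward from the region
   midpoint, the midpoint acting as a tile boundary and only tiles
   overlapping the region being kept. The remaining genome is covered by
   non-overlapping 4096-bp gap-fill tiles. Two situations are not determined
   by the construction above and were decided here: (a) candidate loci from
   nearby active regions can overlap — candidates are processed in
   coordinate order, an overlapping candidate is shifted right to abut the
   previous locus, and dropped if it then reaches into the next active
   region; (b) complement segments shorter than 4096 bp are emitted with
   their true length and flagged `short` (the scoring step N-pads them).
   Both choices keep the final set deterministic, sorted and
   non-overlapping. The sliding-window variant shifts every locus 2048 bp
   toward the 5' end, clipping at zero.

2. **Haplotypes** (`qc_filter`, `enumerate_haplotypes`, `build_sequence`).
   Per locus, variants are kept when imputation INFO >= 0.8 (absent treated
   as passing), Hardy-Weinberg exact p >= 1e-6 (plain exact test, no mid-p,
   computed on post-missingness genotypes), minor allele count >= 10 and
   missing rate <= 10%; individuals missing more than 10% of the retained
   variants in the locus are dropped there. Haplotypes are distinct allele
   vectors over the retained variants; the all-reference haplotype is always
   index 1 even if unobserved. Missing calls that survive QC are filled with
   the reference allele (and counted); this is a modeling choice — the
   alternative of sampling from allele frequencies would make sequences
   non-deterministic. Sequences are built by splicing alternate alleles into
   the locus reference with the 5' ends anchored: a net insertion discards
   the surplus 3' bases, a net deletion appends N, so every haplotype
   sequence has exactly 4096 bases.

3. **Scoring** (`surrogate_score`, `score_sequences`, `compute_hfs`,
   `adjacent_ld`). The scorer is a contract, not a fixed engine: any
   function mapping a 4096-bp {A,C,G,T,N} string to a finite 39-vector
   deterministically can stand behind `make_scorer()`; an external
   deep-learning scorer is used through the same FASTA-in/TSV-out interface.
   The packaged surrogate scores class c as
   `plogis(sum(w_cm * count of motif m))` over a fixed manifest of four
   6-mers per class (overlapping occurrences counted), so a poly-N sequence
   scores exactly 0.5 everywhere, identical sequences give identical rows,
   and edits outside a class's motif windows cannot change that class's
   score. Weights (0.05–0.25) were set so that class scores sit on the
   responsive part of the logistic: with larger weights the argmax class
   saturates near 1 and every haplotype difference vanishes under the
   two-decimal rounding. Rounding is applied *after* centering, half away
   from zero — centering first preserves the exact 0 of homozygous-reference
   individuals, which an earlier rounding could destroy. Histone-mark
   normalization of track scores is deliberately not performed.

4. **Association** (`prepare_phenotype`, `associate`, `lambda_gc`,
   `independent_hits`). Phenotypes are adjusted once (OLS residuals;
   deviance residuals from a logistic model for binary traits, the standard
   reading of "generalized" adjustment) and rank-inverse-normal transformed
   with the Blom offset 3/8. Each HFS column is then tested by simple linear
   regression without covariates, with the Wald chi-square reported.
   Genome-wide significance stays at 5e-8 regardless of locus count, and
   inflation is summarized by `median(chisq) / qchisq(0.5, 1)`; dividing by
   the theoretical null median (0.4549) is required for the conventional
   lambda = 1 null value — a raw median of chi-squares would sit near 0.455
   under the null. Independent hits are selected greedily: take the smallest
   significant p, suppress significant loci within 200 kb of its midpoint,
   repeat.

5. **Fine-mapping** (`susie_fit`, `finemap_blocks`, `call_causal`,
   `match_controls`, `fisher_enrichment`, `tagged_variance`). The
   sum-of-single-effects regression is fitted by iterative Bayesian
   stepwise selection: L = 10 single effects, each updated against the
   residual excluding it; per-column Bayes factors under a normal effect
   prior give the inclusion weights alpha; PIP_j = 1 − prod_l(1 − alpha_lj);
   credible sets are the smallest alpha-mass sets reaching coverage 0.95,
   kept only when the minimum absolute within-set HFS correlation is at
   least 0.5. Numerical choices: columns are centered and scaled to unit
   variance internally (posterior effects are returned on the original
   scale); the default prior variance is fixed at 0.2 * var(y) per effect;
   the residual variance is re-estimated each iteration from the expected
   residual sum of squares; convergence is declared when the largest PIP
   change drops below 1e-4, with a 200-iteration cap and a warning on
   non-convergence. Per-effect prior-variance optimization (bounded 1-D
   marginal-likelihood maximization, with pruning of effects whose optimum
   is ~0) is available via `estimate_prior_variance = TRUE` but is not the
   default: pruning leaves every locus in a signal-free block tied at PIP
   exactly 0, which destroys rank-based discrimination summaries at
   moderate problem sizes, whereas the fixed-prior fit yields continuous,
   comparable PIPs — the behavior the downstream evaluation relies on.
   Causal loci are PIP > 0.95 strictly; control loci are the genomically
   nearest non-causal loci within 0.5 of the causal locus's log10 p
   (greedy, without replacement, global nearest-in-p fallback flagged);
   enrichment tables report the sample cross-product odds ratio (Haldane
   0.5 when a margin is zero) with the exact two-sided Fisher p; tagged
   variance is plain multivariate OLS R^2 with the Gaussian AIC at p + 2
   parameters.

6. **Enrichment** (`annotate_overlap`, `prune_pathways`, `link_pathway`,
   `pip_regression`, `enrichment_scan`, `filter_recurrent`). Locus
   annotations use the bedtools `-f 0.1` convention (>= 10% of the locus
   covered). Gene sets keep 6–499 genes; average-linkage clustering on
   Jaccard distance orders them, adjacent pairs sharing more than 30% of the
   smaller set lose the smaller member, and the cluster-and-scan pass is
   iterated to a fixed point so pruning is idempotent — a single pass is
   order-sensitive and can leave overlapping pairs that only become adjacent
   after removals. SNP-to-gene links need score strictly above 0.5. PIP is
   regressed by OLS on the baseline matrix plus one annotation at a time —
   PIP is bounded in [0, 1] and a logit model might seem more natural, but
   plain OLS is used so coefficients stay on the PIP scale; significance
   needs a positive coefficient and Bonferroni-adjusted p < 0.05 within the
   annotation family, and terms significant in more than half of the traits
   are removed everywhere as likely confounders. The HFS range baseline
   annotation is scaled by the *absolute* reference score (flagged when the
   reference score is ~0, where the ratio is unstable).

7. **Prediction** (`hfs_prs`, `block_scores`, `integrate_lasso`,
   `evaluate_r2`). The HFS polygenic score is the posterior-effect-weighted
   sum of HFS values, optionally restricted to loci above a PIP threshold;
   block scores partition it exactly by construction. Integration with an
   externally trained SNP PRS is an L1-penalized regression over
   [snp_prs | block scores] with the penalty chosen by seeded 5-fold
   cross-validation inside the tuning sample (predictors standardized
   internally, weights back-transformed); elastic-net mixing is exposed via
   `alpha` but 1 (LASSO) is the default. Tuning and evaluation samples must
   be disjoint; `evaluate_r2` is the squared Pearson correlation, i.e.
   simple-regression R^2. The SNP PRS itself is always an input column,
   never trained here.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_hfs` reproduces the statistical shape of cohort-scale
HFS matrices without genotypes. Per locus it builds a haplotype score pool:
pool sizes 4–16 (about what a 10,000-chromosome cohort shows per locus when
scaled down from biobank haplotype counts), frequencies drawn from
Beta(0.2, 2) and renormalized — guaranteeing a heavy tail of rare
haplotypes — and a reference score in (0.2, 0.8). Half of the loci
(`prop_functional = 0.5`, matching the observed share of loci whose
haplotypes change sequence class) carry real functional score spread
(`score_sd = 0.2`); the other half differ from the reference only at
scorer-noise level (`noise_sd = 0.002`), so after two-decimal rounding those
columns are constant and drop out of fine-mapping — exactly the role the
rounding step is designed to play. Individuals draw two haplotypes per
locus; along each block one chromosome copy reuses its previous quantile
with a coupling probability calibrated from the pools' comonotone
correlations so the median adjacent-locus R^2 lands on the target (default
0.013, within ±0.01 as verified by the test suite). All draws flow from one
seed.

`simulate_trait` plants `round(prop_causal * m)` causal loci with
standard-normal effects applied to the (unstandardized) HFS columns and adds
noise orthogonalized and rescaled so the in-sample genetic variance fraction
equals h^2 exactly. `evaluate_finemap` scores discrimination as the
rank-based probability that a causal locus outranks a non-causal one by PIP
(ties mid-ranked) and calibration as the FDR of PIP > 0.95 calls; loci
without a PIP (constant columns) are not evaluable on either side.

What the generator does **not** emulate: genuine haplotype sharing between
loci (coupling is a copula on draw quantiles, not descent), population
structure and relatedness, imputation error, locus-to-locus differences in
scorer reliability, and any correlation between a locus's allele-frequency
spectrum and its functional effect size. Passing simulation tests therefore
demonstrates the statistical machinery, not performance on real cohorts.

The study-scale defaults (n = 5,000 individuals, 5,000 loci in 50 blocks,
50 causal loci, h^2 = 0.1, 5 replicates) keep the mean per-causal-locus
non-centrality at n·h²/m_causal = 10 while fitting in minutes on one CPU;
the test suite uses smaller designs (hundreds of individuals, hundreds of
loci) for the per-operation checks. Note that matching the *mean*
non-centrality does not pin down rank-based summaries: with standard-normal
effects on unstandardized columns the per-locus non-centrality is spread
across several orders of magnitude (a chi-square(1)-distributed effect size
times a heavy-tailed column variance), so a sizable fraction of causal loci
is statistically indistinguishable from null at any evaluation scale, and
the achievable AUC is bounded well below what a homogeneous-signal design
would give. The acceptance harness (`scripts/acceptance.R`) computes and
reports the realized median AUC and FDR rather than asserting them.

## Known limitations

- Cohort-scale empirical quantities (counts of significant and causal loci
  across many traits, inflation-factor ranges, enrichment odds ratios and
  pathway p-values, cross-ancestry R^2 gains) require biobank genotypes and
  phenotypes and are not reproducible at desk scale; the property-based test
  suite stands in for them.
- The surrogate scorer is a deterministic stand-in honoring the scorer
  contract; its scores have no biological meaning beyond their locality and
  determinism, and results on real data require an external trained scorer.
- FDR at PIP > 0.95 is quantized at small call counts (7–10 calls per
  replicate at the study scale), so its per-replicate values move in steps
  of ~1/8 and the median often sits at 0.
- Coding variation is invisible to HFS by construction: a locus whose
  functional effect is purely on protein sequence scores as reference-like,
  so SNP-level analysis should be preferred in exonic regions.
- The fixed 5e-8 threshold and the 200-kb independence window are
  conventions carried over unchanged regardless of locus count.
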