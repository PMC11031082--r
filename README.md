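# hfstools

Genetic association analysis on **haplotype function scores (HFS)** instead
of genotypes. The genome is segmented into 4096-bp loci; at each locus every
individual's two phased haplotype sequences are scored into 39
sequence-class activities (promoter, enhancer subtypes, transcribed
regions, TF-binding classes, ...) by a pluggable scorer; and the locus's
signal is

```
HFS_i = (s(h_i1) + s(h_i2)) / 2 - s(h_ref)
```

— the additive mean of the two haplotypes' scores in the locus's reference
sequence class (the argmax class of the reference haplotype), centered so a
homozygous-reference individual is exactly 0 and rounded to two decimals to
wipe out scorer noise. Because most linked variation does not move
functional scores, adjacent HFS columns are nearly uncorrelated (median
R² ≈ 0.01), which makes per-locus statistical fine-mapping far better
conditioned than SNP fine-mapping under linkage disequilibrium, and rare
variants contribute on the same footing as common ones.

The package is aimed at statistical geneticists who want to run the whole
HFS workflow or any piece of it:

- **segmentation** — consensus chromatin-active regions from per-sample
  state BEDs, centered/midpoint-tiled/gap-fill 4096-bp loci, 2048-bp
  sliding-window variant (`derive_active_regions`, `tile_genome`,
  `sliding_shift`);
- **haplotypes** — per-locus variant QC (INFO ≥ 0.8, Hardy-Weinberg exact
  p ≥ 1e-6, minor allele count ≥ 10, missingness ≤ 10%), haplotype
  enumeration from a phased VCF, fixed-length sequence construction with 3'
  truncation/N-padding for indels (`qc_filter`, `enumerate_haplotypes`,
  `build_sequence`);
- **scoring** — a deterministic surrogate sequence scorer (fixed 6-mer
  motif manifest behind the same contract as an external deep-learning
  scorer), HFS assembly and adjacent-locus LD (`surrogate_score`,
  `hfs_from_vcf`, `compute_hfs`, `adjacent_ld`);
- **association** — covariate adjustment + rank inverse-normal transform,
  per-locus simple regression, genomic-control lambda, greedy independent
  hits within 200 kb (`prepare_phenotype`, `associate_all`, `lambda_gc`,
  `independent_hits`);
- **fine-mapping** — a from-scratch sum-of-single-effects (SuSiE/IBSS)
  fitter with L = 10 effects and 0.95-coverage credible sets, causal-locus
  calls at PIP > 0.95, p-matched control loci, Fisher enrichment, tagged
  variance (`susie_fit`, `finemap_blocks`, `call_causal`,
  `match_controls`, `fisher_enrichment`, `tagged_variance`);
- **enrichment** — baseline + functional annotations (bedtools-style
  overlap fractions, pathway pruning, SNP-to-gene links), OLS regression of
  PIP on annotations with Bonferroni and recurrent-term filtering
  (`annotate_overlap`, `prune_pathways`, `link_pathway`,
  `enrichment_scan`, `filter_recurrent`);
- **prediction** — posterior-effect-weighted HFS polygenic scores,
  per-block scores, LASSO integration with an external SNP PRS
  (`hfs_prs`, `block_scores`, `integrate_lasso`, `evaluate_r2`);
- **simulation** — a seeded synthetic-HFS generator (haplotype score pools
  with Beta(0.2, 2) frequency spectra, functional/noise locus mixture,
  calibrated adjacent-locus correlation), trait simulation with exact
  in-sample h², and AUC/FDR evaluation of fine-mapping
  (`generate_synthetic_hfs`, `simulate_trait`, `evaluate_finemap`,
  `run_simulation_study`), plus an end-to-end text fixture cohort
  (`generate_fixture_cohort`).

## Worked example

Simulate a small cohort-shaped HFS matrix, a trait with eight causal loci,
then associate and fine-map:

```r
library(hfstools)

gen <- generate_synthetic_hfs(n = 1000, m = 400, n_blocks = 4, seed = 42)
sim <- simulate_trait(gen$hfs, prop_causal = 0.02, h2 = 0.3, seed = 43)
y   <- drop(scale(sim$trait))

adjacent_ld(gen$hfs, gen$loci)$median
#> [1] 0.01233

assoc <- associate_all(gen$hfs, y, loci = gen$loci)
independent_hits(assoc)[, c("locus_id", "beta", "p")]
#>             locus_id      beta            p
#> 1 chr3:389120-393216 -2.733623 3.302027e-64
#> 2 chr2:389120-393216 -2.101748 3.044561e-11

fm <- finemap_blocks(gen$hfs, y, gen$block_of, L = 10)
call_causal(setNames(fm$pip, fm$locus_id))
#> [1] "chr2:389120-393216" "chr3:389120-393216"

evaluate_finemap(setNames(fm$pip, fm$locus_id), sim$truth)[c("auc", "fdr")]
#> $auc
#> [1] 0.8497326
#> $fdr
#> [1] 0
```

Reading left to right: adjacent loci are essentially uncorrelated (median
R² 0.012); two loci reach genome-wide significance (p < 5e-8), with effect
sizes per unit HFS; fine-mapping calls the same two loci causal at
PIP > 0.95 — both are planted causal loci, so the false discovery rate is 0,
and ranking all 400 loci by PIP places causal ones above non-causal ones
with probability 0.85. The remaining six planted loci carry effects too
small (or columns too close to constant) to be distinguished at this sample
size.

A thin command-line front end for the shell-shaped steps lives in
`inst/cli/hfs.R`:

```sh
Rscript inst/cli/hfs.R segment --states states/ --chrom-sizes sizes.tsv \
    --gaps gaps.bed --out loci.bed
Rscript inst/cli/hfs.R simulate --n 5000 --m 5000 --blocks 50 --seed 1 \
    --out sim_out/
```

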