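# cryptsplice

Detection and characterisation of the mutant-SF3B1-like cryptic 3'
splice-site pattern from splice-junction count data.

Hotspot mutations in the splicing factor SF3B1 — and alterations that
genocopy them, such as SUGP1 mutation with loss of heterozygosity —
corrupt branchpoint recognition and shift 3' splice-site choice to
cryptic AG acceptors, typically 10–30 nt upstream of the canonical
acceptor. `cryptsplice` is for computational biologists who want to
detect this phenotype in cohorts (tumour series or engineered cell
lines) from STAR `SJ.out.tab` junction tables and raw reads, with every
stage testable on built-in synthetic cohorts carrying known ground
truth.

## What it computes

For an aberrant junction *a* paired with its canonical partner *c*, the
**splicing index** is

    SI = N_a / (N_a + N_c)        (split-read counts; NA when both are 0)

with per-sample expression quantiles **AQ** and **CQ** (empirical CDF of
the sample's canonical-junction counts) gating which junctions are
analysable. On top of this the package provides:

* **Junction taxonomy** (`classify_junctions`): canonical /
  proximal 3'ss / proximal 5'ss / distant / aberrant-exon, with signed
  transcript-orientation distances; chimeric and doubly-noncanonical
  junctions discarded.
* **Probe-burden screen** (`build_probe_set`, `score_sample`,
  `adjust_scores`, `flag_high`): 40-mer probes centred on aberrant
  splice joints, counted in raw reads with ≤ 2 mismatches, burden
  regressed on coverage, high-residual samples flagged against an
  anchor case.
* **Phenotype call** (`pca_phenotype`): PCA of the SI matrix over
  selected junctions, samples above `median + 3·MAD` of PC1 called
  phenotype-positive; `fisher_enrichment` for genotype–phenotype 2×2
  association with Bonferroni correction.
* **Pattern-similarity protocol** (`splice_pattern_similarity`):
  per-junction Wilcoxon scans vs controls, low-p enrichment per
  aberration category, supervised PCA selection of group-associated
  junctions, hypergeometric/resampling overlap test, and SI_max-based
  classification into shared / group-specific / not-determined; plus
  `delta_si_max`, `differential_junctions`, `distance_profile` and
  `frame_fraction` for experimental designs.
* **Synthetic cohorts** (`sim_config`, `make_gene_model`,
  `simulate_cohort`, `simulate_reads`): toy genome + annotation with
  planted cryptic acceptors, negative-binomial junction counts with
  planted SI structure, junction-spanning reads — fully seeded and
  bit-reproducible.

## Worked example

```r
library(cryptsplice)

cfg <- sim_config(n_genes = 10, n_controls = 30, n_groupA = 4,
                  n_groupB = 4, n_sensitive = 10, seed = 42)
gm  <- make_gene_model(cfg)
coh <- simulate_cohort(cfg, gm)

cl  <- classify_junctions(junction_catalog(coh$sj), gm$exons)
#> junction_classification: 33 canonical, 33 aberrant (proximal3=33), 0 discarded

sim <- build_si_matrix(coh$sj, cl, coh$samples)
#> si_matrix: 38 samples x 33 junction pairs
#>   groups: control=30, groupA=4, groupB=4

pca_phenotype(sim, select_junctions(sim, 0.15, 0.1, 0.3))
#> phenotype_calls: 8/38 samples above PC1 cutoff -0.08593

splice_pattern_similarity(sim, "groupA", "groupB",
                          n_resamples = 10000, seed = 1)
#> similarity_report (proximal3): 33 junctions tested
#>   low-p enrichment: A vs ctl 0.0412, B vs ctl 0.022, A vs B 0.336
#>   selected: |A| = 8, |B| = 8, overlap 6 (hypergeom p 0.000619)
#>   shared classification: B_specific=1, not_determined=3, shared=6

distance_profile(cl$pairs)
#> distance_profile: 33 proximal-3' pairs (0 outside window); 100.0% at 10-30 nt upstream
```

Reading the output: the 8 phenotype-positive samples are exactly the 8
planted alteration samples (their PC1 scores exceed the robust cohort
cutoff); both alteration groups are enriched in low Wilcoxon p-values
versus controls while A-vs-B shows no enrichment beyond their planted
group-specific junctions; the two independently selected junction sets
overlap 6 of 8 against a 33-junction universe (hypergeometric
p ≈ 6×10⁻⁴); and all planted cryptic acceptors sit in the
characteristic 10–30 nt upstream window.

Cohort-count arithmetic works directly on printed 2×2 tables:

```r
fisher_enrichment(5, 4, 3, 11338, n_tests = 10000)
#>               altered wild_type
#> phenotype_pos       5         4
#> phenotype_neg       3     11338
#> one-sided Fisher p = 4.5e-15; Bonferroni x10000 -> 4.5e-11
```

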