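---
title: "Detecting mutant-SF3B1-like cryptic 3' splice-site patterns from junction counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mutant-SF3B1-like cryptic 3' splice-site patterns from junction counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptsplice)
```

## The biological problem

Hotspot mutations in the splicing factor SF3B1 corrupt branchpoint
recognition by the U2 snRNP. The downstream signature is highly specific:
cryptic AG acceptors, typically 10–30 nt upstream of the canonical 3'
splice site, are used instead of (or alongside) the canonical acceptor,
producing aberrant junctions that retain a short intronic stub in the
mRNA. Alterations in other factors — notably SUGP1, whose interaction
with SF3B1 the hotspot mutations disrupt — can genocopy this pattern.
`cryptsplice` implements the computational machinery to detect this
phenotype from splice-junction count data, to screen raw reads for a
known burden of aberrant junctions, and to ask whether two alteration
groups share the same set of sensitive splice sites.

Everything is exercised end to end on synthetic cohorts: the package
ships a generator that plants cryptic acceptors with known ground truth,
so each stage has a parameter-recovery test and no external data are
required.

## Junction statistics

Junctions arrive as STAR `SJ.out.tab` tables (1-based first/last
intronic base, strand code, unique-mapping split-read count). Against an
exon annotation, `classify_junctions()` labels each junction:

* **canonical** — both ends match an annotated intron of one gene;
* **proximal3 / proximal5** — one end shared with an annotated intron,
  the free acceptor/donor within 100 nt of the canonical one;
* **distant** — the free end beyond 100 nt;
* **aberrant_exon** — both ends are annotated boundaries of the same
  gene, but the junction itself is not annotated (e.g. exon skipping);
* discarded — two non-annotated ends, or ends in two different genes
  (chimeric).

Distances are signed in transcript orientation (negative = upstream), so
a cryptic acceptor 15 nt into the intron is `-15` on either strand. When
several annotated partners share the joint end, the nearest one is used;
exact distance ties (possible in principle with symmetric annotated
acceptors, absent in the synthetic annotation) break deterministically
toward the lower genomic coordinate.

For each aberrant/canonical pair and sample the **splicing index** is

$$ SI = \frac{N_\text{aberrant}}{N_\text{aberrant} + N_\text{canonical}}, $$

undefined (and later imputed as 0, "aberrant form unexpressed") when
neither junction has a split read. Because raw counts are not comparable
across sequencing depths, expression is gated through per-sample
quantiles: the quantile of a count $x$ is the fraction of the sample's
observed canonical-junction counts $\le x$ (a right-continuous empirical
CDF; ties count as $\le$). Applied to the canonical partner this gives
CQ, to the aberrant junction AQ. The eCDF definition is a package
choice — any monotone within-sample rank transform would do — and makes
CQ/AQ directly comparable across samples.

Unsupervised junction selection keeps a pair when **one** sample passes
all of `SI >= si_min`, `AQ >= aq_min`, `CQ >= cq_min` (typical screen
values 0.15/0.4/0.5; 0.1/0.2/0.5 for deeply sequenced cell-line
designs). Two optional refinements: a *ubiquity* rule (canonical partner
at CQ ≥ 0.3 in ≥ 95% of samples) that removes tissue-restricted genes in
heterogeneous cohorts, and a *control exclusion* rule for experimental
designs (drop pairs whose canonical junction is unexpressed, CQ < 0.5,
or whose aberrant junction is already well expressed, AQ > 0.4, in any
control sample). Selection is monotone: raising any threshold never adds
a junction.

## Probe-burden screening of raw reads

When only raw reads are available, a sample's burden of known aberrant
junctions is measured directly. `build_probe_set()` turns each aberrant
junction into the 40-nt mRNA-sense sequence centred on the aberrant
splice joint (20 exonic nt either side, minus-strand junctions
reverse-complemented); duplicates collapse to one probe.
`score_sample()` counts how many probes occur at least once in the reads
allowing up to 2 substitutions (Hamming distance — no indels — on both
orientations, since libraries may be unstranded). Matching uses
Biostrings' exhaustive shift-or search, so a probe truly present within
the mismatch budget is never missed; the test suite pins the scorer
against an independent sliding-window Hamming scan.

Raw burden scores grow with sequencing depth, so `adjust_scores()` fits
ordinary least squares `score ~ coverage` on the samples below the 99th
score percentile (candidate positives must not pull the trend; boundary
ties are excluded) and takes residuals for **all** samples as the
adjusted burden. `flag_high()` applies an inclusive residual cutoff,
either given directly or anchored at a named sample — the natural choice
being the weakest validated positive, which is how the screen is
calibrated when one known case is available. The coverage proxy is
configurable (read count in the synthetic runs; file size plays the same
monotone role on real data).

## Phenotype calling and enrichment

`pca_phenotype()` runs PCA on the samples × selected-junctions SI matrix
(zero-imputed, column-centred, unscaled — SI already lives on a common
[0, 1] scale). PCA signs are arbitrary, so PC1 is oriented to correlate
positively with per-sample mean SI; a sample is called phenotype-positive
when its PC1 score exceeds `median + 3 * MAD` of the cohort scores.

The MAD here carries the usual 1.4826 normal-consistency factor (the
`stats::mad()` default), making the rule a robust three-sigma cutoff.
This is a deliberate design choice: with the raw (unscaled) median
absolute deviation the cutoff sits at ≈ 2.02 σ for approximately normal
scores, which would flag ≥ 2% of unaffected samples by construction —
incompatible with a screen meant to isolate a rare phenotype. The
unscaled variant remains available via `mad_constant = 1`. A constant
matrix (or zero MAD) is degenerate: a warning, no calls.

Calibration of the screen is a property of the whole pipeline, not of
the PCA alone. In a null cohort (no planted effect) the SI/AQ expression
gates select no junction at all, so the screen makes no call; forcing a
PCA on all unselected junctions of a null cohort instead produces heavy
tails (low-count junctions and coverage heterogeneity make PC1 scores a
scale mixture), which is precisely the noise the gates exist to remove.
The validation therefore measures the control false-positive rate in a
study-scale cohort (400 controls + 11 alteration samples, ~20 selected
junctions) where it is well below 1%, and checks that null cohorts pass
through silently.

`fisher_enrichment()` tests genotype–phenotype association on a 2×2
table with a one-sided (enrichment) Fisher's exact test and a Bonferroni
factor. Two constructions of the table are possible (phenotype-positive
wild-type cases only, or all phenotype-positives); both are supported by
supplying the counts, and the multiple-testing factor is the caller's
gene-set size — the validation uses 10,000 as a conservative upper bound
on any plausible RNA-processing gene set.

## The splice-pattern similarity protocol

To ask whether two small alteration groups (here 5–6 samples each)
share a splice-aberration pattern against hundreds of controls, the
package applies, per aberration category:

1. **Per-junction Wilcoxon rank-sum tests** of SI, group vs control
   (missing SI read as 0). The exact null distribution is used when the
   smaller group has ≤ 10 samples and the data are tie-free; otherwise
   the normal approximation with tie correction. Candidates are
   junctions at p < 0.05, deliberately uncorrected — the next stages do
   the filtering.
2. **Low-p enrichment**: the observed below/above-0.05 split of all
   p-values is compared with the uniform-null split by a one-sided
   Fisher test; only categories that react at all proceed sensibly.
3. **Supervised PCA**: PCA of the centred candidate SI over group +
   control samples; components with > 5% explained variance are
   examined, and a component counts as *group-associated* when its
   scores rank-separate the group from the controls. "Separates" is
   undefined in words alone; the package requires complete rank
   separation (AUC = 1) by default — with 5-sample groups anything
   weaker is too easy to achieve by chance — and exposes the AUC
   threshold. Junctions with |Pearson r| > 0.2 to an associated PC's
   scores, or |loading| > 0.05, are selected as group-specific.
4. **Overlap test**: the two selected sets are compared against random
   draws from the tested-junction universe. Under that null the overlap
   count is exactly hypergeometric, so the Monte-Carlo draws overlap
   counts directly (`rhyper`) — equivalent to materialising random set
   pairs, orders of magnitude faster — and reports the closed-form tail
   alongside the add-one empirical estimate
   $(1 + \#\{ \ge \text{obs}\}) / (R + 1)$.
5. **SI_max classification** of the union of selected junctions:
   *shared* when each group's maximal SI exceeds the control 95%
   quantile; *definitively group-specific* when one group's maximum
   exceeds Q95 while the other's falls below Q75; *not determined*
   otherwise (and excluded from shared-fraction summaries). Quantiles
   are linear-interpolation sample quantiles over ≥ 20 control samples.

The maximum of a handful of samples is a deliberately liberal statistic
(the "best reacting" sample), which makes the *shared* call sensitive
but the *specific* call conservative: for a junction elevated only in
group A, group B's SI maximum over $n$ samples falls below the control
75% quantile with probability at most $0.75^n$ (≈ 0.24 at $n = 5$),
whatever the background distribution. Most truly specific junctions
therefore land in *not determined* — which is why that class exists and
is excluded rather than counted as disagreement. Parameter-recovery runs
show essentially perfect recovery of planted shared junctions and the
expected ~20–25% definitive-specific yield, with the remainder
undetermined rather than misclassified.

For experimental two-condition designs the package adds
`delta_si_max()` — the relative shift of the maximal SI,
$(\max SI_{exp} - \max SI_{ctl}) / \max SI_{ctl}$, undefined when the
control maximum is 0 — and `differential_junctions()`, a per-junction
Welch t-test on replicate SI combined with an
$|\log_2(\text{mean ratio})| \ge 1$ effect filter (raw-p or
Benjamini–Hochberg selection). The location test is a package choice:
the original workflow delegated to an external event caller, and the
reproduced contract is the FDR/fold-change filter, not that tool's
internals. `distance_profile()` and `frame_fraction()` summarise the
cryptic-acceptor geometry: the signed-distance histogram around the
canonical acceptor, the fraction in the characteristic [−30, −10]
window, and the out-of-frame fraction (|distance| not divisible by 3;
2/3 expected under uniform offsets — a deficit suggests
nonsense-mediated decay removes out-of-frame products).

## The synthetic cohort generator

`sim_config()` + `make_gene_model()` + `simulate_cohort()` +
`simulate_reads()` produce a toy genome, annotation, per-sample junction
tables and reads with known ground truth. Design choices:

* **Gene model**: multi-exon genes on both strands of one synthetic
  chromosome; every canonical junction receives GT/AG splice
  dinucleotides and a planted cryptic AG at an offset drawn uniformly
  from 10–30 nt upstream of the canonical acceptor (the empirical mode
  of the phenotype), respecting strand orientation.
* **Counts**: per-junction totals are negative binomial (log-normal
  baseline expression × per-sample coverage multiplier drawn from
  0.5–2×, dispersion 0.15 — standard RNA-seq overdispersion), split
  between canonical and cryptic junction by binomial thinning so the
  expected SI is exactly the planted value: 0.3 at sensitive junctions
  in their elevated group(s), 0.01 elsewhere. No generative model is
  prescribed by the phenotype itself; NB + thinning is the simplest
  model with the right mean structure and overdispersion.
* **Cohort shape** (defaults): 400 controls, 6 + 5 alteration samples,
  90 sensitive junctions of which 50 are shared and 20 specific to each
  group — the study-scale configuration used throughout the validation.
* **Reads**: each junction with $k$ split reads contributes exactly $k$
  junction-spanning reads (flanks concatenated, mRNA sense) plus
  optional uniform background reads and an optional per-base
  substitution error rate. Conservation (reads = counts at error 0)
  makes the burden screen testable against ground truth.
* **Determinism**: one config seed drives all stages through derived
  sub-seeds; identical seeds give bit-identical FASTA/FASTQ/SJ outputs.

What the generator does **not** emulate: transcript isoform structure,
positional/GC coverage bias, sequencing-machine error profiles, indels,
multi-mapping ambiguity, intron retention (excluded from the analysis
scope altogether), or correlated expression between genes. Passing
parameter-recovery tests therefore demonstrates the statistical
machinery is correct under the stated model, not that real-data
preprocessing (alignment, duplicate handling) is solved.

## Numerical and validation notes

* Problem sizes in the shipped validation were chosen to exercise the
  study-scale cohort (411 samples, ~150 junction pairs) while keeping
  the whole suite around half a minute: calibration runs use 2,000 null
  junctions for the Wilcoxon KS check and 500 null replicates for the
  enrichment test; read-level screens run on a 13-sample cohort.
* `wilcox.test`'s exact path is used only for tie-free data; planted
  cohorts contain heavy zero-ties, where the corrected normal
  approximation applies.
* The top-percentile exclusion in `adjust_scores()` uses the strict
  `<` comparison against the type-7 99th percentile, so boundary ties
  are excluded from the fit; with fewer than 3 samples remaining the
  fit falls back to all samples.
* `overlap_test()` validity does not depend on the resample count; the
  hypergeometric tail is exact and the empirical estimate is floored at
  $1/(R+1)$.
* Degenerate inputs are first-class: constant SI matrices warn and call
  nobody; empty candidate sets return empty results rather than errors;
  `SI` and `delta_si_max` guard their zero denominators with NA.

## Known limitations

* The probe scorer is exhaustive per probe × read; it is meant for
  cohort-scale validation and targeted screens, not for a disk-backed
  index over thousands of BAM-scale samples.
* The specific/shared classification inherits the conservatism of the
  SI_max rule discussed above; consumers should treat *not determined*
  as "insufficient evidence", never as "not shared".
* With alteration groups larger than ~10 samples the complete-separation
  (AUC = 1) default becomes overly strict; lower `auc_min` accordingly.
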