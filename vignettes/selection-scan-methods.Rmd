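---
title: "Models and methods behind evoselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evoselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoselect)
```

## The experimental design the package models

`evoselect` analyses multigenerational insecticide-selection experiments on
mosquito lines: a field-derived founder colony carrying resistance alleles at
moderate frequency is split into three lines — one kept unselected as a
control and two selected every generation with a different insecticide, at
exposure doses adjusted so that each round kills 50–70% of the exposed adult
females. Resistance is monitored by bottle bioassays and by individual
genotyping of a major-effect target-site locus (a knockdown-resistance type
mutation in the voltage-gated sodium channel). After a number of generations,
four replicate pools of 30 adult females per line are RNA-sequenced, giving
both gene-level read counts and, within sufficiently expressed transcripts,
pooled allele counts at polymorphic sites.

The pipeline answers two questions per selected line, each contrasted
against the unselected control:

1. **Which genes changed transcription?** (metabolic/cuticular resistance)
2. **Which polymorphic loci shifted in allele frequency more than drift
   allows?** (selection signatures)

## Monitoring statistics

Mortality proportions carry Wald 95% intervals
$p \pm 1.96\sqrt{p(1-p)/n}$, clipped to $[0,1]$; at $p = 0$ or $1$ the
interval degenerates to a point, as the Wald formula does. Pairs of
mortality proportions are compared with a two-sided Fisher exact test,
defined as the total hypergeometric probability of tables no more likely
than the observed one (the conventional two-sided definition, with the same
$1+10^{-7}$ relative tie-guard `stats::fisher.test` uses; the implementation
is a vectorized `dhyper` evaluation and is checked against both
`fisher.test` and exhaustive enumeration). Genotype distributions at the
monitored locus are compared by plain Pearson Chi-squared on the 2×3
genotype table, without continuity correction; genotype classes empty in
both samples are dropped first, so the degrees of freedom equal the number
of informative classes minus one. The comparison operates on genotype
counts, not allele counts — with 30 individuals per time point, both are
defensible; the genotype-level table is the more conservative 2-df version.

## Differential transcription

Counts are normalized with the median-of-ratios estimator: for sample $j$,
$s_j = \mathrm{median}_{g} \, (k_{gj} / (\prod_j k_{gj})^{1/n})$ over genes
positive in every sample, returned without re-centering. Genes must reach
**4 reads per kb in every sample** (inclusive) to be tested; this mirrors
the detection filter used with pooled RNA-seq, and the synthetic generator
draws gene baselines log-uniform over four orders of magnitude precisely so
a realistic fraction of genes fails it.

Each retained gene is tested with a one-way ANOVA across the three lines on
$\log_2(\text{normalized count} + 1)$, followed by a Tukey HSD contrast of
each selected line against the control (studentized-range distribution with
the pooled within-group df), and Benjamini–Hochberg correction applied per
contrast across genes. The log scale is the package's choice — the ratio
thresholds used downstream imply a multiplicative error model and the +1
offset keeps zero counts finite; fold-changes themselves are computed on
the normalized, non-log group means, with $FC > 1$ meaning
over-transcription in the selected line. A gene is called when
$FC \ge 1.5$ in either direction **and** adjusted $p \le 0.005$, both
bounds inclusive. A companion figure-level threshold of adjusted
$p < 0.001$ exists in some reports of this design; both are exposed as
arguments (`call_de(de, fc_threshold, p_threshold)`) and the Methods-level
0.005 is the default — the discrepancy is surfaced, not resolved silently.

BH is applied per contrast rather than pooled across contrasts: the
per-line DE counts this style of analysis reports imply per-contrast
families, and the per-contrast family is the more conservative reading.
Term enrichment of called gene sets is a one-sided Fisher exact
(hypergeometric upper tail) against the universe of all detected genes,
with terms hit by fewer than 5 list genes suppressed and enrichment
declared at $p < 0.05$ (strict). The candidate panel restricts calls to the
gene families recurrently implicated in insecticide resistance (P450s,
esterases, transferases, ABC transporters, cuticle proteins, redox enzymes,
nervous receptors), reported as per-line log2 fold-changes.

## Polymorphism scans

Variant records carry the caller's annotations (mean base quality,
confidence score, strand-bias score, homopolymer run length) as opaque
scores on the caller's own scale, and are kept only if: homopolymer run
≤ 4 (longer runs and their adjacent positions are annotated with the run
length and rejected), per-sample total depth within [30, 5000] — evaluated
in **every** sample, the stricter, replication-preserving reading — variant
support ≥ 2 reads, base quality ≥ 20, confidence ≥ 200, strand bias ≤ 25,
and type substitution or indel. The rules are conjunctive, so the retained
set does not depend on application order; per-rule rejection counts are
reported.

The polymorphism screen keeps biallelic records whose line-mean frequency
differs from the control by ≥ 5% in at least one selected line (line means
over replicate pools, not any-replicate differences — the line-mean reading
matches the frequency estimator used by the tests downstream).

**Differential SNPs.** Per locus and contrast, the per-pool alternate-allele
frequencies (4 selected vs 4 control pools) are compared with a two-sided
pooled-variance Student t ($df = n_1+n_2-2$; Welch available as a switch),
BH-corrected across loci per contrast. A locus is differential when the
mean shift is ≥ 50% in either direction and adjusted $p \le 0.001$. With
exactly zero within-group variance the limiting p-value is used: 0 when the
means differ, 1 when they do not — the limit of the t statistic, applied
because pooled frequencies can be identical across replicates at deep
coverage.

**Bayesian F~ST~ outliers.** The second approach re-implements the Bayesian
differentiation model familiar from F~ST~ outlier scans. Allele counts
$a_{ij}$ of $n_{ij}$ reads in population $j$ at locus $i$ are
beta-binomial around an ancestral frequency $p_i$:
$$a_{ij} \sim \mathrm{BetaBin}(n_{ij},\ \theta_{ij} p_i,\ \theta_{ij}(1-p_i)),
\qquad \theta_{ij} = \frac{1-F_{ij}}{F_{ij}},\qquad
\mathrm{logit}\, F_{ij} = \alpha_i \delta_i + \beta_j,$$
with locus effects $\alpha_i$ (selection) switched in and out of the model
by a reversible-jump move with prior odds for neutrality `prior_odds`
(default 1000, the stringent setting), population effects
$\beta_j \sim N(-1, 1.8^2)$, $\alpha_i \sim N(0,1)$ when included, and
uniform ancestral frequencies. Each replicate pool is one population
(8 populations per contrast); a 2-population summed-counts alternative is
available through `contrast_allele_counts()`. Read counts are used directly
as allele counts, as pooled RNA-seq analyses effectively do; an optional
effective-pool-size downscaling to `2 * pool_size` chromosomes is provided
because read depth can exceed the chromosome count in the pool.

The posterior probability of selection is the inclusion frequency of
$\alpha_i$ over retained samples; the q-value of a locus is the mean of
$(1-\text{posterior probability})$ over all loci at least as extreme, and a
locus is an outlier when its q-value is below `1/retained` — the
finite-sample reading of "q-value equal to zero". The sampler is written in
C++ (Rcpp), uses R's RNG so a seed fixes the chain exactly, adapts proposal
scales during burn-in, and reports acceptance rates; rates outside
[0.1, 0.6] after adaptation raise a warning (the reversible-jump rate is
excluded — it is legitimately near zero when most loci are neutral under
high prior odds). Defaults are burn-in 1000, 2000 retained samples,
thinning 5.

**Gene-level scan.** Each tested SNP is assigned to at most one gene — the
gene with the nearest span boundary among genes whose 1500 bp windows cover
it, ties to the leftmost gene — consistently with effect annotation
(precedence coding > UTR > splice > intronic > near-gene (100 bp) >
upstream/downstream (1500 bp) > intergenic; essential splice sites are the
first/last 2 bp of an intron and splice sites lie within 8 bp of an
exon–intron boundary; where the near-gene and upstream/downstream windows
overlap, near-gene wins). Coding substitutions are classified by codon
substitution under the standard genetic code, strand-aware; CDS indels with
length change not divisible by 3 are frameshifts, in-frame indels are
reported as non-synonymous. Per gene, the proportions of differential and
outlier SNPs among its polymorphic SNPs are plotted at the gene center,
mirrored on two axes; proportions strictly above 20% receive the high
flag. A dual-evidence gene carries at least one SNP of each kind in the
same contrast — same gene, not necessarily the same SNP.

## The synthetic-experiment generator

The generator emits everything the pipeline consumes (counts TSV, VCF 4.2
with AD depths and the quality annotations as INFO keys, GFF3 gene models
with a family attribute, chromosome FASTA, genotype and bioassay TSVs) plus
a truth ledger, under one master seed; every sub-step derives its own seed
from labels (module, line, replicate), so adding replicates never perturbs
earlier draws, and identical configurations give byte-identical bundles.

Defaults mirror the experimental regime described above: 3 lines × 4 pools
× 30 females, 17 generations, census of 300 breeding females per
generation, founder target-site frequency 0.47, exposure calibrated each
generation to the 50–70% mortality window.

*Selection model.* Genotype viabilities are $(1+s,\ 1+hs,\ 1)$ for RR/RS/SS.
At the target-site locus the full census cycle is simulated: Hardy–Weinberg
genotype counts, exposure intensity $c$ solved so expected mortality hits
the window centre with survival $\min(1, c\,w_g)$ per genotype, binomial
survival redrawn (the experimenter adjusts the dose) until realized
mortality falls inside the window, then binomial gamete sampling from the
survivors. The defaults $s = 8$, $h = 0.6$ were chosen so that the
deterministic sweep from 0.47 passes 0.9 by generation 7 and approaches
fixation by G9 — the dynamic observed for target-site sweeps of this kind.
Weaker parameterizations with high dominance cannot reproduce that pattern:
the late-phase per-generation odds growth is bounded by $(1+s)/(1+hs) <
1/h$, so with $h = 0.8$ no selection coefficient reaches near-fixation that
fast. Other planted loci evolve under standard Wright–Fisher viability
selection ($s \sim U(0.8, 1.5)$, $h = 0.8$, founder frequency
$U(0.15, 0.35)$, one locus per host gene, disjoint between the two selected
lines); all remaining loci drift.

*Expression.* Counts are negative-binomial with gene baselines log-uniform
over $[1, 10^4]$, library factors $U(0.7, 1.3)$, and dispersion 0.005
between replicate pools (a 5% CV — pools of 30 females average out most
individual variation; the value is calibrated so that planted 2-fold
changes are recoverable at the pipeline's thresholds while 1.2-fold changes
are not, the bracketing property the recovery tests assert). Planted
fold-changes are log-uniform in 1.5–4× by default and live in genes with
baseline ≥ 150 — planted effects are placed where they are measurable,
since transcriptional resistance signals are by definition observed in
quantifiable transcripts.

*Pooled allele counts.* Pools are drawn without replacement from the census
(hypergeometric chromosome sampling); read depth at a locus is Poisson with
mean proportional to its host gene's expression in that sample, scaled so a
median-expression gene yields `mean_depth` (default 60); intergenic loci
get a fixed floor (default 40). Alternate reads are binomial in the pool
frequency. The target-site locus is deliberately hosted in a weakly
expressed gene (baseline ≤ 3), so it never reaches callable coverage: its
sweep is visible to the genotyping table but invisible to the RNA-seq
polymorphism scan, the behaviour expected for a sodium-channel gene in
whole adult females. Hosts of the other planted loci are bounded to
baselines in [150, 3000] so their depth stays inside the [30, 5000]
coverage window, and the random fraction of filter-failing quality
annotations (default 5% of records) is assigned to non-focal records only —
corruption models caller artifacts at arbitrary sites, and planting it on
the known truth loci would delete the signal by construction rather than
test the scan.

*What the generator does not emulate.* No linkage or haplotype structure
(loci are independent, so the scan's per-gene aggregation is tested without
hitchhiking); no read-level errors or mapping artifacts beyond the
annotation fields; no batch effects or GC/length biases in expression; no
dose–response curve (exposures are discriminating doses, as in the
monitoring design); genotype frequencies always at Hardy–Weinberg within a
generation. Passing the recovery tests therefore shows the statistics
behave correctly under the stated sampling models, not that they are robust
to artifacts the generator does not produce.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally, matching GFF3,
  VCF and the GenomicRanges containers used for all window arithmetic, so
  no re-basing occurs anywhere.
* Zero-variance groups: ANOVA with identical values gives $F = 0$, $p = 1$;
  a zero within-group variance with distinct means gives $p = 0$ (limits of
  the statistics). Same convention for the pooled t.
* Fold-changes with a zero control mean are `Inf` (called if the p-bound
  passes) and 1 when both group means are zero.
* A locus with zero depth in a sample has a missing frequency; line means
  average the non-missing pools, and loci with fewer than two usable pools
  on either side of a contrast are excluded from the t-test and counted.
* Allele frequencies at absorbing boundaries (0/1) are handled exactly in
  the Wright–Fisher kernel and by the beta-binomial likelihood's limit.
* `q`-value ties share the value at the last tied rank, keeping q
  non-decreasing in $1 - $ posterior probability.

## Problem sizes used by the shipped tests

The acceptance checks run the full pipeline at sizes chosen for a
single-CPU workstation: null calibration on drift-only experiments of
2000 genes × 10000 SNPs over 3 seeds, planted-signal recovery at the same
scale over 3 seeds, with the Bayesian stage run with reduced MCMC settings
(burn-in 400, 2000 retained samples, thinning 1) on seeded subsamples of at
most 1000–2000 polymorphic loci per contrast; the `scripts/acceptance.R`
entry point uses 1200 genes × 5000 SNPs, with 25 planted selected loci per
line so the recovery rates it reports rest on enough loci. Oracle-equivalence checks are
exhaustive where stated (all 2×2 tables with margins ≤ 30 for the Fisher
test; all two-population tables with totals ≤ 12 for the F~ST~ estimator).
Larger runs only sharpen the same estimates.

## Known limitations

* The Bayesian outlier model assumes an island-type exchangeable population
  structure; replicate pools from two diverged lines violate it mildly.
  The high prior odds (1000) keep the null outlier rate far below 1% in the
  package's own calibration runs, but hierarchical structure is the known
  failure mode of this model class on real data.
* The differential-SNP t-test has only 6 degrees of freedom with 4+4 pools;
  loci with true shifts just above 0.5–0.6 sit near the adjusted-p boundary
  and a minority of them will always be missed.
* Effect annotation assigns each SNP to one gene; overlapping genes on
  opposite strands (common in compact genomes) lose one of the two
  annotations.
* The simulator's bioassay mortality floor is set by the calibrated dose
  and the viability ratio, so fully resistant lines retain ~30% mortality
  at the G0 dose rather than dropping to zero; monitoring comparisons are
  still strongly significant, but absolute late-generation mortalities are
  less extreme than in a real selection experiment.
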