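---
title: "Copy-number-aware analysis of imprinted DMR methylation"
author: "imprintCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number-aware analysis of imprinted DMR methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintCNA)
```

## The model

Imprinted differentially methylated regions (DMRs) are methylated on
exactly one parental allele in the germline, so a normal diploid cell
shows an average β of about 0.5 at every imprinted DMR. Cancer genomes
break this picture in two independent ways: copy-number aberrations
(CNAs) change the *ratio* of methylated to unmethylated alleles, and
epimutations change the methylation of the alleles themselves. The core
of this package is the allele-counting model that separates them.

For a locus with total copy number $t$ and minor-allele copy number $m$
(the smaller parental count, $m \le t - m$), the *minor methylation
value* is $m/t$. If the observed β lies below 0.5 the methylated allele
is taken to be the minor one and the CNA-predicted methylation is $m/t$;
above 0.5 the methylated allele is the major one and the prediction is
$1 - m/t$. The two branches are the only methylation values consistent
with the copy state, and the observed value selects the parental
configuration — a provable equivalence with choosing the branch nearest
to the observed value (the test suite verifies this by exhaustive
enumeration over $t = 1..14$, all valid $m$, and an observed grid of
0.01).

Consequences worth spelling out:

* a normal 2:1 locus predicts 0.5 whatever the observed branch;
* a 4:1 locus predicts 0.75 or 0.25 depending on parental origin;
* copy-neutral LOH (cnnLOH, $t \ge 2$, $m = 0$) predicts exactly 0 or 1
  irrespective of the total;
* homozygous deletion ($t = 0$) admits no prediction: such loci are
  flagged not-evaluable and excluded from epimutation frequencies.

A sample is called **CNA-independent** (a genuine epimutation) when
$|\text{observed} - \text{predicted}| > 3\,\sigma_c$, where $\sigma_c$
is the per-region standard deviation (n − 1 denominator) of the DMR
averages across normal-tissue controls. The band is centred on the
per-sample predicted value: the observed-vs-expected scatter plots the
prediction on the x axis and the band runs parallel to the identity
line. All threshold comparisons at 0.8/0.2, ±0.2 and 3 s.d. are strict
inequalities, matching their verbal definitions ("above", "below",
"outside"); a deviation of exactly 3 s.d. is not called.

State classification (hypermethylated β > 0.8, hypomethylated β < 0.2,
intermediate gain/loss at ±0.2 relative to the control mean, else
normal) deliberately compares against the *diploid control mean*, not
the CNA-predicted value: the state describes the absolute methylation
profile, while CNA awareness lives entirely in the independence call.
This means a cnnLOH locus legitimately classifies as hyper- or
hypomethylated without being CNA-independent — that is the central
distinction the package exists to make.

At cnnLOH loci only one parental allele survives, so methylation reveals
which: observed β > 0.8 at a maternally methylated DMR means the
maternal allele was retained, β < 0.2 means the paternal one; anything
between is ambiguous. The 0.8/0.2 bands are reused here for internal
consistency (no separate thresholds are defined for this inference).

## Copy-state assignment and CNA geometry

Segments enter as SEG-like tables (1-based inclusive on disk, converted
to 0-based half-open internally; BED region files are read natively).
A segment is eligible for a region when it overlaps by at least 1 bp;
when several overlap, the largest overlap supplies the copy state, ties
broken toward the larger total copy number — the simplest deterministic
rule for split DMRs. Regions with no covering segment default to an
*assumed* 2:1 state (flag preserved) rather than going missing, which
keeps the observed-vs-expected table complete.

Baseline ploidy is the length-weighted median of the total copy number
across a sample's segments, rounded half-up with a floor of 1. The
median resists focal amplification outliers; the per-locus
`ploidy_ratio` (total copies / baseline) is reported alongside the
diploid-relative aberration call because a total of 3 is a gain in a
diploid genome but a loss in a tetraploid one.

A CNA is *internal* when it lies strictly more than 1 Mb from the nearer
of the telomere and the centromere (a segment overlapping the centromere
has distance 0); exactly 1 Mb is bound, and a telomere/centromere tie
goes to the telomere. Size summaries average over segments (not over
samples), which is stated in the output metadata.

## Probe QC and RRBS aggregation

Probe filtering applies four rules in a fixed order, attributing each
probe to the first rule that removes it so counts always reconcile:
detection p > 0.01 in strictly more than 10% of the samples (applied to
the matrix as given — the threshold is not re-computed after cohort
subsetting); any missing β; a common SNP (MAF ≥ 1%) within 5 bp of the
interrogated CpG; chrX/chrY. The filter is idempotent.

RRBS site methylation is methylated reads over total reads; sites under
10 reads are dropped and the region value is the unweighted mean of the
surviving sites (a site belongs to a region when start ≤ pos < end). With
the coverage floor at 0 this reduces to the plain mean of site
fractions, which the tests use as a closed-form check.

## Context burden (CIMP, bivalent domains, DMVs)

Only regions uniformly unmethylated in normals (control mean < 0.2) are
analysable for hypermethylation. Severity is highly (> 0.75), mildly
(> 0.5) or lowly (≥ control mean + 0.2; the boundary is inclusive, a
documented choice since "reaching" the offset is the natural reading).
The per-sample burden score is 3·highly + 2·mildly + 1·lowly — an
explicit convention standing in for ranking "by severity and number of
affected loci"; the weights are configurable arguments with this
default. Correlations between burden vectors use Pearson when both pass
Shapiro–Wilk normality at α = 0.05 and Spearman otherwise.

## The simulator: what it emulates and what it does not

`sim_config()`/`simulate_cohort()` generate allele-resolved cohorts with
complete ground truth. The generative model:

* **Normals** are 2:1 everywhere. Each (normal, region) pair receives an
  inter-individual biological offset (s.d. `biovar_sd`, default 0.01 β at
  the region scale) plus per-probe measurement noise (`noise_sd`,
  default 0.02). The control band exists precisely to absorb inter-donor
  variation, so controls carry it; tumor deviations from the CNA
  prediction are modelled as measurement noise plus injected
  epimutations only (a clonal cell-line picture).
* **Tumor copy states**: each (tumor, DMR) pair is aberrant with
  probability `cna_rate` (default 0.1 — a primary-tumor-like landscape
  where most imprinted loci are copy-normal). Aberrations are cnnLOH
  with probability `cnnloh_rate` (0.1; totals concentrated at 2 with a
  tail to 14), single-copy deletions with probability `del_rate` of the
  remainder (0.15), otherwise amplifications with totals massed at 3–4
  and a geometric tail to `max_total_cn` = 14. Non-LOH aberrations
  retain both parental alleles (minor ≥ 1): in this model a lost parent
  *is* the LOH event class. The parental origin of the minor allele is
  uniform, so both the 75:25 and 25:75 branches occur.
* **Epimutations** rewrite per-copy states with probability
  `epimutation_rate` (default 0.1): hyper methylates all copies, hypo
  unmethylates all, intermediate flips exactly one randomly chosen copy
  (shifting β by 1/t). Labels are recorded in the truth table even when
  the rewrite is a no-op.
* **Purity**: measured tumor β is purity-mixed with the normal value
  (0.5 at DMRs) before probe noise. Default purity is 1 (cell lines);
  primary-tumor settings use e.g. mean 0.72, s.d. 0.2.
* **Context regions** never receive CNAs; each tumor has a latent
  hypermethylation propensity u ~ Uniform(0,1) and every CIMP/bivalent/
  DMV region hypermethylates with probability u to a level
  Uniform(0.3, 0.95). This single shared factor produces the tightly
  correlated CIMP/bivalent/DMV burdens, while imprinted epimutations are
  drawn independently of u — so the imprinted-vs-CIMP burden correlation
  is near zero by construction.
* **RRBS** counts: per-site coverage ~ Poisson(`rrbs_mean_coverage`),
  zero-coverage sites dropped, methylated reads ~ Binomial(coverage,
  site methylation).
* **Determinism**: every (sample, region) pair derives its own RNG
  stream from the master seed, so adding samples never perturbs existing
  ones and the same seed is bit-reproducible.

What the simulator does *not* model: read-level bisulphite chemistry,
subclonal copy-number evolution, probe-specific biases and
heteroscedastic array noise, genuinely biological tumor-side variation
within the control band, or correlated multi-locus CNAs (each DMR draws
its segment independently, clipped so segments never intrude into
neighbouring regions). Passing tests therefore demonstrate that the
pipeline's logic is correct under its own model assumptions, not that
real cohorts will show the same sensitivity.

## Calibration experiments and design choices

The test suite runs the pipeline end to end at stated sizes (chosen to
keep the full suite around a minute): a noise-free round trip at 200
tumors × 37 DMRs must yield zero CNA-independent calls, normal states at
every copy-normal locus, R² = 1 wherever the copy state varies, and
100% correct cnnLOH parent recovery. Note that with CNAs present, states
at cnnLOH loci are *definitionally* hyper/hypomethylated, so the
"everything normal" identity is asserted over copy-normal loci.

Epimutation parameter recovery (500 tumors, 10 normals, rate 0.10,
noise 0.02) is run on a copy-normal background (`cna_rate = 0`). This
isolates detector calibration from a separate, information-theoretic
limit: at a minor-zero locus the CNA-consistent predictions are exactly
{0, 1}, so a full hyper or hypo epimutation lands *on* a consistent
profile and no method using only (β, copy state) can see it — the same
ambiguity that makes cnnLOH-with-retained-methylated-allele
indistinguishable from cnnLOH-plus-hypermethylation. That limit is a
property of the problem, documented here, not a detector defect, and the
recovery experiment measures the detector.

Purity attenuation is checked on one fixed cohort re-rendered across a
purity grid 1.0…0.5 (identical RNG streams, only the mixing weight
changes): the mean |observed − predicted| at epimutated loci decreases
monotonically as dilution pulls observations toward the diploid 0.5.

Numerical choices: the strict 3 s.d. comparison carries an absolute
fuzz of 1e-12 so that floating-point ulp noise cannot create calls when
the control s.d. is zero; an observed β of exactly 0.5 breaks the
prediction tie toward 1 − m/t (it matters only on exact ties, which are
counted and reported); R² is computed directly from residual and total
sums of squares to behave cleanly on numerically perfect fits; region
averages require at least two mapped probes.

Two cohort-level summaries are emitted side by side because "percent of
imprinted DMRs with CNA-independent changes" admits both readings:
independent calls over evaluable (sample, DMR) pairs, and the per-sample
fraction of affected DMRs averaged over samples. On balanced data they
coincide.

## Known limitations

* The branch choice uses the observed β, so predictions are not
  independent of the data they are compared against; at minor-zero loci
  this absorbs full epimutations entirely (see above).
* Control s.d. is estimated per region from few normals; with very small
  control sets the 3 s.d. band is itself noisy. No variance shrinkage
  across regions is applied, keeping the band exactly as defined.
* Split DMRs take the copy state of the largest-overlap segment rather
  than an average; the fraction of split loci is visible in the state
  table (`assumed`/`seg_length` columns).
* Aberration calls are diploid-relative; consult `ploidy_ratio` for
  hyperploid samples.
```{r session}
sessionInfo()
```
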