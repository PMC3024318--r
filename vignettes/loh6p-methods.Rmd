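---
title: "Methods: case-control association and allelic-imbalance screening on 6p"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control association and allelic-imbalance screening on 6p}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nasopharyngeal carcinoma (NPC) risk concentrates on chromosome 6p, and small
germline or somatic deletions there can silence candidate genes without being
visible to assays designed for allelic discrimination.  This package
re-implements, as a tested pipeline, a case-control analysis strategy for a
tag-SNP panel on 6p: single-SNP and haplotype association to localise risk,
a homozygosity-ratio statistic to flag allelic imbalance, runs-of-homozygosity
(ROH) screening to rule out extended autozygosity as a confounder, and
2^-ddCt qPCR follow-up of candidate genes in paired tumor/normal tissue.

The individual-level genotypes of the motivating cohort were never deposited,
so the package ships a synthetic-data generator that emulates the study
design (360 cases, 360 controls, 233 biallelic tag SNPs spanning
6,095,364-30,048,467 bp) and a 19-row transcription of the published
frequent-LOH summary table as a packaged worked example.

## Data model

A `genotype_panel` holds position-sorted SNP metadata and a sample-by-SNP
matrix of genotype codes counting copies of `allele_a` (2 = hom_a, 1 = het,
0 = hom_b, `NA` = missing).  After parsing PLINK-text PED/MAP input,
`allele_a` is re-labelled to the minor allele among controls so that odds
ratios have a deterministic direction regardless of file coding; ties fall
back to the whole cohort and then to first-observed order.  Positions are
1-based and intervals closed, as in MAP files.  Sex and phenotype use the
PLINK 1/2 encodings; unknown codes are rejected at parse time because the
covariate-adjusted model needs complete status and sex.  Age travels in an
optional side table since PED carries none.

## Marker quality control

`apply_qc()` mirrors the analysis-stage screen of the study design:

* missingness: markers absent in more than half the cohort are dropped
  (`geno_max = 0.5`; the stricter 5% cut-off belongs to panel *design* and
  is only relevant when selecting tag SNPs, which is out of scope here);
* minor allele frequency must exceed 0.01 (strict);
* the exact Hardy-Weinberg p-value in controls must exceed 0.001 (strict).

HWE uses the conditional exact test (the PLINK default) rather than the
chi-square approximation: given the allele counts, the two-sided p sums the
probabilities of all heterozygote counts no more likely than the observed
one.  Probabilities come from the stable ratio recurrence, so counts in the
hundreds of thousands are safe.  HWE is computed in both strata and reported
for both, but filtering uses controls only: under a true association, cases
may legitimately deviate.  (The source design was ambiguous on this point;
filtering on controls is standard practice.)

## Single-SNP association

The allelic test is the Pearson chi-square (df = 1, no continuity
correction) on the 2x2 allele-by-status table, treating each individual as
two independent alleles — an approximation shared with the tool family this
reproduces.  The odds ratio is the cross-product ratio with a Woolf logit
95% CI; a zero cell triggers the Haldane-Anscombe 0.5 correction and a
flag.  The genotypic test is the df = 2 Pearson statistic with degrees of
freedom reduced for empty genotype columns.  Covariate adjustment uses
maximum-likelihood logistic regression (additive dosage coding, age and sex
covariates, IRLS tolerance 1e-8, at most 100 iterations); complete
separation is reported as `converged = FALSE` rather than an error.

Multiple testing offers textbook Bonferroni (`min(1, m p)`) and max-T
permutation: case/control labels are shuffled, the maximum per-SNP statistic
is recorded per permutation, and each SNP's adjusted p is
`(1 + #{max >= observed}) / (n_perm + 1)`.  The published report corrected
its three top SNPs to values (e.g. 0.0004 from 3.36e-5) that are not
`m = 231` textbook Bonferroni (which gives 7.8e-3); the effective test count
behind those numbers is not stated, so this package documents plain
Bonferroni and leaves the discrepancy visible.

## Haplotypes and linkage disequilibrium

`em_haplotypes()` is the classical EM over unphased multilocus genotypes for
windows of 2-8 SNPs: the E-step weights each compatible diplotype by the
product of current haplotype frequencies; the M-step re-estimates
frequencies from expected haplotype counts; convergence is a maximum
frequency change below 1e-6.  Initialisation is uniform over compatible
haplotypes, which makes the fit deterministic at these window sizes —
restarts added nothing in testing, so there are none.  Individuals with a
missing call inside a window are dropped from that window (summing over
missing states would buy little at a 2% missing rate and complicate the
posterior bookkeeping).  The log-likelihood trace is exposed and asserted
non-decreasing in the tests.

The EM runs on the pooled sample; case and control frequencies come from the
posterior diplotype weights within each stratum.  Per-haplotype association
is the 2x2 chi-square of EM-expected haplotype counts
(haplotype-vs-all-others by case/control), with fractional counts used as-is
in the statistic and haplotypes below overall frequency 0.01 pooled into one
`rare_pooled` test (ties in reporting broken lexicographically).
Permutation correction reuses the fixed per-individual haplotype dosages and
shuffles labels only — re-running the EM inside every permutation would
change nothing materially for a null permutation while multiplying the cost.

Pairwise LD reports |D'| and r-squared from the two-locus EM frequencies.
The D' confidence interval profiles the unphased two-locus likelihood over a
101-point D' grid at the MLE allele frequencies and takes the 5th/95th
percentiles of the normalised profile, the construction family used by
confidence-interval block finding.  Blocks follow the Gabriel-style rule:
strong LD when the CI is at least (0.70, 0.98), strong recombination when
the upper bound is below 0.90, and a span is a block when its outermost pair
is in strong LD and at least 95% of informative pairs are strong LD
(two-SNP spans need their single pair strong).  Candidates are accepted
longest-first without overlap, so blocks always partition.

## The homozygosity-ratio (T/N) micro-deletion screen

This is the package's core computation.  A hemizygous deletion carrier is
typed as homozygous for the surviving allele at every SNP in the deleted
span — never as missing — so carriers inflate the homozygous genotype
frequency in cases.  Per SNP:

* `f_hom` = (hom_a + hom_b) / non-missing, per stratum;
* T/N ratio = `f_hom_case / f_hom_ctrl`;
* significance: Pearson chi-square (df = 1, no correction) on
  case/control x homozygous/heterozygous — the same statistic family as the
  association module, since the source names no test for its summary table;
* a locus is *frequent LOH* when T/N > 1.0 **and** p < 0.05, both strict,
  as printed.

A *micro-deletion region* is a maximal run of at least 3 consecutive
panel SNPs that are all frequent LOH.  "Adjacent" means consecutive in the
QC-passed genotyped panel ordered by position; the published table does not
reconstruct the full 231-SNP ordering, so the packaged worked example uses
the table's own bold flags as the adjacency surrogate, which reproduces its
three regions exactly.

## Runs of homozygosity

`detect_roh()` slides a 50-SNP window one SNP at a time; a window is
homozygous when it has at most 1 heterozygous and at most 5 missing calls;
each SNP's hit fraction is the proportion of its overlapping windows that
are homozygous (edge SNPs use the reduced denominator), and the SNP is
in-run at fraction >= 0.05.  Runs are split at inter-SNP gaps above 1,000 kb
*before* the segment criteria apply; surviving stretches are segments when
they span >= 1,000 kb, contain >= 100 SNPs and average <= 50 kb/SNP.  The
segment-level defaults are the published screening criteria; the
scanning-window internals are the PLINK defaults, since only segment
criteria were published, and all eight knobs sit in `roh_params()`.  The
published "100 SNPs" is read as the segment minimum (PLINK's
`--homozyg-snp`), not the scanning-window size; both are exposed for users
who read it the other way.

One sizing consequence worth knowing: on a study-like panel (~103 kb marker
spacing) a 2 Mb tract covers only ~20 markers and *cannot* satisfy the
100-SNP criterion, so the negative ROH screen on that design is partly
structural.  The implant-recovery demonstrations therefore use a dense
10 kb-spaced panel where a 2 Mb tract spans ~200 markers.  A second edge
effect: the outermost SNP of a perfect tract is covered by only two
homozygous windows out of fifty (4% < the 5% hit threshold), so segments
start one SNP inside the ideal tract boundary under defaults.

## qPCR follow-up

Replicate Ct values are averaged arithmetically before any differencing
(standard ddCt practice); `dCt = Ct_target - Ct_endogenous` per specimen,
`ddCt = dCt_sample - dCt_reference`, fold change `2^-ddCt` with
amplification efficiency 2 assumed exactly, as the method requires.  Paired
inference runs on the log2 (ddCt) scale for symmetry: a two-sided paired t
and a Wilcoxon signed-rank test (exact for n <= 25 without ties) are both
reported, because the motivating analysis names non-parametric tests in its
methods yet prints paired-t p-values with its figures.  A |log2 fold| below
0.1 is labelled "unchanged" for reporting only.  All-zero differences are
degenerate: p = 1 with a flag, not an error.

## The synthetic-data generator

`simulate_panel()` draws two haplotypes per LD block per individual from
configured pools, spaces markers evenly over the region, and emulates:

* **case/control sampling** — either a logistic disease model additive in
  risk-haplotype copies (intercept set for ~50% case probability at the
  mean dose; strata filled by rejection, matching a matched case-control
  design), or direct per-stratum haplotype frequencies when the design is
  stated that way (as the published 0.822 / 0.733 risk-haplotype
  frequencies are);
* **micro-deletions** — carriers drawn per stratum lose one haplotype over
  the span and are typed homozygous for the survivor, the exact mechanism
  the T/N statistic presumes;
* **ROH** — autozygous tracts copied from one haplotype, placed so the full
  tract fits the panel;
* **missingness** — uniform at 2% by default, consistent with the >= 97.8%
  published call rate.

Covariates mirror the cohort description (case age ~ N(46.4, 11.2), control
age ~ N(41.4, 8.9), 71.8% / 34.4% male).  A single seed drives everything;
per-fixture sub-seeds derive from it by fixed offsets.  What the generator
does *not* emulate: coalescent-realistic LD decay (blocks are exchangeable
draws from explicit pools), population structure, genotyping batch effects,
and EBV or environmental covariates.  Passing tests therefore demonstrate
the statistical machinery under the design assumptions, not robustness to
real-data artefacts such as stratification — users of real cohorts should
add their own structure control.

## Problem sizes and power honesty

The test suite and the acceptance script size their simulations to the study
design where the property is about that design (360+360 cohorts; 2,000 null
SNP replicates for the type-I check; 100 replicates of the risk-haplotype
design; 200 replicates of the deletion design; n = 2,000 haplotype
recovery), and scale n up only where an example asserts an expectation
without fixing n (Monte-Carlo stability, e.g. the span-restricted T/N
elevation at n = 2,000).

Two published-design checks are power-limited, and the package reports them
honestly rather than retuning the conditions.  First, at case/control
haplotype frequencies 0.822 / 0.733 and 360+360, the per-haplotype z
statistic is approximately N(4.1, 1), so any single replicate lands inside
the two-sided p bracket [1e-5, 1e-3] only ~42% of the time even though the
*median* p (about 6e-5 in our runs) sits squarely on the published 6.46e-5.
Second, a 4-SNP deletion at 20% / 5% carrier frequencies shifts per-SNP
homozygosity by at most 0.15 x (1 - f_hom_baseline) <= 0.075, capping the
per-SNP z near 2; requiring three adjacent significant loci then caps region
recovery well below half, so the region caller is a low-sensitivity,
low-false-positive instrument at these carrier rates — consistent with it
having been used descriptively, on loci already selected as significant.
Both calculations are reproduced by the acceptance script's
`risk_haplotype_bracket_rate` and `deletion_recovery_rate` outputs.

## Known limitations

* The allelic test's two-independent-alleles assumption is anti-conservative
  under Hardy-Weinberg departure in cases.
* D' confidence intervals come from a profile at fixed allele frequencies,
  not a full joint likelihood; block calls inherit Haploview-style
  heuristics.
* The permutation engine keeps EM posteriors fixed; with very strong
  haplotype effects the null distribution is slightly misspecified.
* The region caller requires a control homozygosity above zero at every
  locus (T/N undefined otherwise) and flags rather than models degenerate
  2x2 margins.
* No strand harmonisation: multi-platform real data must be pre-harmonised
  before PED import.
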