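---
title: "Quantifying CRISPR-Select editing outcomes and cohort-level mutation statistics"
author: "crisprselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR-Select editing outcomes and cohort-level mutation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprselect)
```

## The assay and its statistic

CRISPR-Select measures the fitness consequence of a single mutation by
competing it against an internal control inside one cell population. A
Cas9 cut is repaired from two co-delivered templates: one carries the
mutation of interest (Mut), the other a synonymous substitution (WT*)
at a nearby site. Both knock-ins are read out together by deep
amplicon sequencing, so every source of experimental variation —
transfection efficiency, editing efficiency, sequencing depth — hits
numerator and denominator alike. The readout per sample is the raw
ratio

$$r = \frac{\text{MUT\_KI reads}}{\text{WTSTAR\_KI reads}},$$

and the selection statistic is the baseline-normalized ratio

$$R(t) = \frac{r(t)}{r(\text{D2})},$$

with cells harvested at day 2 (the initial timepoint) and day 12,
untreated or under cisplatin. If the mutation is neutral, $R$ stays
at 1; a deleterious or drug-sensitizing mutation drives $R$ below 1.
We also report a log-linear summary, the per-day selection
coefficient $s = \ln(R)/\Delta t$, so that a constant per-day fitness
ratio $w$ between Mut and WT* cells yields $R = w^{\Delta t}$ and
$s = \ln w$ exactly.

Two guide strategies are modeled. With an exon-targeting guide, the
allele that is not repaired from a template usually acquires a
frameshift InDel, so Mut cells effectively lose the second allele.
With an intron-targeting guide (single-allele editing), the
second-allele InDels fall in noncoding sequence and one functional
wild-type allele is preserved — the heterozygous context in which
most clinically observed ERCC2 missense mutations occur.

## Read classification

Each read is globally aligned to the amplicon reference with affine
gap penalties (match +2, mismatch −2, gap open −6, gap extend −1;
indels are left-normalized so placement does not depend on aligner
tie-breaking). The decision order is:

1. **DISCARDED** — alignment identity below `min_identity` (default
   0.8 of alignment columns);
2. **INDEL** — any insertion/deletion within ±20 bp of the cut site
   (configurable); InDels far from the cut with an otherwise perfect
   template match are background and do not veto knock-in calls;
3. **MUT_KI / WTSTAR_KI** — the full substitution set of one template
   present and the other absent;
4. **AMBIGUOUS** — both sets present, or a partial set (template
   recombination); these are excluded from ratio denominators;
5. **UNEDITED** otherwise.

InDel reads are stratified by frameshift status — the summed exonic
net length change modulo 3 — and by region (exonic, intronic, or
splice-site, with the two intronic bases at each junction taking
precedence). This yields the exon-vs-intron InDel quantification used
to validate the single-allele assay, and the frameshift frequency
whose decline over time reflects selection against disruptive InDels
in an essential gene.

Reads of reference length with at most 3 mismatches are classified
without invoking the aligner: under the default scoring a gapped
alignment can only beat the gapless one when it absorbs at least 4
mismatches, so the shortcut is exact, not an approximation.

## What the simulator emulates

`simulate_select_experiment()` models the experiment as discrete daily
multiplicative growth of diploid genotypes. Each genotype pairs two
allele outcomes (Mut knock-in, WT* knock-in, unedited, or a cut-site
InDel) with per-day growth multipliers; the cisplatin multiplier
applies on treatment days (day 3 through 12 with the default window).
Reads sample alleles independently — amplicon PCR on pooled genomic
DNA cannot phase the two alleles of a cell — and sequencing noise is
uniform per-base substitution error (default 0.5%), with InDel errors
off by default to keep the error model interpretable. The default
genotype mixture gives 85% modified alleles (the assay's observed
guide efficiency exceeds 80%), allocates knock-in alleles equally
between Mut and WT*, and pairs most knock-ins with a frameshift InDel
on the other allele. Because the Mut:WT* ratio depends only on the
relative growth of Mut- and WT*-carrying genotypes, the planted
per-day fitness $w$ of the Mut genotype yields a closed-form expected
$R(\mathrm{D12}) = w^{10}$ against which recovery is tested.

Features of real data deliberately not modeled: PCR duplicates and
chimeric templates, position-dependent error profiles, InDel
sequencing errors, and paired-end structure. Passing tests therefore
demonstrate correctness of the quantification machinery under a clean
error model, not robustness to every sequencing artifact.

`simulate_cohort()` generates the cohort arm's three linked tables
(mutations, allele-specific copy-number segments, clinical). Per-gene
alteration indicators are Bernoulli with probabilities
$p_{ij} = \mathrm{plogis}(\mu_i + \nu_j)$; the per-sample effects
$\nu_j$ (SD = `sample_rate_dispersion`) create the heterogeneous
per-tumor alteration rates that motivate the margin-aware
exclusivity test, and the per-gene intercepts are calibrated so
marginal rates match `gene_rates`. Planted exclusive or cooccurring
pairs relocate one gene's alterations while preserving both margins.
Survival is exponential with status-specific hazards under
independent exponential censoring; platform assignment scales the
per-sample mutation burden; and a synthetic 20-kb locus sequence is
emitted together with locus-restricted SNVs drawn from a trinucleotide
signature mixture.

## The cohort statistics

**Status calls.** A sample is ERCC2-mutant when it carries a missense
or truncating (stopgain, frameshift, nonstop) variant inside the
helicase-domain residue intervals; qualifying variants outside the
intervals, and non-qualifying classes, leave it wild-type. The
intervals are configuration, not code — `ercc2_helicase_domains()`
provides defaults covering the two conserved helicase lobes so
examples run, but analyses of real data should supply the residue
ranges for their transcript. TP53 status follows
pathogenic/likely-pathogenic labels (VUS count as wild-type) or deep
deletion. LOH is any overlapping copy-number segment with minor copy
number 0; no overlapping segment yields NA rather than a forced call.

**TMB harmonization.** Burden is mutations per megabase with the
published per-platform footprints (WES 38 Mb; OncoPanel 0.753334 /
0.826167 / 1.315078 Mb; MSK-IMPACT 0.896665 / 1.016478 / 1.139322 /
1.25964 Mb; Caris 1.4 Mb). Cross-platform comparability is achieved
by z-scoring within platform strata. The standardization is applied
to $\log_{10}(\mathrm{TMB}+1)$: TMB is strongly right-skewed, and a
z-score on the raw scale would be dominated by the tail. The
published harmonization defers some details to supplementary material
not reproduced here, so the log basis is a stated package decision.

**Mutational signatures.** The 96-channel single-base-substitution
spectrum uses pyrimidine-centered channels in the conventional COSMIC
order; purine-reference sites are counted on the reverse-complement
strand, and indels/MNVs are excluded with counts logged. Exposures of
reference signatures are fitted by nonnegative least squares
(Lawson–Hanson active set), reporting the residual norm. The package
ships a clearly labelled *synthetic* signature matrix for simulations
and tests; real analyses should load a COSMIC subset with
`read_signature_matrix()`.

**Mutual exclusivity.** The alteration matrix is built from nonbenign
exonic and splice-site variants, with WES and panel strata kept
separate. The null model preserves both margins: maximum-entropy
probabilities $p_{ij} = \mathrm{plogis}(\mu_i + \nu_j)$ fitted by
alternating Newton updates until expected row and column sums match
the observed ones (default tolerance 1e-8, deterministic from zero
initialization; all-zero/all-one rows and columns are excluded and
reported). For a gene pair the overlap count is Poisson-binomial with
per-sample probabilities $q_j = p_{Aj} p_{Bj}$, computed by exact
dynamic-programming convolution; exclusivity is the lower tail,
cooccurrence the upper. The Fisher screen is reported alongside with
BH adjustment at the 0.01 threshold; with heterogeneous per-tumor
rates it is conservative for exclusivity and anticonservative for
cooccurrence, a contrast the calibration tests assert directionally.

A note on how calibration is checked. The acceptance suite verifies
near-uniformity of exclusivity p-values on 500 *disjoint* gene pairs
against the generative background probabilities (1,000 genes × 2,000
samples, dispersion 1). Three effects make the naive alternative — a
Kolmogorov–Smirnov test on pairs drawn from one small matrix with a
refit background — unsuitable as a sharp test: the lower-tail
p-value of a discrete count is super-uniform by construction;
refitting margins on the tested matrix itself removes part of the
overlap variance from the realized statistic but not from the
Poisson-binomial null (a compression of order $2p/(1+p)$ that does
not vanish with more genes or samples and is mild only at the sparse
alteration rates typical of somatic mutation data); and pairs sharing
gene rows or samples are dependent, which the KS test does not
tolerate. The refit path is exercised separately: fitted margins must
reproduce observed margins to 1e-6, and a planted perfectly exclusive
pair must reach BH-adjusted p < 0.01 through the full
fit-and-screen procedure.

**Survival.** Kaplan–Meier curves with Greenwood standard errors; the
K-group log-rank test with hypergeometric variance; and Cox
proportional hazards by Newton–Raphson on the partial likelihood with
Efron tie handling by default (Breslow available), convergence at
max |Δβ| < 1e-9 or 25 iterations, Wald tests reported, and the
score test at β = 0 exposed (for one binary covariate without ties it
equals the log-rank chi-square, a cross-check the tests enforce to
1e-9). Monotone likelihoods (complete separation) abort with the
offending covariate named. The interaction analysis of ERCC2
helicase-domain status and TP53 status enters the model as two main
effects and their product, with wild-type as the reference level
(0/1 coding), since the original covariate coding is not printed.

## Numerical and design choices

* Coordinates are 0-based half-open in the amplicon frame; protein
  positions and genomic intervals are 1-based inclusive, matching
  community conventions.
* Splice sites are the 2-bp intronic dinucleotides at each junction;
  the window is configurable. The upstream splicing analysis is not
  reproduced — only splice-overlap flags are exposed — because the
  metric behind it is not specified in enough detail.
* The two-sided Fisher p-value uses the probability-mass rule with a
  relative tolerance of 1e-7 guarding floating-point ties; the exact
  Wilcoxon path (combined n ≤ 20, no ties) uses the count recursion,
  switching to the tie-corrected, continuity-corrected normal
  approximation otherwise.
* Zero Mut knock-in reads with nonzero WT* give R = 0 with a warning
  (observable extinction); zero WT* reads are an error, not an
  infinity. No continuity correction is applied to counts.
* The paired replicate t test is the default endpoint contrast
  (treated vs untreated at D12, paired across replicates); the
  unpaired Welch test serves cross-cell-line comparisons.
* All randomness in a simulation or pipeline run flows from one seed;
  two runs with the same seed produce byte-identical output trees
  (no timestamps are written).

## Problem sizes in the test and acceptance runs

The suite exercises: per-read classification at depths 2,000–10,000
with 0.5% per-base error; the fitness-recovery grid
$w \in \{1.0, 0.9, 0.8, 0.6\}$ at depth 10,000 × 3 replicates;
1,000 neutral count-level simulations for the type-I error of the
paired test; exact-test enumeration oracles at n ≤ 12; the
calibration design described above (1,000 genes × 2,000 samples);
100 Poisson resamplings of a 500-mutation spectrum; 1,000 null
log-rank simulations at n = 200 and 50 Cox recoveries at n = 2,000;
and two full pipeline runs for byte-identity. These sizes keep the
whole suite to a few minutes on one core while leaving each
stochastic check with comfortable statistical margin.

## Known limitations

* The classifier assumes a single amplicon per sample and does not
  merge paired-end reads, trim by quality, or handle UMIs.
* The background model's plug-in p-values inherit the mild
  conservatism discussed above on small matrices; groupwise (>2 gene)
  exclusivity tests are out of scope.
* De novo signature extraction is not provided — only refitting of a
  supplied signature matrix.
* Copy-number segmentation, variant-effect prediction and clinical
  endpoint derivation are consumed as inputs, never inferred.
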