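# crisprselect

Quantification machinery for **CRISPR-Select** editing experiments and
the cohort-level statistics used to interpret DNA-repair gene mutations
(here, ERCC2 helicase-domain mutations in bladder cancer) as predictive
biomarkers of platinum response.

## Who this is for

Two audiences, two arms:

* **Editing arm** — labs running CRISPR-Select (or any
  dual-template knock-in competition assay) who need to turn amplicon
  FASTQ files into editing-outcome counts and the normalized Mut:WT*
  selection statistic, including the single-allele (intron-guide)
  variant of the assay that preserves one wild-type coding allele.
* **Cohort arm** — analysts relating mutation status to clinical
  outcome across tumor-sequencing cohorts: helicase-domain status
  calls, loss of heterozygosity from allele-specific copy-number
  segments, tumor mutation burden harmonized across capture platforms,
  region-restricted 96-channel mutational-signature refitting,
  margin-aware mutual-exclusivity testing, and survival analysis.

A synthetic-data module simulates both arms with known ground truth,
so every stage is testable without external downloads.

## The statistic at the core

A Cas9 cut is repaired from two co-delivered templates: the mutation
of interest (**Mut**) and a synonymous control (**WT\***). Deep
amplicon sequencing counts both knock-ins in the same library, and the
per-sample readout is the ratio *r* = MUT_KI / WTSTAR_KI, normalized
to the day-2 baseline:

*R*(t) = *r*(t) / *r*(D2),  *s* = ln *R* / Δt.

Neutral mutations keep *R* at 1; a cisplatin-sensitizing mutation
drives *R*(D12) below 1 under treatment. Because both templates ride
through the same cells, transfection, and library, the ratio cancels
experimental variability that would swamp absolute frequencies.

The cohort arm's mutual-exclusivity test uses a null that preserves
per-gene *and* per-tumor alteration rates: logistic background
probabilities fitted to both margins, with the pairwise overlap count
tested against its exact Poisson-binomial distribution (lower tail =
exclusivity, upper tail = cooccurrence). The conventional Fisher
screen is also provided; under heterogeneous per-tumor rates it is
conservative for exclusivity and anticonservative for cooccurrence.

## Worked example

Simulate an exon-guide experiment in which Mut-carrying cells grow at
0.8×/day under cisplatin (days 3–12), classify the reads, and compute
the selection statistics:

```r
library(crisprselect)

design <- example_design("exon")
mix <- default_genotype_mix(design, mut_cisplatin_fitness = 0.8)
sim <- simulate_select_experiment(design, mix, depth = 5000, seed = 42)

outcomes <- quantify_experiment(sim)
head(outcomes[, c("sample_id", "n_MUT_KI", "n_WTSTAR_KI",
                  "n_UNEDITED", "n_INDEL", "frameshift_frequency")], 4)
#>     sample_id n_MUT_KI n_WTSTAR_KI n_UNEDITED n_INDEL frameshift_frequency
#>  D2_untr_rep1      772         767        788    2671               0.5342
#>  D2_untr_rep2      811         796        761    2630               0.5260
#>  D2_untr_rep3      808         820        734    2636               0.5272
#>  D2_trea_rep1      754         809        695    2737               0.5474

select_analysis(outcomes)
#> CRISPR-Select analysis
#>  timepoint condition    mean_R       sd_R
#>          2   treated 1.0000000 0.00000000
#>         12   treated 0.1121004 0.01721374
#>          2 untreated 1.0000000 0.00000000
#>         12 untreated 1.0022579 0.07791185
#> Endpoint treated vs untreated: t = -19.041, df = 2.0, p = 0.002747
```

Reading the output: at day 2 every ratio is 1 by construction. Without
cisplatin the mutation is neutral (mean *R* ≈ 1.00). Under treatment
the planted per-day fitness of 0.8 over 10 days predicts
*R* = 0.8¹⁰ ≈ 0.107, and the classifier recovers 0.112 ± 0.017 across
three replicates; the paired two-tailed t test on the endpoint
contrast gives p = 0.0027. The frameshift frequency column is the
fraction of reads carrying a frameshift InDel — the quantity whose
decline over time indicates selection against disruptive InDels.

The cohort arm runs the same way from simulated tables:

```r
cohort <- simulate_cohort(n_samples = 300, seed = 1)
status <- cohort_status_table(cohort)      # ERCC2/TP53 status, LOH, TMB z
surv <- cohort_survival_analysis(cohort, status)  # KM, log-rank, Cox
```

A thin command-line wrapper (`exec/crisprselect`) exposes the stages as
subcommands (`simulate-select`, `quantify`, `select-stats`,
`simulate-cohort`, `cohort`, `cooccur`, `survive`, `all`); `all` runs
the full pipeline deterministically from one seed.

## Package layout

* `R/` — amplicon designs, simulators, read classifier, selection
  statistics, self-implemented statistical primitives, cohort
  genomics (status/LOH/TMB/signatures), mutual-exclusivity testing,
  survival models, pipeline/CLI.
* `vignettes/crispr-select-methods.Rmd` — the model, its assumptions,
  parameter defaults, numerical choices, and known limitations.
* `inst/extdata/` — small plain-text fixtures: an example design
  (YAML), a 40-read FASTQ, and a clearly labelled synthetic signature
  matrix (TSV).
* `tests/testthat/` — unit, property, and end-to-end acceptance tests
  with enumeration/DP oracles.
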