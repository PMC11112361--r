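---
title: "Quantifying kinase activity from targeted T-loop phosphoproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying kinase activity from targeted T-loop phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(kinact)
library(dplyr)
```

## The measurement and its model

Protein kinases switch on when their activation loop (T-loop) is
phosphorylated, so for most kinases the abundance of the phosphorylated
T-loop peptide is a direct proxy of catalytic activity. A targeted
(SRM/PRM-style) assay monitors, for each of a few hundred T-loop
phosphopeptides, a handful of fragment-ion *transitions* on a triple
quadrupole, together with a spiked stable-isotope-labeled ("heavy")
synthetic copy of every peptide. The heavy standard co-elutes with the
endogenous ("light") peptide and is chemically identical, so the light/heavy
ratio cancels spike amount, injection volume and instrument response.

`kinact` takes the exported transition-level integration results (one row
per sample x peptide x charge x fragment x label, with area and background)
and turns them into per-patient kinase-activity estimates and
treatment-outcome statistics. The abundance model is deliberately simple:
for peptide $p$ in sample $s$, over the fixed quantification transition set
$Q_p$,

$$ a_{ps} \;=\; \log_2 \frac{\sum_{f \in Q_p} \text{light}_{psf}}
                            {\sum_{f \in Q_p} \text{heavy}_{psf}}. $$

If every light transition is the heavy one scaled by the true relative
abundance, this recovers the truth exactly for *any* positive per-sample
spike variation — the package tests this identity to `1e-12`.

## Interference filtering

Chromatographic co-elution can contaminate individual light transitions.
Because the heavy standard defines what the fragment pattern of a clean
peptide looks like, contamination is detectable as a distorted *relative
contribution* (a transition's share of its peptide's summed signal). The
cascade runs in a fixed order, each stage shrinking the record set:

1. **Signal-to-noise** — a transition is removed when its area is below
   `snr_min` (default 3) times its background. A zero background is treated
   as noise-free: signal is kept rather than discarded for lack of a noise
   estimate.
2. **Contribution mismatch** — per sample and peptide, light and heavy
   relative contributions are computed separately; a light transition is
   removed when its contribution differs from its heavy counterpart's by
   more than `contribution_tol` (default 0.20, read as an absolute
   difference of fractions — contributions are themselves fractions, and
   the absolute reading is stable when contributions are small). Light
   fragments without a surviving heavy partner are removed; heavy records
   are never removed. The stage is a single pass over its input: survivor
   contributions are not renormalized and re-tested, which matches the
   worked behaviour of the rule (removing a dominant contaminated fragment
   necessarily inflates the shares of the survivors).
3. **Sparsity** — a peptide counts as detected in a sample when at least
   `min_transitions` (default 2) light transitions survive; undetected
   peptide/sample groups are dropped, then peptides detected in fewer than
   `min_files` (default 5) samples are dropped entirely. "Detected" is
   deliberately tied to the same `min_transitions` threshold that the
   quantification rule uses.
4. **Transition selection** — quantification demands the *same* transitions
   in every sample. Per sample the per-fragment log2 light/heavy ratios are
   summarized by their median; a fragment enters the quantification set
   when its mean absolute deviation from that reference across samples is
   at most `ratio_consistency_tol` (default 0.5 log2 units, i.e. about
   1.4-fold). The original procedure included a visual-inspection step with
   no numeric criterion, so this threshold is an explicit, configurable
   formalization; every run logs it. Peptides ending up with fewer than
   `min_transitions` consistent fragments are excluded.

Filter decisions are invariant to rescaling all intensities of a sample by
a positive constant, and each removal stage's output is a subset of its
input; the test suite checks both properties, plus record-for-record
equality with an independent brute-force implementation of each rule.

## From peptides to activation states

Methionine-oxidized satellite forms of a T-loop peptide report on the same
activation state at roughly 10-fold lower signal. When both forms are
quantified in a sample only the non-oxidized value is used; when only the
oxidized form is present its value is used *as-is*, without a +log2(10)
correction — the oxidation rate is similar across samples, and mixing
corrected and uncorrected values would distort cross-sample comparisons
more than consistent per-form usage does (cells quantified from the
oxidized form are flagged `from_oxidized`). Doubly phosphorylated forms
(e.g. `p38A (T180 + Y182)`) are distinct activation states and are never
merged with the singly phosphorylated form. Peptides whose sequence is
shared across paralogs are reported once under a joined label (e.g.
`MARK1/MARK2 (S219)`) with `paralog_shared = TRUE`.

## Differential statistics and predictive panels

Patients carry one of three pathological outcomes — complete response
(pCR), near-complete (npCR), no complete response (NoPCR) — and pCR alone
defines the "responder" class. Per activation state, complete-case:

* log2 fold change responders vs non-responders with a pooled-variance
  Student t-test (the common default for this design; Welch is available
  via `var_equal = FALSE`);
* one-way ANOVA across the three outcome groups with Tukey HSD pairwise
  p-values (`aov()` + `TukeyHSD()`);
* ROC analysis in the Mann–Whitney formulation (ties half-counted), with a
  two-sided z-test of AUC against 0.5 using the Hanley–McNeil standard
  error. Scores are oriented by the sign of the fold change, so inverse
  markers (FAK-like states, higher in non-responders) also report a
  discriminative AUC above 0.5. The Hanley–McNeil p-value is an
  approximation chosen for transparency; at AUC = 1 its standard error
  degenerates to zero and the p-value is reported as 0.

No multiple-testing correction is applied by default (raw p < 0.05 is the
selection currency here); Benjamini–Hochberg columns can be added with
`p_adjust = "BH"` and never overwrite the raw values. A minimum of two
patients per class is required by default; it can be lowered to
accommodate very sparsely detected states.

Two rule-based panels condense the table (`select_panel()`):

* **six_kinase** — t-test p < 0.05, linear fold change > 1.5 and detection
  in at least 80% of patients;
* **four_kinase** — t-test p < 0.05 and detection in 100% of patients.

Applied to the packaged reference statistics table
(`reference_kinase_stats()`, from a published 32-patient HER2+ neoadjuvant
cohort), these rules reproduce the published six-state and four-state
panels exactly:

```{r}
select_panel(reference_kinase_stats(), "six_kinase")
select_panel(reference_kinase_stats(), "four_kinase")
```

`fit_logistic()` then fits a multiple logistic regression of responder
status on the panel abundances by iteratively reweighted least squares
(complete-case patients, no imputation), flags complete separation
(diverging coefficients / degenerate fitted probabilities) as
non-convergence, and scores the panel by the ROC of its fitted
probabilities. In-sample AUC is reported, matching the original analysis;
cross-validated performance estimation is out of scope.

Clustering (`hierarchical_cluster()`) follows the heatmap conventions of
this literature: row z-scoring, Euclidean distance, complete linkage by
default (average/Ward selectable). Distances over partially missing
profiles use the shared observed dimensions rescaled by
$\sqrt{p/p_\text{obs}}$; item pairs sharing no observation are placed at
just beyond the maximum observed distance, with a warning.

## The synthetic cohort generator

Real transition reports for this assay are not redistributable at package
scale, so `simulate_cohort()` generates cohorts from an explicit generative
model and keeps the ground truth (`SimTruth`) for every quantity it draws.
The defaults encode the study conditions the pipeline targets:

| parameter | default | what it emulates |
|---|---|---|
| `n_patients` | 17/6/9 | pCR / npCR / NoPCR group sizes |
| `n_targets` | 311 | targeted T-loop peptides (heavy standards) |
| `n_detectable` | 56 | endogenously detectable peptides |
| `dynamic_range` | 3.6 log10 | span of base abundances across kinases |
| `between_patient_sd` | 1.0 log2 | biological variability (not reported by the assay literature; a round, conservative choice) |
| `heavy_spike_cv` | 0.10 | per-(sample, peptide) spike variation |
| `transition_noise_cv` | 0.05 | per-transition multiplicative noise |
| `interference_rate` | 0.05 | contaminated (sample, light transition) cells |
| `interference_magnitude` | 2–10x | contamination boost |
| `oxidation_fraction` | 0.10 | detectable targets with an oxidized satellite at 10-fold lower signal |
| `background_level` | 2000 | constant per-transition background |

Noise is lognormal throughout: intensities are positive and CVs are
approximately scale-free, which is the standard working assumption for MS
intensity noise. Effects are injected as responder-vs-non-responder log2
fold changes on named states (default: a HER2-pathway-like set including
one inverse FAK-like marker), with the npCR group at an intermediate
half-effect level; group offsets are rescaled so the responder vs
non-responder mean difference equals the stated effect exactly. Detection
is *not* an independent dropout process: a state is missing in a patient
exactly when too few of its light transitions clear the S/N threshold, so
missingness is informative (low abundance means missing), as in real
targeted MS. With the defaults this produces 20–40 quantified T-loops per
patient. With a zero background the S/N detection limit disappears and the
abundance scale is anchored at a fixed reference instead, which is how the
noise-free exactness tests are constructed.

What the generator does **not** emulate: chromatographic peak shapes,
retention-time drift, batch effects, censoring from manual peak-boundary
review, and correlated interference across fragments of one peptide.
Passing the simulation-based tests therefore demonstrates correctness of
the computations under the stated model, not robustness to every artifact
of real acquisitions.

## A small end-to-end run

```{r}
cfg <- sim_config(
  n_patients = c(6, 3, 3), n_targets = 40, n_detectable = 20,
  effects = c("ERK2 (T185)" = 1.1, "FAK (Y576)" = -0.6), seed = 1
)
sim <- simulate_cohort(cfg)
run <- run_pipeline(sim$transitions, sim$panel, sim$design,
                    panel_rule = "four_kinase")
run
head(run$stats, 4)
truth_report(sim, run$abundance, run$filtered$removed)$summary
```

## Numerical choices and degenerate inputs

* S/N boundary: `area >= snr_min * background` is kept ("below" removes).
* Contribution boundary: exactly 20 percentage points is kept ("more
  than" removes).
* Zero heavy sum cannot be normalized; the cell is set missing with a
  warning rather than propagating an infinity.
* Zero-variance rows are dropped before z-scoring and zero-variance
  predictors before logistic fitting, each with a warning.
* Tie-breaking in clustering and ROC curves is deterministic in input
  order; the generator is fully determined by its seed.
* The logistic fit converges on a log-likelihood change below 1e-8 or 100
  iterations; coefficients above 15 in absolute value or fitted
  probabilities within 1e-6 of 0/1 are treated as separation.

## Problem sizes used by the test suite

Unit and property tests run on small constructed tables and reduced
simulated cohorts (12 patients, 40 targets); the end-to-end checks use the
full default cohort (32 patients, 311 targets), 100 randomized filter
tables against the brute-force oracle, 1000 random score sets for the AUC
identity, 2000 replicates for t-test calibration and 500 for fold-change
recovery — sizes at which every Monte-Carlo tolerance used is several
standard errors wide.

## Limitations

The package ingests transition-level integration exports; it does not read
vendor raw files or perform peak integration. In-sample panel AUCs are
optimistic by construction and the panels themselves are selected on the
same cohort they are evaluated on — with 32 patients this is a
hypothesis-generating analysis, and any clinical claim needs external
validation. The ratio-consistency criterion formalizes a step that was
partly visual in the original workflow; its default tolerance is a design
choice, logged with every run, not a measured property of any instrument.
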