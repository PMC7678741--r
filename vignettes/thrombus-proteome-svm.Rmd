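---
title: "Exhaustive SVM panel search for two-group LFQ proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive SVM panel search for two-group LFQ proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thromboSVM)
```

## The problem

Thrombi retrieved by mechanical thrombectomy from acute ischemic stroke
patients carry molecular information about the clot's origin: whether it
formed in the heart (cardioembolic, group **C**) or on an atherosclerotic
arterial lesion (atherothrombotic, group **A**). Label-free quantification
(LFQ) mass spectrometry of such tissue yields a protein-by-sample intensity
matrix with two awkward properties: intensities span orders of magnitude,
and a large share of cells is *missing* — a protein simply was not
quantified in a sample, predominantly because its abundance sat near the
detection limit.

With cohorts of a few dozen patients per group, single-protein statistics
are underpowered and honest cross-validation of high-capacity classifiers
is not feasible. The approach implemented here instead asks a bounded,
descriptive question: **does a small panel — up to three proteins — admit a
linear hyperplane that separates the two groups, and how well?** Every
candidate panel is scored exhaustively, so the result is a property of the
dataset rather than of a heuristic search path.

## The pipeline

1. **Read** a MaxQuant-proteinGroups-style table (`read_lfq_table()`).
   Zeros and blanks are recorded as missing, never as measured values;
   contaminant and reversed-decoy rows are dropped and counted. Each
   protein group is represented by its *leading protein*: the candidate
   with the most identified peptides, ties resolved by annotation quality
   (curated entry first, then strongest protein-existence evidence, then
   most GO annotations), and finally by identifier order so the choice is
   deterministic (`select_leading_protein()`).
2. **Filter.** The panel search requires complete features, so it operates
   on the *commonly detected* proteins — those with a valid value in every
   sample (`filter_common()`). The univariate branch instead keeps proteins
   with at least 50% valid values (`filter_min_valid()`, inclusive
   boundary). The 50% rule counts over *all* samples by default; the
   per-group variant ("at least the fraction in one group"), common in
   Perseus workflows, is available behind `per_group = TRUE`. Nothing is
   ever imputed: all downstream statistics consume valid values only.
3. **Search.** Every combination of `k` proteins (`k` ≤ 3) is scored with a
   linear soft-margin SVM on log2 intensities, by resubstitution accuracy
   (`search_panels()`).
4. **Univariate statistics.** Per-protein bilateral Wilcoxon rank-sum tests
   (`wilcoxon_rank_sum()`) for the panel members, and a Welch/Student
   t-test volcano analysis (`welch_t_volcano()`) on the 50%-valid matrix.
5. **Clinical covariates.** The same exhaustive SVM scoring applied to
   clinical variable subsets (`clinical_variable_search()`), with named
   exclusions, and to combined protein + clinical feature blocks
   (`combined_panel_accuracy()`).

## The classifier and its score

The SVM is the standard soft-margin linear machine: minimize
½‖w‖² + C·Σᵢ max(0, 1 − yᵢ(w·xᵢ + b)), with y = +1 for group C. Four
modelling choices are deliberately exposed as configuration because no
single convention is canonical:

* **Kernel: linear.** Panels live in a 2- or 3-dimensional protein space; a
  separating *hyperplane* there is what "a discriminative trio" means.
* **C = 1 by default.** There is no validation set to tune against; C = 1
  is the common default of reference implementations, and the search
  ranking is reported at a stated, fixed C.
* **Features are z-scored** per protein (means/SDs stored in the model).
  LFQ intensities differ by orders of magnitude between proteins; without
  standardization the regularization would be dominated by abundant
  proteins. All accuracy results are therefore invariant to affine
  per-feature rescaling.
* **Input scale: log2 LFQ.** All quantitative analysis in the package is
  on the log2 scale; `search_panels()` transforms on the fly if handed a
  raw-scale matrix.

The score is **resubstitution accuracy**: the model is evaluated on the
samples it was fitted on. With n ≈ 60 this is a *descriptive
discriminability measure* of the panel — an upper bound, not an estimate of
generalization error, and it is documented as such wherever it appears.

### The solver

`fit_svm()` solves the dual by maximal-violating-pair SMO, written for this
package: the search needs 10⁵–10⁷ fits of tiny problems (≤ 3 features, tens
of samples), where per-call overhead of a general-purpose library dominates
runtime. The solver is deterministic — no random initialization, a fixed
pair-selection rule, KKT tolerance 10⁻⁶ (configurable), an iteration cap of
20,000 — so accuracies, and therefore the search ranking, are bit-stable
across runs and chunkings. Two numerical details matter: alphas within
10⁻¹² · C of a box bound are snapped onto the bound so the bound-set
bookkeeping cannot oscillate on ties, and a zero-variance feature has its
SD set to 1 with a warning (after centering it carries no information). The
test suite cross-checks predictions against an independent reference
implementation (libsvm via e1071) on random small instances.

## The exhaustive search and tie handling

`search_panels()` walks all C(p, k) strictly increasing index tuples in
lexicographic order (a 438-protein trio space has 13,908,836 of them). Two
reporting rules follow from the discreteness of the score:

* Accuracy is an integer count of correctly classified samples, so ties at
  the maximum are *exact*, and **all tied panels are retained** rather than
  an arbitrary winner. The `core_proteins` field reports the intersection
  of all top panels — a protein recurring in every top trio is the search's
  most robust signal.
* Within an exact tie the panels are ordered by decreasing **geometric
  margin** (1/‖w‖ in standardized space) — the SVM's own secondary
  criterion — with a final canonical sort on protein IDs. On small cohorts
  resubstitution saturates at 100% for many panels; the first reported
  panel is then a deterministic, permutation-invariant representative of
  the tie (the widest-margin separation) instead of whichever panel happens
  to enumerate first.

Ranking uses full-precision accuracy; the one-decimal percentage is display
formatting only. The enumeration can be chunked (`chunk_size`) with an
order-independent reduction — serial and chunked runs return identical
summaries — and checkpointed to JSON for restartable long searches, since a
full 13.9M-trio search is hours-scale on one CPU.

## Univariate statistics

* **Wilcoxon rank-sum**, two-sided: exact enumeration when the smaller
  group has ≤ 10 values and there are no ties; otherwise the normal
  approximation with midrank tie correction and continuity correction.
  Completely tied data carry no evidence and report p = 1; an empty group
  is flagged `untestable` rather than dropped.
* **t-test volcano**: Welch's unequal-variance test is the default (the
  safer choice when group variances are not known to match); the
  pooled-variance Student test is available via `var_equal = TRUE`. The
  `difference` axis is mean(log2 A) − mean(log2 C), so proteins enriched in
  cardioembolic thrombi have *negative* differences. `neg_log10_p` uses
  base 10. Raw p-values are reported — the significance flag at α = 0.05 is
  unadjusted — with an optional Benjamini–Hochberg `q_value` column for
  good practice.

Degenerate cases are defined, not left to float arithmetic: identical
groups give p = 1 exactly; a zero-variance shift underflows to the smallest
positive double rather than p = 0, keeping p ∈ (0, 1].

## Clinical integration

Binary covariates encode to 0/1 and share the single standardization
pathway inside the SVM. Missing clinical values are handled by listwise
exclusion per analysis, and the excluded sample count is always reported —
a cohort of 60 quietly becoming 59 changes every percentage, so the
denominator is surfaced rather than hidden. Excluded variables are removed
before subset enumeration and can never appear in a reported subset. The
per-size best subsets make "adding a third variable did not improve the
score" directly checkable, and `combined_panel_accuracy()` degenerates
exactly to the pure-proteome and pure-clinical scores when one feature list
is empty (a property the tests assert).

## The synthetic cohort generator

Every downstream stage is tested against `simulate_cohort()`, which
emulates the statistical structure of a two-group thrombectomy cohort with
known ground truth:

* **Intensity model.** Protein mean abundances are drawn from
  Normal(`base_log2_mean` = 25, `protein_log2_sd` = 2); within a protein,
  per-sample log2 intensities are Normal(meanᵢ, `base_log2_sd` = 1); raw
  LFQ = 2^log2. The between-protein spread is essential: without it,
  intensity-dependent missingness could not produce the real-data pattern
  in which a minority of (abundant) proteins is quantified in *every*
  sample while most are not.
* **Planted effects.** `n_planted` proteins shift group C by
  `effect_size × base_log2_sd` on the log2 scale, so `effect_size` is
  Cohen's d against the within-group SD; the shift direction is
  configurable per protein (cardioembolic-enriched, i.e. upward in C, by
  default). All other proteins have identical group distributions.
* **Missingness.** Each cell is independently missing with probability
  plogis(qlogis(`missing_rate`) − `missing_intensity_slope` · z), where z
  is the cell's log2 intensity standardized by the overall spread. This
  left-censoring-like logistic model is an *assumption* — real acquisition
  processes are not characterized well enough to fix the mechanism — but
  it reproduces the two properties the filters care about: low-abundance
  cells are missing more often, and a stable subset of proteins is complete
  everywhere. The defaults (rate 0.08 at the central intensity, slope 5)
  are calibrated so that a 2,455-protein, 60-sample cohort retains roughly
  18% commonly detected proteins, the fraction seen in thrombectomy
  proteomes. Missing cells are written as 0 in the raw table (the MaxQuant
  convention) and carried as an explicit mask internally.
* **Reproducibility.** The master seed selects the planted set; each
  protein then uses its own deterministically derived sub-stream, so a
  protein's values do not depend on how many proteins are simulated, and
  identical seeds give bit-identical cohorts.
* **Clinical covariates** are per-group Bernoulli or normal draws; the
  default descriptor list resembles a stroke cohort (atrial fibrillation
  strongly C-associated, cardiac failure absent in A, older C patients,
  mostly uninformative blood counts).

What the generator does **not** emulate: peptide-level evidence, retention
times, batch effects, inter-protein correlation, heavy-tailed or skewed
intensity distributions, more than two groups. Passing tests therefore
demonstrate correctness of the algorithms under a plausible cohort
geometry, not performance claims about any real dataset.

```{r example}
cfg <- simulation_config(n_group_c = 20, n_group_a = 20, n_proteins = 30,
                         n_planted = 3, effect_size = 2.5, missing_rate = 0,
                         seed = 7, clinical_spec = list())
sim <- simulate_cohort(cfg)
srch <- search_panels(filter_common(sim$lfq)$matrix, k = 3)
srch$top_panels[[1]]$protein_ids
sim$truth$planted_protein_ids
```

## Problem sizes used by the test and acceptance suites

The suites are sized to exercise every property at full fidelity while
staying laptop-friendly: exhaustive searches use 20–30 proteins (1,140 –
4,060 trios) for ground-truth recovery across 10 seeds, and one full
161,700-trio search over 100 common proteins on a 32 + 28 cohort verifies
serial/chunked equivalence at scale; null calibration uses 2,000 simulated
proteins; Wilcoxon exact-path equivalence enumerates all group splits up to
a total of 10 samples. The complete 438-protein trio space is counted (both
in closed form and by streaming the actual enumeration loop) but not
searched in the test suite.

## Known limitations

* Resubstitution accuracy is optimistically biased by construction; the
  package reports it as a panel discriminability score and offers no
  cross-validated alternative, because the target use case (n ≈ 60) cannot
  support one honestly.
* The exhaustive search is O(p³) SVM fits; beyond a few hundred common
  proteins it needs chunking/checkpointing, and k > 3 is out of scope.
* The min-valid filter's "overall vs per-group" convention and the
  missingness mechanism of the generator are assumptions made explicit
  above, not facts about any acquisition pipeline.
* Wilcoxon p-values in the normal-approximation regime are approximate for
  heavily tied data; the exact path is restricted to small untied groups.
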