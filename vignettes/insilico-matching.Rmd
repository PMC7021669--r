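---
title: "Screening unknowns against in-silico spectral libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening unknowns against in-silico spectral libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntamatch)
library(dplyr)
```

## The problem

Non-targeted analysis (NTA) by LC-HRMS aims to identify compounds in a
sample without a pre-defined target list. Empirical MS2 reference
libraries only cover a small fraction of chemical space, so screening
workflows increasingly match experimental MS2 spectra against libraries of
*predicted* (in-silico) fragmentation spectra covering hundreds of
thousands of structures. Predicted spectra are less accurate than
empirical ones: the true compound is often *not* the best-scoring
candidate, and any practical workflow must quantify — and filter on — how
well the true compound separates from isobaric co-candidates.

`ntamatch` implements that workflow end to end:

1. read and de-duplicate experimental MS2 spectra (MGF);
2. retrieve candidate compounds whose neutral monoisotopic mass lies
   within a ppm window of the observed precursor (only \[M+H\]+ and
   \[M−H\]− adducts), optionally restricted to the known molecular
   formula;
3. score each candidate's predicted spectra against the experimental
   spectrum with a normalized dot product;
4. aggregate scores across collision energies (CE) by one of three
   approaches;
5. normalize candidate scores to ranks, percentiles and quotients; and
6. calibrate percentile/quotient cutoffs on a TPR floor via ROC sweeps,
   reporting per-mixture TPR/FPR, top-k summaries, and
   reference-vs-in-silico overlap.

A fully seeded synthetic-benchmark generator stands in for instrument
data, so every stage is testable offline.

## Model and procedure

### De-duplication

One chromatographic feature commonly triggers several MS2 acquisitions of
the same precursor. For a given precursor mass, only the spectrum with the
highest summed ion intensity is retained. Grouping "the same precursor
mass" needs a tolerance the instrument vendor does not report; we group by
single linkage with a default of 0.005 Da (`group_tolerance` in
`deduplicate_spectra()`), roughly instrument precision for a Q-TOF, and
break ties deterministically toward the lexicographically smallest
spectrum id.

### Candidate retrieval

The neutral mass of an observed precursor is `m/z ∓ 1.007276` Da for
positive/negative mode. Candidates are all compounds with

$$\frac{|M_\text{candidate} - M_\text{query}|}{M_\text{query}} \times 10^6 \le \text{ppm}$$

with a 10 ppm default. The denominator is the *query* mass (the window is
centred on the observed value); `ppm_reference = "candidate"` switches the
convention. Formula filtering (`filter_by_formula()`) additionally
requires element-count equality with a target formula; in evaluation mode
the target is the spiked compound's formula, making it a best-case
scenario for candidate-list purity.

### Dot-product similarity

Peaks of the experimental and predicted spectrum are paired one-to-one
inside a fragment mass window (0.02 Da default): all cross pairs within
the window are considered in order of increasing |Δm/z| (ties broken by
peak index) and accepted greedily. The score is

$$S = \frac{\sum_{(i,j) \in \text{matched}} I_i^{(a)} I_j^{(b)}}
        {\sqrt{\sum_i I_i^{(a)2}}\sqrt{\sum_j I_j^{(b)2}}} \in [0, 1]$$

with the norms over **all** peaks of both spectra, so unexplained peaks on
either side reduce the score; identical spectra score exactly 1 and
disjoint spectra 0. We use raw intensities with no m/z weighting by
default; the classical weighted variant
$w = I^{0.6}(m/z)^3$ is available through `intensity_power`/`mz_power`,
since published dot-product implementations differ and the choice is
deliberately exposed rather than hidden. Peaks are not
intensity-thresholded before scoring (also exposed as an option for
experimentation). Greedy nearest-Δm/z pairing was chosen over optimal
assignment because it is the field's standard, costs
O(pairs · log pairs), and is testable against an exhaustive oracle; on
well-separated peak lists the two coincide.

### Collision-energy aggregation

Spectra are acquired at CE 10, 20 and 40 V and the library holds one
predicted spectrum per CE. The 3×3 grid of scores per candidate can be
used three ways:

* **approach 1** — only the score where the predicted CE equals the
  experimental CE;
* **approach 2** — sum over the three predicted CE levels for one
  experimental spectrum;
* **approach 3** — approach 2 summed across the experimental CE spectra of
  the same precursor (a composite over the full grid).

By construction approach 2 is the sum of single-cell selections over the
predicted CEs, and approach 3 is the sum of approach-2 aggregates over the
experimental CEs; the test suite asserts these identities exactly. A
candidate lacking a predicted spectrum at some CE contributes nothing for
that cell but is *flagged absent* rather than scored zero in approach 1 —
"not predicted" and "predicted badly" are different statements.

### Ranks, percentiles, quotients

Within one query's candidate list, candidates are ranked by descending
aggregate score (ties by id). The **quotient** is the candidate's score
divided by the maximum score in the list (1 for the top candidate whenever
the maximum is positive); the **percentile** is the linear rank position
`100 (N − rank)/(N − 1)`, which is uniformly distributed over the list by
construction. Quotients inherit the score distribution's shape; in
realistic candidate lists, where most candidates are dissimilar and a few
are similar, that shape is right-skewed — most quotients are small. This
asymmetry is exactly why quotient cutoffs discard more false candidates
than percentile cutoffs at the same TPR.

### Confusion counting and cutoff calibration

Each query contributes one true compound; at a cutoff c on the percentile
or quotient scale a candidate is **retained** when its value is ≥ c (so
c = 0 retains everything). The true compound retained is a TP, dropped an
FN; any other retained candidate an FP, dropped a TN; a true compound the
mass window never retrieved is an FN at every cutoff (conservative, and
keeps TP+FN constant). `roc_sweep()` tallies these on the fixed grids
0, 1, …, 100 (percentile) and 0, 0.01, …, 1 (quotient) — 101 points each —
with TPR = TP/(TP+FN) and FPR = FP/(FP+TN), both non-increasing in the
cutoff, and rates with zero denominators reported as `NA`, never 0 or 1.
`select_global_cutoff()` returns the *largest* cutoff whose TPR meets the
floor (default 0.90): the most stringent filter honouring the floor. The
spec of the selection rule is "a minimum TPR of 0.90"; taking the largest
qualifying cutoff is the natural operating point, since any smaller
qualifying cutoff admits weakly more false positives. `fpr_at_tpr()` reads
FPR at an exact TPR level by linear interpolation between grid points,
which removes the quantization artifact that short candidate lists imprint
on the percentile grid. Percentages in printed summaries use round-half-up
(`round_half_up()`, `pct_round()`) to match the convention of published
tables.

## The synthetic benchmark

The generator (`benchmark_config()`, `generate_bundle()`,
`generate_benchmark()`) emulates a blinded spike-in trial: known compounds
distributed across mixtures, acquired at three CE levels, and matched
against a compound database salted with isobaric decoys. It reproduces the
*statistical structure* the matcher assumes — not fragmentation chemistry
(no bond energies or mechanisms; that is a non-goal).

Defaults (the package's study conditions, fixed once):

| parameter | default | why |
|---|---|---|
| `n_compounds` | 400 | 100 isobar clusters of 4 |
| `n_mixtures` × `n_true_per_mixture` | 5 × 20 | 100 spiked true compounds |
| `isobar_cluster_size` | 4 | every true mass carries 3 decoys inside 10 ppm |
| `isobar_ppm` | 8 | decoys stay retrievable after ±5 ppm precursor jitter |
| `ce_levels` | 10/20/40 V | three-CE acquisition design |
| `fragments_per_compound` | 5–15 | small-molecule MS2 peak counts |
| `decoy_fragment_overlap` | 0.4 | mean shared-fragment fraction (Beta-distributed per decoy) |
| noise: `mz_sigma` | 0.003 Da | Q-TOF-scale fragment mass error |
| noise: `intensity_cv` | 0.2 | multiplicative log-normal intensity noise |
| noise: `dropout_prob` | 0.1 | peaks below detection |
| noise: `contaminant_rate` | 2 | spurious peaks per spectrum (Poisson) |

Compound formulas are random valence-plausible CHNOS compositions with
masses computed from a built-in monoisotopic element table (C 12, H
1.0078250319, N 14.0030740052, O 15.9949146221, S 31.97207069); cluster
seeds occupy distinct nominal masses so clusters never overlap and no two
spiked compounds in one mixture collide in precursor m/z. Decoys either
carry their own formulas with masses jittered into the seed's ppm window
(default; they vanish under formula filtering, the best-case scenario) or
share the seed's formula exactly (`decoy_mode = "shared_formula"`, for
stress-testing formula-filtered evaluation).

Two generator choices matter for realism and were settled by inspecting
the score distributions they induce:

* **Decoy similarity.** Each decoy draws a fraction of its fragment
  positions from its cluster seed's spectrum, the fraction itself drawn
  per decoy from a right-skewed Beta distribution (mean 0.4, concentration
  1.5). Candidate lists therefore contain mostly dissimilar decoys and a
  few similar ones, giving the right-skewed quotient distribution observed
  in practice. A constant overlap instead concentrates decoy scores at
  moderate values and destroys the skew.
* **Precursor lability.** At 10 V the intact precursor survives with an
  ion-current share drawn per compound from Beta(1, 2) (attenuated ×0.3 at
  20 V, absent at 40 V). All isobaric candidates' precursors fall inside
  the fragment window of the observed precursor, so a *fixed* dominant
  precursor peak would hand every decoy a large matched term and compress
  quotients toward 1; variable lability keeps the intact-precursor match
  from dominating the cosine.

Experimental spectra are the predicted spectra of the spiked compounds
corrupted per the noise model (Gaussian m/z jitter, log-normal intensity
noise, per-peak dropout, Poisson contaminants at a low intensity quantile,
±5 ppm precursor jitter). With all noise at zero the experimental spectrum
equals the predicted one and the true compound scores exactly 1. A
spectrum emptied by dropout is regenerated with dropout disabled (logged),
so every truth row has a spectrum. All generation is a pure function of
`(config, seed)`; bundles written to disk are byte-identical across runs.

What passing tests on this benchmark do **not** show: robustness to real
fragmentation-prediction error (systematically wrong intensities, missing
rearrangement ions), retention-time information, adducts beyond
protonation, multiply charged species, isotope patterns, or chimeric
spectra. On real data the matcher's absolute top-1 rates will be much
lower (published composite-score top-1 rates on real spike-in data are
~34% by mass and ~50% by formula); the benchmark validates the *machinery*
— retrieval windows, score algebra, normalization, and cutoff calibration
— not predictor quality.

### The calibration benchmark

Under the default conditions the matcher recovers essentially every true
compound at rank 1; every true quotient is then exactly 1 and both ROC
curves sit at FPR 0, so cutoff calibration is trivial and the
percentile-vs-quotient comparison degenerate. `roc_benchmark_config()` is
a second preset — 800 compounds in clusters of 8, mean decoy overlap 0.6,
and heavier noise (m/z σ 0.012 Da, intensity CV 1.2, dropout 0.55, 8
contaminants) — that pulls top-1 recovery down to roughly 65–80% and moves
the TPR-0.90 operating points into the interior of both curves. On this
benchmark the quotient-based FPR at TPR 0.90 is consistently at or below
the percentile-based FPR, reproducing qualitatively the advantage of
quotient cutoffs that motivates right-skew-aware filtering. The acceptance
script reports both FPRs, computed fresh at run time.

## Worked example

```{r example, eval = FALSE}
bundle <- generate_bundle(benchmark_config(seed = 1))
results <- match_spectra(bundle$spectra, bundle$library,
                         approach = 3, truth = bundle$truth)
topk_summary(results)
cal <- calibrate_cutoff(results, metric = "quotient", min_tpr = 0.90)
glance(cal)
autoplot(cal)
```

Problem sizes were chosen so the full test suite and the acceptance script
each run in minutes on a single CPU: the default benchmark scores 100
queries against clusters of 4 (≈3,600 cosines), the calibration benchmark
100 queries against clusters of 8, and the ROC property tests sweep 1,000
small random fixtures.

## Numerical choices and degenerate inputs

* Duplicate m/z values within a peak list are merged by summing intensity;
  zero-intensity peaks are dropped at parse time; a spectrum with no
  remaining peaks is skipped with a warning.
* An all-zero-intensity spectrum cannot be scored (error, not 0).
* Tie-breaks are deterministic everywhere: peak pairs by (|Δm/z|, index),
  candidate ranks by id, de-duplication winners by spectrum id — fixed
  seeds therefore give byte-identical outputs.
* A single-candidate list has percentile 100 and quotient 1; an all-zero
  score list has all quotients 0.
* If no grid cutoff reaches the TPR floor, `select_global_cutoff()`
  errors and reports the maximum attainable TPR instead of silently
  returning a weaker cutoff.
* The ppm window's denominator, the proton mass constant, the
  de-duplication tolerance, the fragment window, and the dot-product
  weighting are all configuration, not constants, because published
  workflows differ on each.

## Known limitations

* Only \[M+H\]+ and \[M−H\]− adducts; the adduct map is config-extensible
  but nothing else is implemented.
* MGF/MSP dialect support is deliberately narrow (the fields the workflow
  needs); exotic vendor keys ride along in `metadata` untouched.
* Greedy peak pairing is not guaranteed to maximize the matched-intensity
  sum on pathological peak clusters (it is the standard, deterministic
  choice, and equals the exhaustive greedy oracle by construction).
* The evaluation of formula filtering requires a truth table; it is an
  evaluation-mode construct, not something available for true unknowns.
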