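---
title: "Quantifying temporal biomarkers of preclinical SUDEP: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal biomarkers of preclinical SUDEP: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sudepmetrics)
```

## The analysis this package implements

Kv1.1 knockout (*Kcna1*-null) mice model sudden unexpected death in epilepsy
(SUDEP): every knockout dies prematurely, and candidate physiological
biomarkers — disrupted sleep, bradycardia, apnea, intermittent hypoxemia —
emerge in the days before death. Because animals die at widely varying ages,
prospective (age-aligned) averages smear these terminal changes out. The
central analytical device is therefore *retrospective alignment*: every
recording session is re-indexed by days prior to death (PTD) and pooled into
10-day bins, so that the last session before death always lands in bin 1
(1–10 days PTD), the previous in bin 2, and so on.

The package implements that full pipeline — endpoint quantification per
modality, PTD realignment and binning, and the cohort-level statistical
battery — together with a seeded synthetic-study generator that reproduces
the reported cohort structure, so the pipeline is exercisable and testable
end to end without animal recordings.

### PTD conventions

The day of death is PTD 0 and never carries a session; a session is valid
retrospectively only if it precedes death by at least one day, so
`compute_ptd()` rejects `record_day >= death_day` rather than coercing.
Bins are the closed integer ranges $[10(k-1)+1,\, 10k]$, i.e.
`bin = ceiling(ptd / 10)`; a session exactly 10k days before death falls in
bin k (the ceiling rule is one consistent choice — no convention is forced
by the binning description itself).

## The synthetic-study generator

The generator's defaults *are* the study conditions: cohort sizes, survival
moments, the wild-type heart-rate Gaussian, per-bin bradycardic and
hypoxemia fractions, SaO2 means, and apnea rates are set to the published
cohort summaries (see `study_config()`). The subsections below record the
modelling choices where only summary statistics were available.

### Survival times

Only mean ± SEM and n are reported per cohort (KO on standard diet:
57 ± 2 days over n = 22; KO on ketogenic diet: 77 ± 4 over n = 19). The
minimal model reproducing both is a normal with SD = SEM·√n, truncated below
at day 22 (no death before weaning at day 21) and rounded to whole days.
This is a modelling convenience, not a claim about the true shape of murine
survival distributions; consequences are noted under *Limitations*.

### Heart-rate segments

Wild-type segment means are Gaussian (770 ± 43 bpm, SD). Bradycardic
cohorts are modelled as a two-component mixture: the normal component plus a
fixed "low" component at 620 ± 30 bpm chosen to sit clearly below the
684 bpm threshold. Only the mixture *weight* is calibrated — the
below-threshold mass is linear in the weight, so
`calibrate_mixture_weight()` has a closed-form solution and the calibration
is one-dimensional and well-posed. Sessions emit ~16 segments of 25–75
beats, matching the per-subject screening counts.

### Oximetry streams

Eight parameters at 5 Hz for 1 h (18,000 nominal samples). SaO2 is a
two-component mixture: a clean baseline component (SD 1.2%) and a hypoxemic
dip component fixed at 85 ± 3%, i.e. clearly below the 90% demarcation.
Hitting both a target stream mean and a target below-90% fraction requires a
joint solve: the baseline mean is tied to the weight by the mean constraint,
and the weight is found by a 1-D root search on the below-90 mass. That
equation can have two roots — a small-weight solution that parks the
*baseline* at the demarcation (so "hypoxemia" would come from baseline
noise) and a larger-weight solution where hypoxemia comes from the dip
component. The solver searches upward from the minimizer so the dip-driven
root is selected; with a zero fraction target it degenerates to a pure
baseline at the target mean. The per-sample error rate defaults to 0.94 so
that a session's error-free count (~1,080) falls inside the reported
507–1,530 per-subject range. Behaviour labels alternate rest/active blocks;
no behaviour-dependent SaO2 shift is modelled, since the source analysis
found none and pooled behaviours.

### Airflow traces

A quasi-sinusoid at the eupneic rate (default 120 breaths/min, 100 Hz) with
per-breath amplitude jitter (SD 0.05) and small additive sensor noise
(SD 0.005). Injected apneas scale the envelope by 1 − depth over a whole
number of cycles; ground truth records whether each event meets the
operational definition (depth ≥ 0.90 for ≥ 2 complete cycles), so detector
sensitivity and specificity can be scored exactly.

### EEG/EMG epochs

Vigilance states follow a first-order Markov chain over wake/NREM/REM whose
transition matrix is constructed to have the configured occupancy as its
exact stationary distribution (off-diagonal entries proportional to the
destination occupancy; dwell parameter a = 0.15, giving mean bouts of about
a minute at 10 s epochs). Per-epoch band powers are lognormal,
state-conditional: delta power high only in NREM; EMG power high in wake,
intermediate in NREM, low in REM — the same feature geometry the staging
rule assumes. The delta band is fixed at 0.5–4 Hz: the band edges are not
specified by the acquisition description (which band-passes 0.5–40 Hz), and
0.5–4 Hz is the field's standard delta definition. Traces are synthesized
at 2 kHz to match acquisition, but the rate is configurable; the test suite
and examples use 100–200 Hz, which changes nothing about epoch-level band
power geometry and keeps runtimes in seconds.

Seizure epochs superimpose high-amplitude spike trains on both channels and
are flagged in ground truth; they feed the exclusion logic, not the staging
fit.

### What the generator does not emulate

No within-subject correlation across repeated sessions (none is reported to
calibrate against), no circadian modulation, no biophysically realistic
ECG/EEG morphology, and no seizure waveform realism. Passing recovery tests
therefore demonstrates that the pipeline is calibrated and internally
consistent — that it recovers known parameters from data with the reported
statistical structure — not that it would segment arbitrary real-world
recordings correctly.

## Endpoint pipelines: numerical choices

### Seizure burden

Burden per 48 h session is $\sum_i S_i \cdot d_i$ over events with Racine
grade $S_i \in \{1..6\}$ and duration $d_i$; durations are in seconds (the
reporting leaves the unit open; seconds is documented here as the package's
choice). Severity is an input annotation — the package validates grades but
never re-scores, since video adjudication is out of scope. No filtering is
applied to event counts. Burden is not normalized by time.

### Sleep staging

Features per 10 s epoch: mean Hann-tapered periodogram power in 0.5–4 Hz
(EEG) and 10–50 Hz (EMG); the trailing partial epoch is dropped. The
published description says only that principal component analysis
segregated epochs by state, so the partition rule here is the package's
own: log-transform, standardize, project on principal components, and run
3-means with a seeded farthest-point initialization (first centre a seeded
random point, each next centre maximizing the minimal distance to those
chosen). Farthest-point seeding makes the partition deterministic given the
seed and robust to the unequal cluster sizes typical of hypnograms.
Clusters are mapped to states by the band-power rule — highest mean delta
power is NREM; of the remainder, higher mean EMG is wake, the other REM —
so the result is invariant to cluster relabelling, and the ambiguous
"low-to-medium EMG" description of NREM never needs a second threshold.
Degenerate feature variance (e.g. a flat recording) is an error advising
manual staging, not a silent guess. Agreement with generator ground truth
(≥ 95% required, ~100% observed at default separation) is the acceptance
surface for this design.

Epochs overlapping annotated seizure or husbandry-check intervals are
excluded before occupancy; occupancy is normalized to analyzed epochs only,
so wake + NREM + REM = 1 per subject by construction.

### Bradycardia

The wild-type reference pools all clean WT segment means across diets and
sessions (WT-SD and WT-KD rates do not differ, and one reference histogram
with a single 684 bpm cutoff is the published operational definition);
sample SD (n − 1) is used, another unstated detail fixed here. The
threshold is exactly mean − 2·SD, classification is strictly below, and
noisy segments are excluded from numerator and denominator of the
per-subject fraction. With the reference values 770/43 the threshold is
684 bpm exactly.

### Apnea detection

The printed respiratory-cycle formula, "2 × (breaths·min⁻¹ / 60 s)", has
units of frequency, not duration; the package implements the duration of
two complete cycles, 2·60/f seconds, which matches the verbal definition.
The detector references "decrease in airflow" to a running-median baseline
of the preceding 10 breath amplitudes (robust to single deep breaths; no
baseline is named in the source). The breath-amplitude envelope is a
running maximum of |flow| over half a respiratory period: |flow| peaks
every half period, so this window always contains an amplitude extremum
while eroding a sub-threshold run by only half a cycle (a full-period
window would erode a 3-cycle apnea to exactly the 2-cycle minimum and make
detection of the shortest legitimate events a coin flip). Events are the
maximal contiguous intervals with envelope ≤ 10% of baseline lasting at
least two cycles; a depth of exactly 0.90 is included (the definition is
"≥ 90%"), and adjacent events are never merged across super-threshold gaps.
An exhaustive interval-scan oracle in the test suite verifies the run-length
logic sample-for-sample.

### Oximetry

A measurement is error-free only if all eight parameters were acquired — a
sample whose SaO2 was read but another parameter failed is excluded.
Sessions with fewer than 50 error-free measurements are dropped entirely.
Hypoxemia is strictly below 90%. Per-subject fractions *pool* measurements
across the subject's QC-passing sessions within a PTD bin (rather than
averaging per-session fractions); this matches the per-subject
"hypoxemia measurements / total error-free measurements" definition and is
exactly count-additive under stream concatenation, which the tests assert.
Cohort statistics are means of per-subject fractions.

### Survival

Kaplan–Meier curves per KO cohort (WT littermates are euthanized, not
SUDEP, and are excluded from survival analysis); with 100% mortality and no
censoring the restricted mean equals the arithmetic mean of death ages,
which the tests assert on every synthetic cohort. Cohorts are compared with
the log-rank (Mantel–Cox) test. The hazard ratio is the Mantel–Haenszel
O/E form, HR = (O₁/E₁)/(O₂/E₂), with the log-scale confidence interval
SE(log HR) = √(1/E₁ + 1/E₂) — chosen over Cox regression because no method
is named in the source and the O/E form needs no iterative fitting. The
published HR value itself is not a calibration target because it depends on
the unknown shape of the real survival distributions, which the truncated
normal model does not claim to reproduce.

### Statistical battery

Two-way ANOVA uses Type III sums of squares (mortality makes designs
unbalanced; Type III matches the behaviour of the commercial software
family used in this literature) with classical η² = SS_effect/SS_total
(classical vs partial is unstated in the source; classical is chosen and on
balanced designs the SS partition, and hence Ση² = 1 including residual, is
asserted to 1e-9). Šidák adjustment is 1 − (1 − p)^m. Welch's t uses the
Welch–Satterthwaite df. The chi-square test is Pearson without continuity
correction. Kruskal–Wallis is tie-corrected, with Dunn's pairwise z from
pooled ranks and Šidák-adjusted p-values (Šidák rather than Bonferroni for
consistency with the ANOVA family; configurable). A Shapiro–Wilk gate
(α = 0.05) routes comparisons to the rank-based battery when normality
fails, mirroring the stated workflow.

## Determinism and seeding

Every generator is deterministic given (configuration, seed). The pipeline
expands one study seed into per-module substreams by hashing a stream label
(subject, modality, session day), so adding a modality never perturbs
another modality's draws; identical (config, seed) reproduce byte-identical
endpoint tables, which the tests verify. All derived seeds stay below 2³¹.

## Problem sizes

The test suite and examples run the pipeline at sizes chosen to exercise
every code path at full statistical fidelity while completing in minutes:
staging-recovery and epoch-conservation checks use the full 7 h window
(2,520 epochs) at 100 Hz; oximetry recovery uses 6–12 subjects × ~1,080
error-free samples × 100 replicates; apnea recovery uses 12 subjects ×
3-minute traces × 100 replicates; detector-oracle equivalence uses 200
random 60 s traces at 50 Hz; survival recovery uses 120 replicates of the
full cohort sizes; type-I-error checks use 2,000 null replicates per test.
Larger sizes change none of the verified quantities beyond Monte-Carlo
error.

## Known limitations

* The truncated-normal survival model reproduces reported means and SEMs
  but not necessarily the real hazard shape; derived quantities that depend
  on distribution shape (notably the hazard ratio) should not be compared
  against published point values.
* Staging is a two-feature, three-cluster partition; real recordings with
  artefacts, transitional epochs, or theta-dominated REM may need richer
  features or manual review. The semi-automated workflow it emulates also
  included manual video verification, which has no synthetic counterpart.
* The apnea detector assumes a roughly stationary eupneic rate per session
  (rate is estimated from the leading 30 s when not supplied); marked
  within-session rate drift would blur the cycle-based windows.
* Noise screening of real ECG segments is provided only as a simple
  amplitude heuristic; in the synthetic pipeline noisiness is a generator
  flag, as manual review is the reference method.
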