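---
title: "Dynamic co-activation analysis of executive networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic co-activation analysis of executive networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdyn)
library(dplyr)
```

## The problem

After glioma resection, short-term attentional and executive deficits are
common, and they frequently resolve by three months. A clinically useful
question is whether the *pre-surgical* temporal dynamics of the executive
control networks — the fronto-parietal network (FPN) and the dorsal attention
network (DAN) — predict who will show a deficit one week after surgery and
how performance evolves to the three-month follow-up.

capdyn implements a complete analysis chain for this question on parcel-level
resting-state BOLD time series:

1. **Co-activation pattern (CAP) extraction.** Frames in which a seed system
   is most active are clustered into a small number of recurring whole-cortex
   co-(de)activation states.
2. **Temporal state metrics.** Each subject-session state sequence is
   summarized by occurrence, dwell duration, resilience (self-transition
   probability), IN-/OUT-degree (shares of between-state switches) and
   betweenness centrality on the transition graph.
3. **Brain–behavior inference.** Longitudinal changes in these metrics are
   related to changes in neuropsychological scores (Trail Making Test A, B,
   B−A; attentional matrices) by paired tests, correlations, a grouped
   behavioral partial least squares correlation (PLSC), and a suite of
   linear, logistic and random-intercept mixed models.

Because patient-level imaging data of this kind is not openly distributable,
the package ships a synthetic cohort generator that emulates the study
design; every stage of the pipeline is exercised and benchmarked on it.

## The synthetic cohort generator

The generator is a hidden-Markov co-activation model. A cohort has
`n_subjects = 22` subjects scanned at two sessions (`pre`, `post3m`) with
`T = 180` frames of `P = 90` parcels at `TR = 2` s — desk-scale defaults for
the imaging dimensions, chosen for fast, reproducible benchmarking rather
than as a claim about any particular acquisition. Each frame is in one of
`K = 4` co-activation states or a baseline state 0:

* a CAP frame emits `a_t * map_s + noise` with `a_t ~ N(1.5, 0.5)` and unit
  parcel noise; the per-frame spatial correlation with the state map
  (about 0.75) is deliberately generous relative to single real fMRI frames,
  which keeps the benchmark clean while still forcing the clustering to work;
* the baseline emits pure noise, which makes "suprathreshold frame"
  well defined in the generator;
* all state maps load positively on a designated 12-parcel seed region, so
  seed-driven frame selection preferentially captures CAP frames;
* no hemodynamic convolution is applied: CAP analysis treats frames as
  instantaneous samples, and convolution would only blur state boundaries.

The default transition matrix makes CAP states sticky (self-transition 0.6),
returns them to baseline with probability 0.2, and routes most of the
remaining mass along a preferred next state. The uneven routing matters:
with uniform switching, every shortest path on the transition graph is a
direct edge and betweenness centrality degenerates to exactly zero for all
states; preferred transition routes are also what empirical state analyses
report.

Two planted effects connect dynamics to behavior:

* **Group effect.** A deficit subgroup (10 of 22) has its FPN-like state
  destabilized (self-transition ×0.6) and receives more switching into the
  state (×1.6), at both sessions — "a less stable, more switching FPN". The
  effect size was fixed once so that a 22-subject logistic regression of
  deficit status on pre-surgical OUT-degree detects it in most replicate
  cohorts, i.e. the planted effect is at the edge of what the study's sample
  size can resolve.
* **Latent axis.** Per-subject score changes at 3 months are driven by a
  single standardized combination of the FPN state's occurrence and
  resilience changes, with negative loadings on TMT times (better dynamics,
  faster completion) and a positive loading on the attentional matrices.
  Loadings were calibrated once so the leading PLSC latent correlation sits
  in the 0.8–0.9 range typical of reported brain–behavior saliences.
  One week post-surgery the deficit group's scores are shifted past their
  clinical cutoffs; at 3 months scores regress to the pre-surgical level in
  expectation. TMT B−A is always computed as TMT-B − TMT-A, never drawn.

One integer seed governs a whole cohort; per-subject streams are derived by
stable hashing of (seed, subject, session), so enlarging a cohort never
perturbs existing subjects.

What the generator does **not** emulate: vascular and motion artifacts,
spatial autocorrelation of parcels, lesion-induced signal dropout,
hemodynamic lag, site effects. Passing recovery benchmarks on this generator
shows the pipeline is correct and well calibrated, not that effect sizes of
this magnitude are typical of real glioma cohorts.

## CAP extraction choices

* **Normalization.** Each run is z-scored per parcel over usable frames
  (population SD). Censored frames pass through untouched and are excluded
  everywhere downstream.
* **Frame selection.** Default: the top 15% of usable frames by seed
  z-score (the dominant convention in the CAP literature; the threshold is
  not standardized in the field, so it is a config knob). A z-threshold mode
  and a `polarity = "both"` mode (sign-flipped co-deactivation frames) are
  available. Co-deactivation structure is otherwise captured in the negative
  values of the CAP maps themselves.
* **Clustering.** k-means with distance 1 − Pearson correlation
  (amplitude-invariant pattern matching), greedy k-means++ seeding,
  20 restarts, 300-iteration cap. Internally frames are row-centered and
  unit-normalized, making each Lloyd step a spherical k-means update whose
  objective provably never increases (asserted at every iteration). Maps are
  plain means of member frames; CAPs are renumbered by descending member
  count with deterministic tie-breaks, so a fixed seed gives bit-identical
  results. Euclidean distance is not offered: amplitude already lives in a
  separate generative parameter, and correlation distance is what the CAP
  literature uses.
* **Model-order selection.** Consensus clustering: for each candidate k,
  k-means is run on 100 random 80% subsamples; the consensus of a frame pair
  is its co-assignment rate among co-inclusions; PAC (proportion of
  ambiguous clustering, consensus strictly between 0.1 and 0.9) is minimized,
  ties toward smaller k. Each subsample is clustered **once** (no restarts):
  with well-separated clusters, restarting to the global optimum makes every
  subsample agree on the same merged partition even for wrong k, so
  under-partitioning would spuriously show PAC = 0; a single run per
  subsample lets the resampling express exactly the ambiguity PAC is meant
  to measure.
* **Assignment.** Frames passing the selection policy take the label of the
  maximum-correlation CAP (ties to the lower index); other usable frames are
  baseline; censored frames stay censored. Note that occurrence estimates
  from assigned sequences are *relative* (the selection caps labeled frames
  at the selection fraction), which attenuates subject-level metric
  differences relative to the generative sequences — visible in the
  end-to-end example below.

## Temporal metrics

For a sequence over states {0, …, K} (0 = baseline participates in all
transitions and normalizations; statistics are reported for CAP states):

* occurrence — fraction of usable frames (sums to 1 including baseline);
* duration — mean dwell length × TR, dwells split at censored gaps;
* resilience — self-transition probability; the dwell-based alternative is
  deliberately not the default because self-transition probability is the
  quantity the prediction models use;
* IN-/OUT-degree — column/row sums of off-diagonal transition counts over
  total between-state switches; each sums to 1 when any switch exists, so
  values are comparable across subjects with different switch rates. By flow
  balance a state is entered about as often as it is left, so IN- and
  OUT-degree are nearly collinear per subject — they are therefore never
  placed together in one regression design;
* betweenness — on the directed graph of observed between-state transitions
  with edge length −log(probability) (high-probability routes are short,
  and lengths add along paths). Shortest paths are counted by Brandes'
  algorithm with an explicit tie tolerance, because probability-derived
  weights produce exactly tied path lengths that naive floating-point
  comparison splits arbitrarily. Normalization is the average, over ordered
  connected source–target pairs excluding the node, of the fraction of
  shortest paths through it: a pure relay on a single chain scores 1, and
  values stay in [0, 1] regardless of how sparse the graph is.

Longitudinal change is `post3m − pre`, defined only for subjects with both
sessions.

## Deficit classification

A subject has a deficit at a timepoint if **any** score is on the impaired
side of its clinical cutoff after orientation normalization: above cutoff
for time scores (higher = worse), below for accuracy scores. A score exactly
at its cutoff is *not* impaired — the dichotomy is strict, and tests pin
this boundary. Classification happens on the adjusted scale; normative
age/education adjustment is upstream of this package.

## Grouped behavioral PLSC

Brain and behavior blocks are z-scored within group, the group-wise
behavior-by-brain correlation matrices are stacked, and the stack is
decomposed by SVD. Within-group standardization removes absolute group
differences, so latent components express *covariance patterns* that may
differ between groups. Sign indeterminacy is fixed by making the
largest-magnitude brain salience of each component positive.

Inference choices, each of which we validated by simulation:

* **Permutation.** Behavior rows are shuffled within group (the grouped
  analysis' exchangeability unit); p-values use the add-one estimator and
  compare raw singular values per component index. A Procrustes flag exists
  but is **off** for permutations: aligning permuted saliences to the
  observed basis before comparing breaks the exchangeability of the leading
  singular value and, in our null simulations, inflated its rejection rate
  roughly tenfold. Raw comparison is calibrated (leading-LC type-I ≈ 3–5%
  at α = 0.05).
* **Multiplicity.** All `min(G·C, B)` components are tested, so counting
  "significant components" on raw p-values finds at least one spurious extra
  component in roughly a fifth of cohorts. `plsc_permutation()` therefore
  also reports Bonferroni-adjusted p-values, and statements about *how many*
  axes exist should use them; a genuinely strong first axis (raw p ≈ 0.001)
  is unaffected.
* **Bootstrap.** Subjects are resampled with replacement within group; each
  refit is Procrustes-aligned to the original basis (here alignment is the
  right tool — the question is stability of the observed axes); 5th–95th
  percentile intervals that exclude zero flag robust saliences. Degenerate
  resamples (a constant column) are redrawn, at most 100 times.

## Outcome models

Predictors are the FPN state's metrics, standardized so coefficients are
comparable across metrics. The suite follows the clinical questions above
and is overridable:

1. mixed model per TMT score: score at pre/3m against deficit × session ×
   betweenness plus occurrence and resilience, with a random intercept per
   subject. Random slopes are deliberately absent — two or three timepoints
   per subject cannot support them. Inference is Wald-t with residual
   degrees of freedom; at this design size the difference from Satterthwaite
   is negligible and is documented as an approximation.
2. logistic: 1-week deficit against pre-surgical OUT-degree (and a companion
   IN-degree fit; see the collinearity note above). Logistic terms carry
   likelihood-ratio p-values alongside Wald: with 22 subjects the Wald
   statistic is non-monotone in the effect (Hauck–Donner), and in our
   simulations the LRT had uniformly better power with intact type-I error.
3. logistic: deficit against pre-surgical occurrence + resilience
   (stability).
4. linear per score: 1-week score against pre-surgical IN-degree.
5. linear per executive score: 3-month score against pre-surgical
   OUT-degree.

The random-intercept model is fitted by REML via lme4; at zero
between-subject variance it reproduces OLS, and on balanced designs it
matches the closed-form ANOVA estimators (both are tested).

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds through a stable hash;
  library code never touches the caller's RNG state.
* Time series are serialized at 17 significant digits and parsed by strtod,
  so the TSV round-trip is bit-exact; reruns of the whole pipeline with the
  same config produce bit-identical run directories (hash-verified in the
  tests).
* Degenerate inputs have defined behavior: zero-variance parcels error (or
  drop on request), zero-variance frames fall back to baseline with a
  warning, empty clusters trigger reseeding, never-visited states report
  zero metrics with a `visited` flag, complete separation in logistic fits
  raises a flag instead of a silent divergence.

## Benchmarks computed by the test suite

On default synthetic cohorts the suite verifies: consensus selection of the
planted model order k = 4 over k ∈ {2..8}; recovery of the planted CAP maps
with mean correlation ≥ 0.90; occurrence/resilience estimation within ±0.05
of the chain values at T = 600; detection of exactly one significant latent
component in ≥ 8 of 10 replicate cohorts; betweenness, k-means, PLSC and
REML agreement with exhaustive/closed-form oracles; and type-I calibration
of the paired t-test, PLSC permutation and logistic LRT within [0.02, 0.08]
at α = 0.05. Problem sizes (10–250 replicates, 99–1000 permutations) were
chosen to keep Monte-Carlo error well inside each acceptance band at
desk-scale runtime.

## A small end-to-end run

```{r pipeline, eval = FALSE}
run <- run_pipeline(list(rng_seed = 11, n_resamples = 50,
  n_perm = 500, n_boot = 200))
run$extraction$consensus$selected_k   # 4
tidy(run$extraction$consensus)        # PAC per candidate order
run$plsc$permutation                  # LC table: raw and adjusted p
tidy(run$suite$fits$model2_out)       # deficit ~ pre-surgical OUT-degree
```

Note the attenuation discussed above: on assigned (rather than generative)
sequences the subject-level metric changes are noisier, so the end-to-end
PLSC association is weaker than the planted-axis benchmark — exactly the
behavior one should expect when metric estimation error is added on top of a
finite-sample association.

## Known limitations

* Betweenness on sparsely labeled sequences is frequently zero and is
  dropped from the PLSC block automatically when constant within a group.
* The permutation test's per-index singular-value comparison is
  conservative/anti-conservative in small, structured blocks; the
  Bonferroni-adjusted count is the defensible statement about the number of
  axes.
* Wald degrees of freedom in the mixed model are a residual-df
  approximation.
* The generator's noise model is white; real parcel noise is spatially and
  temporally structured.
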