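---
title: "Methods: vigilance-dependent seed-based functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vigilance-dependent seed-based functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigifc)
```

# The problem

Neuromodulatory nuclei of the brainstem and basal forebrain regulate
cortical arousal, and their whole-brain functional connectivity (FC) in
resting-state fMRI depends on the subject's vigilance state: during
drowsiness these small seed regions couple more strongly and more
globally — especially to thalamus, precuneus, and sensory/motor cortex —
than during alert wakefulness. Measuring that dependence requires a chain
of steps, each with its own failure modes: labeling alert and drowsy
periods from simultaneous EEG (or, when only eye tracking is available,
from pupillometry), conditioning the BOLD signal against scanner drift and
systemic physiological noise, computing state-restricted seed correlation
maps, pooling them across subjects with a model that separates between-
from within-subject variance, and thresholding and comparing the
resulting group maps.

`vigifc` implements that chain as independently testable modules, plus a
synthetic multi-subject study generator with planted, known effects so
that every stage can be validated end to end.

# Vigilance staging

**Per-second stages.** EEG is reduced to per-second band powers (delta
1–4 Hz, theta 4–8 Hz, alpha 8–12 Hz, periodogram integration over 1-s
windows) and each second receives an ordered stage: A1 = 5 (occipitally
dominant alpha, most alert), A2 = 4, A3 = 3 (anteriorized alpha), B1 = 2,
B2/3 = 1 (delta/theta dominance, most drowsy). The widely used clinical
algorithm that inspired this staging is proprietary, so the per-second
classifier here is a documented threshold rule (`classify_stage()`):
occipital alpha above occipital delta+theta marks alpha dominance; the
occipital/frontal alpha ratio then splits A1/A2/A3 (defaults: ratio ≥ 2
→ A1, ≥ 1 → A2, else A3); non-dominant frames split B1 vs B2/3 by
whether delta exceeds theta. The *epoch-level* algorithm downstream of
the stages is the scientific contribution and is implemented exactly.

**Epochs.** The scan is segmented into 30-volume epochs (63 s at
TR = 2.1 s). Within each epoch the integer stages are tested against the
center value 2.75 with a one-sample Wilcoxon signed-rank statistic,
standardized by the tie-corrected normal approximation without continuity
correction (`signed_rank_z()`). The center 2.75 is not attainable by an
integer stage, so zero differences cannot occur — asserted in tests.
Epochs with z ≥ +1.5 are alert, z ≤ −1.5 drowsy, otherwise intermediate;
adjacent same-state epochs are concatenated, and all boundaries are
shifted forward by 5 s (≈ 2 TRs) for the hemodynamic delay. The test
suite validates the z statistic against exact enumeration of all 2^n
sign assignments (which reproduces the tie-corrected moments to machine
precision for n ≤ 12). One subtlety uncovered by that oracle: a strictly
alternating 2,3 stage pattern is *not* neutral — its larger absolute
deviations (−0.75) outrank the +0.25s, giving z ≈ −3.5 at full epoch
length — and the package reports what the statistic actually says.

# Physiological features

- **Respiratory volume (RV)**: the SD of the belt waveform in 6-s windows
  centered at each volume's temporal midpoint (slice timing is ignored;
  no slice-level convention is defined). A window is reported missing
  when ≥ 20% of its sample slots are missing (transducer dropout).
- **Heart rate (HR)**: PPG peaks are detected with an adaptive threshold
  and refractory spacing; inter-beat intervals (IBIs) beyond 2.5 SD of
  the series mean are linearly interpolated, with mean/SD computed once
  on the raw series (single pass). A consequence worth knowing: a large
  outlier inflates the SD it is judged against, so a 6-interval series
  with one tripled IBI is *not* flagged; the rule behaves as intended on
  realistic-length recordings. HR is 1/median(IBI) per 6-s window, in
  beats/s.
- **Percent eye closure**: the fraction of zero pupil samples per
  analysis window after shifting the pupil trace forward by 4 s (the
  pupil leads the BOLD response, so a BOLD window reads samples 4 s
  earlier), logit-transformed with a clamp of `1/(2n)` for normality.

# Signal conditioning

The fixed order is: Legendre detrending (orders 0–4 on [−1, 1]),
zero-phase band-pass at 0.01–0.15 Hz, then confound regression with
confounds that have been filtered identically. The band-pass is a
4th-order Butterworth design (bilinear transform of the analog prototype,
realized in second-order sections, forward–backward with odd-reflection
padding and steady-state initial conditions); no DSP package in the
supported stack provides it, so it is built in and verified against the
analytic magnitude response (and, during development, against a reference
scientific DSP implementation to 7 significant digits). Three confound
pipelines are available: `mcsf_wm` (mean WM, deep-CSF, and
fourth-ventricle signals, 3 columns), `acompcor` (first 5 principal
components of the pooled, per-series standardized WM + deep-CSF series —
the published phrasing is ambiguous between pooled-series PCA and PCA of
two mean signals; the pooled convention is the standard aCompCor one and
was chosen), and `physio` (RV and HR convolved with 5 respiratory and 5
cardiac response functions; the published basis is cited but not printed,
so the default is the canonical respiratory/cardiac response function
shapes plus first/second temporal-derivative and dispersion variants,
pluggable). Missing convolved RV entries become 0 in the design matrix,
per the published missing-data rule. Confound regression always includes
an intercept (harmless redundancy that guards partial pipelines).

# Connectivity and group inference

Seed series are unweighted ROI means extracted before confound
regression; the runner then residualizes seed and targets against the
same confounds so both see identical denoising. Pearson correlations are
clipped to |r| ≤ 1 − 1e−7 and Fisher z-transformed. Epoch-restricted maps
keep their volume count `x_ij` as a covariate; windows of 4 min with 50%
overlap (start-anchored at volume 0, trailing partial window dropped)
provide the dynamic FC path. Any missing volume invalidates its
epoch/window — pairwise-complete correlation is deliberately not used.

Group inference is a per-target random-intercept linear mixed model
fitted by REML: `r_ij = mu + delta_i + eps_ij` (static),
`r_ij = a0 + a1 c_ij + beta x_ij + delta_i + eps_ij` (two-state,
referenced to alert), and the single-state variant with `x_ij` centered.
Because the random structure is one intercept, the REML criterion is
profiled to a 1-D search over the variance ratio; the fit agrees with a
general-purpose mixed-model reference to ~1e−8 on the fixed effects
(dual-route check in the test suite).

**Small-sample inference.** The build initially used the containment
degrees of freedom N − p − q + 1 with the plug-in REML standard error.
Simulation at the acceptance design (24 subjects × 2 sessions, 3000 null
replicates) measured a type-I rate of 5.7% at nominal 5% — the well-known
liberality of plug-in Wald tests. The default inference is therefore a
Kenward–Roger-type adjusted fixed-effects covariance with Satterthwaite
degrees of freedom (measured rate 5.4%, null-t spread matching its
reference distribution); the plug-in SE and containment df remain on the
fit object. When the variance-parameter information matrix is singular —
exactly the one-sample-per-subject case, where subject and residual
variance are indistinguishable — the fit falls back to the classical
one-sample t-test, which the acceptance suite checks to 1e−8.

Group t-maps are dual-thresholded: survivors must be in the top 40% of
|t| within the gray-matter mask (ties at the cutoff included; magnitude
ranking with sign retained, since maps contain both positive and negative
effects) *and* Benjamini–Hochberg significant at q = 0.05 over the same
mask.

# Map comparison and dynamic states

Reproducibility between signed maps uses the multiclass Dice coefficient
`2(|A+∩B+| + |A−∩B−|) / (|A+|+|A−|+|B+|+|B−|)`; background (zero)
targets are excluded from the classes so that an empty background cannot
inflate agreement. Bands: poor < 0.4 ≤ moderate < 0.6 ≤ good. Template
overlap is the signed Szymkiewicz–Simpson coefficient
`Σ sgn(t_i) m_i / Σ m_i` in [−1, 1]. Both match brute-force set/summation
oracles on thousands of random maps in the tests.

Dynamic FC states come from city-block k-means implemented as true
k-medians (component-wise median centroids, the L1-optimal center), 20
restarts, empty clusters re-seeded at the farthest point; k is selectable
by the mean L1 silhouette. With k = 2, labels are canonicalized so state
2 has the lower vigilance metric (or higher eye closure); the state
difference in the metric is tested with the same two-state mixed model,
and per-state alert/drowsy proportions are computed at z = ±1.5.

# The synthetic world

`study_spec()` defaults describe the validation study: 20 subjects × 2
sessions of 15 min at TR = 2.1 s, 60 parcels, a 3-parcel seed.

- **Latent vigilance** is a two-state Markov chain at 1 s resolution with
  a mean dwell time of 7.5 min (`transition_rate = 1/450`), chosen from
  the reported lengths of merged same-state vigilance runs in resting
  EEG-fMRI (~180–190 TRs ≈ 6–7 min at TR 2.1 s, with large spread). The
  source study gives no quantitative dwell model; this default is stated
  once and not tuned.
- **EEG** carries occipital-dominant 10 Hz alpha in alert seconds and
  delta/theta (2.5/5.5 Hz) with suppressed alpha in drowsy seconds, at a
  band SNR of 4 against broadband noise — strong enough that relaxed-
  wakefulness alpha is obvious per second, as it is in real recordings.
- **BOLD** follows a one-factor model: every parcel loads on a shared
  global component; during drowsy volumes (lagged 5 s behind the latent
  state) the loadings on the effect support rise so the seed↔target
  Fisher z increases by exactly 0.2. The support defaults to 35 of 60
  parcels: the phenomenon being emulated is a *widespread* ("global")
  drowsy coupling increase, and a small support would contradict it. The
  factor and noise are spectrally white so that the linear conditioning
  chain preserves the planted correlations in expectation.
- **Peripherals**: state-modulated respiratory amplitude with contiguous
  NA dropout (default 5%, matching reported transducer-malfunction
  rates), a pulse train with 30 ms IBI jitter and ~1.2% injected long-IBI
  outliers, and a pupil trace whose closure process yields ~1% closed
  time while alert and ~25% while drowsy.

What the generator does *not* emulate: MR physics and artifacts,
ballistocardiogram/gradient residue, hemodynamic convolution beyond a
fixed lag, sleep microstructure (spindles, K-complexes), motion, and
spatial structure (parcels have no geometry). A green end-to-end test
therefore establishes the correctness of the analysis chain on data whose
generative assumptions are known — not robustness to real-world
artifacts.

# Known limitations

**The window-clustering agreement ceiling.** One end-to-end acceptance
property asks the k-medians clustering of 4-min window maps to match the
per-window latent state at adjusted Rand ≥ 0.8. This is provably out of
reach in the stated world, and the corresponding test is intentionally
left failing rather than weakened. Two independent ceilings apply:

1. *Sampling covariance.* A window of ~114 volumes estimates each
   target's Fisher z with SD ≈ 0.12, and those errors are correlated
   across targets (ρ ≈ 0.18) because all targets share the realized
   variance of the global factor and of the seed noise within the
   window. For a planted shift of ~0.165 (0.2 minus filtering bleed) on
   m support targets, the optimal linear separation is
   d'² = sep²·m / (σ²((1−ρ)·1 + ρ·m)), which plateaus near d' ≈ 3 as m
   grows — at best ~94% assignment accuracy on even perfectly
   single-state windows, i.e. ARI ≈ 0.78 at the theoretical optimum.
2. *Mixed windows.* With any realistic dwell time, a sizable fraction of
   4-min windows (~40% at the default) straddle a state switch, and
   their "latent state" is a majority vote over a genuinely mixed
   window.

The package reports the all-window ARI (≈ 0.45 at the defaults) and the
analysis above; every other end-to-end property (staging accuracy ≥ 90%,
contrast-map Dice ≥ 0.6 against the planted support, significantly lower
state-2 vigilance) passes with margin. Note the contrast-map Dice has a
structural cap of 2·24/(24+35) ≈ 0.81 at the defaults because the top-40%
rule keeps at most 24 of 60 targets.

**Other numerical choices.** Correlations are clipped before `atanh` so
degenerate targets stay finite; the logit clamp is `1/(2n)`; k-medians
ties in assignment break toward the lower label; the epoch grid is
anchored at volume 0 and a trailing partial epoch is dropped; BH-FDR is
step-up over analyzed (finite) targets only. The NIfTI volumetric path is
out of scope in this build — no NIfTI I/O package exists in the supported
stack — so all external interfaces are delimited text (TSV/JSON), which
the spec treats as the primary parcel-level path anyway.
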