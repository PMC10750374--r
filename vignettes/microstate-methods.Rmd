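---
title: "Models and methods: EEG microstates, band power, and the residual-inhibition study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package computes

`mstateri` analyzes multichannel resting-state EEG from a two-group
(tailor-made notched music training, TMNMT, vs. placebo music), three-condition
(before, during, and after acoustic stimulation) residual-inhibition study of
tinnitus. Two complementary characterizations of the resting EEG are computed:

* **Band power** — Welch power spectral density per channel, summarized as
  dB (`10 log10` of microvolts-squared per hertz) in nine canonical bands:
  delta (0.5–4 Hz), theta (4–8), alpha1 (8–10), alpha2 (10–13), beta1
  (13–18), beta2 (18–21), beta3 (21–30), gamma1 (30–45), gamma2 (55–100).
  The 45–55 Hz gap avoids the power-line region.
* **Microstates** — quasi-stable scalp potential topographies (on the order
  of 60–120 ms) treated as discrete brain functional states. The analysis
  derives a small set of template maps from the data, assigns every time
  point to one template, and summarizes the resulting symbol sequence by
  per-class mean duration, occurrence rate, time coverage, and the
  transition-probability syntax between classes.

Because no participant EEG is available, the package ships a first-class
synthetic-study generator with complete ground truth. Every downstream claim
in the test suite is checked against that ground truth or against an
independent analytic/brute-force oracle.

## The microstate model and its estimation pipeline

At each time point the referenced scalp potential is a vector
$V(t) \in \mathbb{R}^N$ over $N$ electrodes. The global field power

$$\mathrm{GFP}(t) = \sqrt{\tfrac{1}{N}\sum_{i=1}^N\bigl(V_i(t) - \bar V(t)\bigr)^2}$$

is the spatial standard deviation of the topography; it is
reference-independent, and its local maxima are the time points of highest
signal-to-noise ratio at which the topography is most stable. The pipeline:

1. extracts the topographies at GFP peaks;
2. clusters them, **ignoring polarity**, with atomize-and-agglomerate
   hierarchical clustering (AAHC): every map starts as its own cluster, and
   at each step the cluster contributing least to the global explained
   variance is dissolved and its members reassigned by maximal absolute
   spatial correlation. The cluster map is the first principal orientation
   of its members (sign-free), and the contribution of a cluster is the
   GFP-weighted sum of squared correlations of its members with that map.
   AAHC is deterministic and yields a nested sequence of solutions, which
   is also how `choose_k()` obtains every candidate `k` in one pass. A
   polarity-invariant modified k-means is provided as a cross-check;
3. selects the number of classes with the Krzanowski–Lai (KL) criterion
   (relative change of the dimension-adjusted dispersion curve), reporting
   the cross-validation criterion
   $\hat\sigma^2\,\bigl((N-1)/(N-1-k)\bigr)^2$ alongside. The study
   pipeline fixes `k = 4` (classes A–D), the canonical choice for
   resting-state EEG; `choose_k()` is exposed but not used to vary `k` per
   subject;
4. derives templates at three levels: per recording (subject level), per
   subgroup — group × condition — from the pooled subject maps, and a grand
   set from all subject maps. Grand clusters are labelled A–D in order of
   decreasing contribution; group and subject sets inherit labels by greedy
   best-correlation matching to the grand set;
5. back-fits: every GFP peak takes the label of the template with maximal
   absolute spatial correlation, and every remaining sample the label of
   its nearest peak (nearest-neighbor interpolation; ties go to the earlier
   peak). No temporal smoothing or minimum-duration rejection is applied
   afterwards — fidelity to the stated procedure was preferred over the
   many post-processing variants in the literature;
6. computes per-epoch metrics (mean run duration in ms, occurrences per
   second, coverage fraction) averaged over epochs with equal weights, and
   run-to-run transition counts row-normalized into conditional
   probabilities. Transitions never cross epoch boundaries. Reported
   transition probabilities are conditional (each row with outgoing
   transitions sums to 1); published tables in this literature do not
   always follow that convention and are not reverse-engineered.

## Preprocessing

The deterministic chain is: resample to the target rate (Fourier method;
spectrum truncation is the anti-alias step), zero-phase windowed-sinc FIR
band-pass 0.5–100 Hz with band-stop notches at 50 and 100 Hz (Hamming
window, order ≈ 3.3·fs/transition width, applied forward–backward), common
average reference, segmentation into 2-s epochs, and rejection of any epoch
containing a sample beyond ±100 µV. The microstate branch additionally
band-passes 2–20 Hz. Independent-component artifact removal and spherical
channel interpolation are deliberately out of scope: the synthetic data
contain no blinks or broken channels.

Numerical notes: edge padding for the zero-phase filter uses *even*
reflection — for zero-mean oscillatory signals this continues every
sinusoid with at most a phase error, whereas odd reflection injects a step
whose pass-band ringing is visible with kernels this long. Epoch boundaries
discard a trailing partial epoch. Filtering and average referencing are
both linear, so their order is immaterial (verified to 1e-6 RMS).

## The synthetic world

`generate_study()` renders one recording per subject and condition as

$$X(t) = s_r\,E(t)\,T_{z(t)} + \eta(t) + \textstyle\sum_b A_b\, w_b \sin(2\pi f_b t + \phi_b)$$

* $T_1..T_k$ are spatially smooth, zero-mean, unit-GFP template maps (a
  Gaussian process over the electrode positions, orthogonalized). Exact
  orthogonality is an idealization — real templates are merely weakly
  correlated — chosen so the generator satisfies its near-orthogonality
  contract by construction.
* $z(t)$ is a semi-Markov state sequence. Dwell times follow a
  **truncated-geometric law**: a minimum dwell (default 30 ms, capped at
  half the state mean) plus a geometric tail tuned so the mean equals the
  requested per-state mean. The truncation matters: with a pure geometric
  law a sizeable fraction of runs is shorter than the GFP-peak spacing, and
  back-fitted durations overshoot the generative means by 15–30% while
  occurrences undershoot — the generator would contradict the package's own
  recovery contract. A minimum dwell is also the more faithful reading of
  "quasi-stable" topographies. The successor state is uniform over the
  other states, so self-transitions cannot occur.
* $s_r = \pm 1$ is a per-run polarity sign, exercising the
  polarity-invariance contract of the entire analysis path.
* $E(t)$ is the GFP envelope: a rectified 5 Hz sinusoid plus a constant
  floor (default 0.2 of the scale), so GFP peaks are well defined and GFP
  never vanishes. Sensor noise $\eta$ (white, per-channel) makes the
  *observed* GFP peak train dense (every few samples), which is what real
  broadband EEG looks like; the signal-to-noise ratio of the defaults
  (scale 9 µV, noise 2 µV) is ≈ 4 in the RMS sense.
* Oscillations are sinusoids at a frequency drawn uniformly inside a band,
  with a fixed sum-to-zero spatial weight pattern of unit mean square, so
  they survive average referencing and contribute `A^2/2` of mean per-
  channel band power. Injected group × condition effects scale oscillation
  amplitudes in dB and state mean-durations multiplicatively; per-subject
  log-normal random effects (duration SD 0.08, gain SD 1 dB) provide
  between-subject variability at magnitudes typical of test–retest EEG.
* Questionnaire scores (THI, TFI, VAS, residual-inhibition intensity on a
  −5..5 Likert scale and duration in seconds) are Gaussian with the
  group-level summary statistics reported for this design, clamped to the
  instrument ranges. The generator exposes, but does not assume, any
  coupling between scores and EEG parameters.

What a green test does **not** establish: the generator has no volume-
conductor forward model, no 1/f background, no blink/muscle artifacts, no
non-stationarity across the recording, and its rhythms are single sinusoids
rather than bursting band-limited noise. Results about detection power
therefore speak to the pipeline's statistical machinery, not to real-EEG
effect sizes.

## Statistics

All tests are implemented from their definitional formulas (and verified
against independent oracles): pooled-variance Student t (reproducing the
printed between-group questionnaire comparison to 3 decimals; a Welch flag
is exposed), paired t, Pearson chi-squared with optional Yates correction,
balanced split-plot (mixed-design) ANOVA via the classical sum-of-squares
decomposition with no sphericity correction, one-way simple effects, and
step-up Benjamini–Hochberg FDR adjustment. FDR families follow the table
granularity of the report: e.g. all condition contrasts of one group and
one metric form one family, and family membership is visible in the output
tables.

One modelling quirk is inherited deliberately: the source analysis treats
the three conditions of a group as *between*-subject levels in its
repeated-measures ANOVA even though they are the same participants. The
pipeline mirrors this by using subject × condition as the observational
unit in the balanced mixed ANOVA (class as the within factor). The paired
condition contrasts do respect the within-subject pairing.

Back-fitting defaults to the subgroup (group-level) template sets, the
reading most consistent with the described procedure; a `backfit_level =
"grand"` switch is available, and measurements on synthetic studies show
the two choices give nearly identical paired contrasts.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| band-pass | 0.5–100 | Hz | broadband analysis band |
| notches | 50, 100 | Hz | line noise and harmonic |
| epoch length | 2 | s | rejection granularity and Welch segmenting |
| rejection threshold | ±100 | µV | amplitude artifact rule |
| microstate band | 2–20 | Hz | canonical microstate band |
| Welch segment | 2 s, 50% overlap, Hamming | — | unbiased for white noise; variance ≈ 1/K |
| k | 4 | classes | canonical A–D solution |
| GFP peak separation | 10 | ms | suppresses duplicate noise maxima |
| min dwell (generator) | 30 | ms | truncated-geometric run law |

Band-power summaries average the *density* over in-band bins, convert to
dB per channel, then average dB across channels (the whole-brain value);
bins are half-open `[low, high)` so shared band edges are never counted
twice.

## Scaled defaults and runtime

The demo pipeline configuration simulates 6 subjects per group, 19
channels, 256 Hz, 12-s recordings — a desk-scale stand-in for the full
design (22 per group, 60 channels, 512 Hz after resampling, 5-min
recordings). Tests that pin the full geometry (template recovery, metric
recovery, model selection) use 60 channels at 512 Hz explicitly; the
end-to-end power simulation keeps the pinned 20 subjects per group and the
0.8× duration multiplier but uses 16-s recordings at 128 Hz so that 50
seeds complete within the stated budget. The dilution of a multiplicative
duration effect by peak-train quantization is roughly additive, so the
paired contrast remains detectable at this scale; measured power is ≈ 0.9.

## Known limitations

* AAHC weights cluster contributions by GFP, so an occasional very-high-GFP
  noise map can survive as a singleton cluster at the subject level; the
  group and grand levels are robust to this (bad subject maps are outvoted).
* Durations measured by back-fitting are biased upward by roughly half the
  mean GFP-peak spacing; comparisons across conditions are differences of
  equally-biased quantities and remain valid.
* The EDF codec is a minimal single-record 16-bit implementation (physical
  units µV), sufficient for round-tripping synthetic recordings; it is not
  a general EDF+ reader.
* The 100 Hz notch sits at the upper edge of the gamma2 band; band energy
  is logged as computed, without compensation.
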