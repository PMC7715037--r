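---
title: "Models and methods behind shufflespeller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shufflespeller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shufflespeller)
```

## The problem

People with severe speech and physical impairment — most prominently
locked-in syndrome in late-stage ALS — may retain only limited, slow eye
movement as a voluntary channel. Conventional eye-tracking keyboards select
a key after a continuous *dwell* on it, which fails when gaze is slow,
jittery, or cannot be held inside a small target. The shuffle speller takes
a different route: the 28 typing symbols (A–Z, space `_`, backspace `<`)
are distributed over just four large boxes at the screen edges, the user
indicates *which box* holds their letter — by gazing at it, or by attending
a flickering LED whose steady-state visual evoked potential (SSVEP) is
decoded from occipital EEG — and a recursive Bayesian engine accumulates
evidence over repeated re-partitions ("shuffles") of the alphabet until one
character's posterior probability strictly exceeds 85%.

This package implements that decision core together with everything needed
to exercise it end to end on synthetic data: signal generators, feature
extraction, likelihood models, information-theoretic calibration analysis,
the copy-spelling study protocol, and its performance metrics.

## Synthetic signals

`generate_ssvep_trial()` emulates a 3-channel occipital montage (O1, Oz,
O2) at 256 Hz. Attending target $k$ produces sinusoids at the stimulation
frequency $f_k \in \{8.0, 9.7, 11.3, 13.0\}$ Hz and its harmonics
(second-harmonic amplitude ratio 0.5 by default — response morphology is a
free parameter of the generator, not a measured quantity), with
channel-specific gains and phases, superposed on $1/f$-amplitude-shaped
Gaussian noise as a minimal model of EEG background. `snr` is defined as
RMS(signal)/RMS(noise) per channel *before* summation, so `snr = 0` is pure
noise and `snr = Inf` is noise-free. Real SSVEP responses are nonstationary
and subject-specific; the generator's defaults are chosen to span the
failure-to-success range rather than to mimic one person, and the default
`snr = 1` sits comfortably in the success regime of the decoder.

`generate_gaze_trial()` scatters 60 Hz gaze samples isotropically
(bivariate normal) around a target centre with i.i.d. Bernoulli dropouts —
the simplest model consistent with "inconsistent eye tracking".
`inject_artifacts()` adds Poisson-timed, ~100 ms, saturation-style bursts
at a configurable multiple of the channel's clean peak and flags the
affected channel, reproducing the intermittent high-amplitude non-EEG
contamination that ends real sessions.

What the generators deliberately do **not** model: eye blinks/EOG, photic
driving nonlinearity, inter-trial drift, spatially correlated noise.
Passing tests on these signals therefore demonstrates correctness of the
*decoding and protocol machinery*, not clinical performance.

## CCA features

For each stimulation frequency a reference bank holds $\sin/\cos$ pairs at
$hf$, $h = 1..2$ (`build_reference_bank()`). The feature is the first
canonical correlation between all EEG channels and the bank
(`cca_scores()`), one scalar per frequency in $[0,1]$. We use only the
first canonical correlation: this is standard SSVEP-CCA practice and keeps
the downstream density estimate one-dimensional per (target, frequency).

Numerics: both variable sets are mean-centred and whitened through an SVD
that drops components with singular value below $10^{-9}$ of the largest.
This makes the score exact (1.0 to machine precision for an in-subspace
signal), invariant to per-channel affine rescaling and channel order, and
stable under duplicated channels — a ridge term would instead bias the
noise-free score away from 1. A constant segment has no usable direction;
it scores 0 at every frequency and raises a degenerate-input warning
rather than an error, since online sessions must survive a flat channel.

## Likelihood models and the confusion matrix

`fit_kde_model()` fits one Gaussian-kernel KDE per (intended target,
frequency) — 16 densities — with Silverman's rule bandwidth, floored at
0.01 so that a zero-variance calibration sample (noise-free fixtures
produce exactly repeated scores) collapses to a narrow peak instead of a
delta or, worse, `bw.nrd0`'s magnitude-scaled fallback. The joint
likelihood of a score vector multiplies the per-frequency densities;
independence across frequencies is an approximation consistent with
fitting the densities per frequency in the first place. Densities are
floored at $10^{-12}$ in evaluation so Bayesian updates never divide by
zero.

The gaze model summarises a trial by the 20%-trimmed mean of its valid
samples; trials under 25% validity are classed *unrecognized* rather than
forced onto a target, mirroring how an online system refuses unusable
input.

`estimate_confusion()` uses leave-one-out classification — with only 20
trials per target a held-out split would be noisier — and Laplace
smoothing (pseudo-count 0.5) so no entry is zero and channel capacity is
well defined. LOO refits relax the 5-trials-per-target precondition by one
for the inner fits. Two known consequences, quantified in the tests: the
smoothed diagonal cannot exceed $20.5/22 \approx 0.93$ even for a perfect
decoder (use `smoothing = 0` to see the identity), and under
label-permuted calibration the LOO rows are *not* uniform-multinomial —
the simulated null envelope of max-row total variation reaches ~0.64 at
this design size even though mean decode accuracy stays at chance.

## Capacity and trial length

`nykopp_capacity()` treats the confusion matrix as a discrete memoryless
channel and computes its capacity $C = \max_p I(\text{intended};
\text{decoded})$ by Blahut–Arimoto (tolerance $10^{-9}$ bits on the
duality gap, $0\log 0 \equiv 0$ throughout). Unlike the Wolpaw-style ITR
it makes no symmetry assumption on the error structure — that classic
formula is out of scope here beyond this mention.

`select_trial_length()` truncates every calibration trial to each
candidate window (default 1–6 s in 0.5 s steps), re-runs scoring → model →
LOO confusion → capacity, and maximises the information *rate*
$C(L)/(L + \text{overhead})$, ties toward the shortest window. We maximise
bits/second rather than bits/selection because the trial length only
matters through the time it spends; the overhead defaults to the 2 s
inter-query pause and is configurable since the true denominator of the
original system is not documented. A plan is flagged degenerate when its
best rate falls below 0.12 bits/s: across 50 pure-noise calibrations of
the standard design the LOO-overfit capacity bias alone produces max rates
up to 0.095 bits/s, so the floor sits just above that null envelope while
any usable calibration clears it by an order of magnitude.

## The shuffle engine

`optimize_partition()` maximises the expected information of a query,
$I(\text{intended box}; \text{decoded box})$, where the intended-box
distribution aggregates the current posterior over the assignment and the
channel is the confusion matrix. Because the objective depends on the
assignment only through the per-box posterior mass,
$I = H(\text{decoded}) - \sum_b P(b)\,H(W_{b\cdot})$, instances with at
most 65536 assignments are solved exactly by vectorised enumeration; the
full $4^{28}$ production case uses deterministic greedy seeding plus
hill-climbing over single moves, pair swaps, and pair co-moves. The
co-move neighbourhood exists because pure move/swap search provably stalls
on subset-sum-style local optima. All ties break toward the earlier box
and alphabet order, so partitions are reproducible.

`bayes_update()` multiplies each character's posterior by the likelihood
of its box and renormalises, in log space (a 200-query stress test shows
no underflow). Evidence passes a recognition criterion — max normalised
box likelihood ≥ 0.3 and top-to-second ratio ≥ 1.05 — chosen as a minimal
operationalisation of "unrecognized input"; unrecognized queries leave the
posterior untouched and count toward a consecutive-unrecognized limit
(default 10). `select_character()` is strict at the threshold: exactly
0.85 does **not** select. Selection timing counts the 5 s initial
alphabetical display, each query's stimulation time, and 2 s re-shuffle
pauses between queries. Each selection starts from a uniform prior; a
text-conditioned prior is exposed as the `prior` argument but off by
default, since how the original system used previous inputs is not
specified.

## Copy-spelling protocol

`run_copy_session()` implements the study protocol: five 5-letter words
per session; the intended character is the next letter while the typed
string is a correct prefix, else backspace; selections are categorised as
correct letter / correct backspace / incorrect. Stop rules in precedence
order: 20-minute session cap; termination at 5 minutes with zero correct
selections; word advancement after 4 consecutive errors or persistent
unrecognized input. Backspace on an empty string is incorrect (nothing to
delete), and word advancement clears the typed string — both points the
protocol leaves implicit. The word pool is a bundled list of 65 common
five-letter words (a constructed stand-in; word identity affects nothing
computational), from which 26 pairwise-distinct session lists are sampled.

`simulate_dwell_speller()` provides the baseline conditions: a static
three-step hierarchy (alphabetical blocks of ≤ 7 assigned top → right →
bottom → left, then sub-groups of ≤ 2, then the character), a box selected
when *continuous* gaze inside it accumulates the dwell time (1.2 s or
2.5 s; accumulation resets on exit), a central go-back target for wrong
group selections, and an attempt cap (default 30 s) after which simulated
time has still passed — this is what lets a hopeless-scatter session reach
the 5-minute early stop with zero selections.

## Metrics

`compute_metrics()` reports the two accuracies (with backspaces counted
correct — the primary measure — and letters-only) and three
characters-per-minute rates (total, correct incl. backspace, correct
letters only) over active typing time, which includes intra-selection
pauses but excludes between-word breaks. Early-stopped sessions with no
selections still produce a 0% row, matching how all-zero baseline sessions
are reported rather than dropped. Exports round accuracies to one decimal;
in-memory values keep full precision.

## Problem sizes and determinism

Every stochastic component takes an explicit seed and restores the
caller's RNG state, so trials, sessions and whole pipelines are bit-wise
reproducible. The test suite and the acceptance script use desk-scale
sizes chosen to keep Monte-Carlo error well inside the asserted
tolerances: 20 calibration trials per target (the study protocol), 100–150
simulated selections per accuracy estimate, 50-instance oracle sweeps for
the partition and capacity checks, and 50-seed null simulations behind the
degeneracy floor. Human performance numbers from any particular study —
driven by fatigue, signal quality, and individual SSVEP strength — are
outside what synthetic signals can reproduce; the package's claims are
about the correctness of the machinery.
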