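---
title: "From projection-neuron ensembles to appetitive behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From projection-neuron ensembles to appetitive behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

pnvalence links odor-evoked spiking of antennal-lobe projection neurons
(PNs) in the locust to an appetitive behavioral readout, the palp-opening
response (POR). The package covers the full chain: behavioral preference
statistics, PN response classification, population-level manifold analyses
(PCA trajectories, correlation-distance clustering, cosine-angle
similarity), a linear decoder from ensemble activity to innate POR
probability, an L1-regularized mapping from time-varying activity to POR
dynamics after conditioning, and a Hebbian neuron/anti-neuron network that
reproduces which odors can be associated with a food reward. A synthetic
generator provides data with the statistical structure these analyses
assume, so every stage is testable without recordings.

This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions taken where the procedure was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The synthetic study conditions

`synth_config()` defaults encode the emulated study: 89 PNs recorded over
10 trials per odor, a 22-odor panel assayed behaviorally in 26 locusts, a
4 s odor pulse followed by a 4 s OFF window, and 30 fps palp-tracking
traces. Firing is piecewise-constant-rate Poisson -- the minimal stationary
model, since no generative spiking model is implied by the analyses
themselves -- at a 3 Hz spontaneous rate, a plausible magnitude for
antennal-lobe PNs rather than a measured value. Spiking is simulated from
4 s before onset so that both baseline conventions used downstream (4 s for
the consistency filter, 2 s for response classification) exist in every
trial.

Valence structure enters through four PN pools (appetitive-ON,
appetitive-OFF, non-appetitive-ON, non-appetitive-OFF) and a fixed
per-neuron sensitivity rank. An odor of a pool's class recruits the pool
members whose rank lies below `ensemble_overlap * (0.2 + 0.8 * p)`, where
`p` is the odor's innate POR probability; recruited PNs add
`on_gain * (0.7 + 0.5 * p)` Hz (OFF analogously) during their window.
Ensembles of same-class odors are therefore nested around a shared core:
higher-valence odors recruit more PNs and drive them somewhat harder, which
is the regularity the valence decoder exploits, while odors of different
classes engage disjoint pools. Two further ingredients implement the
premises of the conditioning model: the most broadly tuned
`cross_activation` fraction of the appetitive-ON pool is weakly but
reliably driven (`cross_gain`, 9 Hz) by unappetitive odors -- the response
overlap that carries cross-learning -- and unappetitive odors suppress a
random `inhibition_prob` fraction of the remaining appetitive-pool PNs to
`inhibition_factor` of baseline.

What the generator does **not** emulate: odor-identity patterning beyond
recruitment breadth (same-class odors differ in magnitude, not in pattern,
so identity decoding within a class is out of reach), spike-train
temporal structure (no onset transients, adaptation, or oscillations),
trial-to-trial gain drift, and electrode-level noise. Passing tests
therefore certify the analysis chain and its statistical behavior under
the assumed ensemble logic -- not performance on real recordings.

POR traces are a baseline of 1 arb.u. plus a smooth opening envelope for
trained-appetitive odors (peak inside the stimulus window after
ON-paradigm training, after offset for OFF-paradigm training), Gaussian
frame noise of 1 arb.u. s.d., clipped at zero because a palp separation
cannot be negative.

## Behavioral statistics

`por_scores()` reduces the binary locusts-by-odors matrix to per-odor
totals, normalized scores (response probabilities), and preference indices
(normalized score minus the across-odor median), so the median odor sits
at zero. `classify_valence()` tests each total against a null response
probability with exact one-sided binomial tails at `alpha = 0.1` per side.
The null probability is the median normalized score by default -- the test
is framed as deviation from the median response -- with 0.5 or a fixed
value available through `null_prob`. `mc_locust_subsample()` quantifies
how many individuals are needed for a stable preference ranking by
correlating subset-derived indices with the full-cohort indices (Pearson,
squared); at the full cohort size the subset is the sample itself and the
statistic is identically 1.

`detect_por_response()` marks a trace as a response when at least 30
frames (1 s at 30 fps) inside the response window exceed the pre-stimulus
mean by 6.5 baseline standard deviations and an absolute 1.5 arb.u. gate
(the tracking noise floor). Three choices are deliberate: the 30 frames
need not be contiguous (a `contiguous` flag restores the stricter
reading); the response window extends 4 s past odor offset because learned
PORs persist into the OFF period; and a `1e-6` floor on the baseline s.d.
keeps flat baselines from dividing by zero. The absolute gate makes the
detector intentionally *not* scale-invariant; with the gate disabled it
is, which the tests document. `normalize_traces()` rescales per locust
(not per trace) to [0, 1] so relative response sizes across test odors are
preserved.

## PN response classification

`classify_pn_responses()` works on 50 ms non-overlapping, half-open count
bins -- the bin width is not dictated by the rule itself, so it follows
the binning used everywhere else and is exposed as a parameter. Per trial,
an ON (OFF) call requires some ON-window (OFF-window) bin to exceed the
baseline mean by 6.5 baseline s.d.; an inhibition call requires no ON bin
above mean + 2 s.d. *and* a mean ON rate below baseline. A label needs
agreement in at least half the trials (5 of 10), with precedence
ON > OFF > inhibited within a (PN, odor) pair, since the source procedure
resolves conflicts only across odors, not within one.

Baseline statistics are pooled across the trials of a (PN, odor) pair by
default. At a few Hz, a single trial's 2 s baseline holds ~6 spikes in 40
bins; the resulting s.d. estimate occasionally collapses, and with it the
threshold, pushing the excitation rule's false-positive rate on
signal-free Poisson data to 1-2%. Pooling (400 bins) estimates the null
spread properly and keeps the measured false-positive rate far below 1%,
which is the level the rule is designed to operate at;
`pooled_baseline = FALSE` restores strictly per-trial statistics. The
inhibition rule is a different matter: with 50 ms bins at 3 Hz the
mean + 2 s.d. ceiling sits almost exactly at one count, so on pure noise
it retains a chance level of a few percent. Inhibition calls at low
spontaneous rates should be read as qualitative.

`filter_consistent_pns()` implements the recording-stability screen: a PN
is kept only if every trial's 4 s baseline rate is at least 15% of that
PN's maximum baseline rate. On real recordings this catches drift and unit
loss. On the synthetic data the generator already emulates the *retained*
population, and at 3 Hz the min/max ratio across 220 trials is dominated
by Poisson counting noise; `run_pipeline()` therefore records the filter's
output as a QC table and carries the full emulated population forward.

## Manifold analyses

`pca_trajectories()` eigendecomposes the PN-by-PN covariance of the
trial-averaged, concatenated response matrix (89 x 1760 for 22 odors at
80 ON bins each), projects every population vector onto the top
eigenvectors, subtracts each odor's first projected bin so all
trajectories share a pre-stimulus origin, and smooths with a 3-point
moving average. Each PN's mean across concatenated bins is subtracted
before the covariance (the standard covariance definition; an uncentered
variant is exposed). Eigenvector signs are canonicalized
(largest-magnitude loading positive) so results are comparable across
solvers; zero eigenvalues of rank-deficient covariances are kept, ordered
last. On synthetic data the top three components capture substantially
more variance than is typical of real ensembles, because the generator is
deliberately low-dimensional.

`cluster_odors()` delegates to complete-linkage agglomeration on the
correlation distance 1 - r, so proportional activation patterns merge at
height zero regardless of overall rate. Optimal leaf ordering is cosmetic
and not implemented; merge structure and heights are the substance, and
they are verified against an exhaustive agglomeration oracle. Ties merge
at whatever order the distance method yields; the oracle breaks ties
toward the lowest index.

`valence_angle_scores()` computes, for each odor's mean ensemble vector,
the mean angle to the appetitive and to the non-appetitive group (neutral
and unappetitive pooled; self-comparison excluded, giving 21 angles per
odor on a 22-odor panel) and reports non-appetitive minus appetitive, so a
positive score means an appetitive-like code.

## Decoding innate preference

`fit_valence_regressor()` is the linear readout with a squashing output:
prediction = sigmoid(w'n + b), where `n` holds each PN's mean spike count
over the full 4 s epoch (no feature standardization -- none is part of
the procedure). A single scalar output makes the logistic sigmoid the
only monotone "softmax" consistent with outputs in (0, 1); this reading is
deliberate and pinned here. The mean-squared-error cost is minimized by
full-batch gradient descent from zero initialization with step 0.05, at
most 10,000 iterations, stopping when the loss improves by less than
1e-10. Because the features live on a spike-count scale, a fixed step can
overshoot into sigmoid saturation; the step is therefore backtracked
(halved until the loss does not increase, mildly re-grown after accepted
steps), which makes the recorded loss trace non-increasing without
changing the estimator's target.

`loocv_valence()` leaves one odor out at a time (22 models), and the
headline R-squared is the squared Pearson correlation between predictions
and targets (1 - RSS/TSS is also reported, since the two conventions
differ out of sample). `shuffled_valence_control()` permutes targets
before training; with the neural-behavioral correspondence destroyed,
predictions collapse toward the mean target. `weight_analysis()` and
`mc_pn_subsample()` quantify weight stability across leave-outs/epochs and
performance as a function of population size.

## Mapping activity onto POR dynamics

`build_por_design()` assembles the conditioning-stage regression: per
odor, 2 s baseline + 4 s ON + 4 s OFF at 10 Hz (100 points; onset at
column 21), concatenated over the four conditioning odorants into an
89 x 400 input and a 400-point mean POR trace (locust-averaged, 30 fps
block-averaged to 10 Hz). The baseline segment stays in the loss: the
400-point construction includes it, and it anchors the intercept.

`fit_por_lasso()` minimizes `(1/(2T)) ||y - X'w - b||^2 + alpha ||w||_1`
with an unpenalized intercept and no standardization. The `1/(2T)`
scaling is load-bearing -- it defines what `alpha = 0.01` means and hence
the sparsity split of the population into positive / negative / zero
weight groups -- and is pinned to that convention. Solutions must satisfy
the L1 subgradient conditions; the maximal KKT violation is stored on the
model and checked against a proximal-gradient oracle in the tests.
Per-odor prediction quality is a Pearson correlation with a two-sided
t-test on (segment length - 2) degrees of freedom for whatever segment
length is configured. `weight_dissection()` averages weights across the
six paradigm models, groups PNs by sign, and relates group firing to the
assigned weights.

## The Hebbian neuron/anti-neuron network

`init_hebbian_network()` builds the conditioning model on 50 ms
trial-averaged activity over the four conditioning odorants (baseline, ON,
and OFF bins included). The two decoder weight vectors are least-squares
solutions `W = (XX')^{-1} X Y'` for binary targets marking the stimulus
bins of the appetitive pair (decoder 1) and the non-appetitive pair
(decoder 2); a ridge-stabilized pseudoinverse with
`lambda = 1e-8 * trace/n` is substituted, with a warning, if `XX'` is
numerically singular. The DN1 threshold is set 1% (`epsilon`) above the
maximum pre-learning drive -- the construction guarantees a silent
appetitive decoder, and readouts verify POR = 0 for every odor before
learning -- while the DN2 threshold is half the maximum decoder-2 drive
(a per-odor variant is exposed). The readout is the rectified difference
`POR(t) = max(DN1(t) - DN2(t), 0)`.

`partition_ensembles()` assigns PNs with stronger hexanol than
benzaldehyde ON responses to Ensemble 1; ties go to the smaller group, and
by default the least-committed PNs (smallest response difference) are
reassigned from the larger group until sizes differ by at most one,
keeping the two ensembles of nearly equal size without disturbing clearly
committed neurons. Plasticity is confined to Ensemble-1-to-DN1
connections: `hebbian_update()` adds `delta * xbar` (learning rate 0.25;
`xbar` the mean activity over the conditioned odor's stimulus bins) to the
weights of PNs that are both in Ensemble 1 and ON-classified for the
conditioned odor. A six-trial session is collapsed into one batch step by
default (`n_updates` gives per-trial mode); masked weights with positive
reward-bin activity can only grow, and no other parameter changes.

The mechanism the model isolates: appetitive odors drive Ensemble 1
strongly, so conditioning either appetitive odor lifts the DN1 drive for
*both* (shared core), producing PORs to hexanol and isoamyl acetate;
benzaldehyde conditioning reaches DN1 only through the cross-activated
corner of Ensemble 1, producing the same generalization without a
benzaldehyde POR, because the anti-neuron -- driven robustly by
non-appetitive ensembles -- vetoes it. Setting `cross_activation = 0` in
the generator abolishes cross-learning entirely, which the acceptance
tests check.

## Numerical conventions and problem sizes

All times are seconds relative to stimulus onset; all bins are half-open
`[t, t + width)`, with a `1e-7`-bin-width tolerance so boundary spikes land
deterministically. Baseline s.d. floors are `1e-6` (counts and arb.u.).
The delta-RMS chain for behaving-preparation voltage uses a 4th-order
zero-phase Butterworth band-pass at 300-6000 Hz (only the band is
specified by the procedure; the realization is pinned here), +/-5 s.d.
clipping, a 20 ms moving RMS, downsampling by 150, a 10-point moving
average, downsampling by 5 (15 kHz -> 20 Hz), and subtraction of the 1 s
pre-stimulus mean.

The test suite runs the full chain at the default study sizes (89 PNs, 22
odors, 10 trials) where the property under test concerns those conditions
-- decodability, tuning trends, angle signs, conditioning outcomes,
false-positive control at 1000 signal-free pairs -- and at reduced sizes
(24 PNs, 6 odors, 6 trials; 50-odor regression problems with 12 features)
for oracle-equivalence and invariance checks, where the property is
size-independent and small instances allow exhaustive or brute-force
oracles.

## Known limitations

Within a valence class, synthetic odors differ only in recruitment breadth
and gain, so identity-level structure (distinct looped trajectories per
odor) is not reproduced and captured PCA variance is higher than in real
ensembles. The inhibition label is unreliable at low spontaneous rates, as
discussed. The behavioral generator ties learned PORs to innate valence
class rather than to a learned association per se; it emulates the test
phase of conditioning, not acquisition. The delta-RMS stage processes
single traces and does not model electrode cross-talk or movement
artifacts.
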