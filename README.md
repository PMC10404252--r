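# pnvalence

Linking odor-evoked projection-neuron (PN) ensemble activity in the insect
antennal lobe to innate and learned appetitive behavior.

In locusts, the appetitive value of an odor can be read out behaviorally as
a palp-opening response (POR). pnvalence implements the computational chain
that connects that behavior to the spiking of antennal-lobe PN ensembles
recorded over a baseline / 4 s odor (ON) / 4 s post-odor (OFF) protocol:

- **Behavior**: per-odor preference indices
  (`norm_score_odor = total PORs / n locusts`, preference index =
  norm score − across-odor median), exact one-sided binomial valence
  classes (appetitive / neutral / unappetitive at *P* < 0.1), Monte Carlo
  locust-subsampling stability, POR detection in 30 fps palp-separation
  traces (6.5 s.d. above baseline for ≥ 30 frames, > 1.5 arb.u.), and
  per-locust trace normalization.
- **Electrophysiology**: half-open 50 ms spike binning, the
  6.5-s.d./5-of-10-trials ON/OFF/inhibited response classification, the
  15% baseline-consistency screen, per-PN tuning breadth and
  valence correlations, and a ΔRMS envelope chain (300–6000 Hz band-pass →
  clip → 20 ms RMS → 20 Hz) for recordings that cannot be spike-sorted.
- **Manifolds**: PCA state-space trajectories of the concatenated
  PN × time-bin matrix, complete-linkage clustering on correlation
  distance, and cosine-angle similarity of each odor's ensemble vector to
  the appetitive vs non-appetitive groups.
- **Decoding**: `POR ≈ sigmoid(Σᵢ wᵢ nᵢ + b)` fit by gradient descent on
  mean squared error with leave-one-odor-out cross-validation, shuffled
  controls, weight-stability analysis, and PN-subsampling curves.
- **POR dynamics**: lasso regression
  `(1/2T)‖y − X′w − b‖² + α‖w‖₁` (α = 0.01) from time-varying ensemble
  activity (89 × 400) onto mean POR traces across the four conditioning
  odorants, with KKT-certified solutions and weight-sign dissection.
- **Conditioning model**: a Hebbian neuron/anti-neuron network — decoder
  weights `W = (XX′)⁻¹XY′`, a silent-by-construction appetitive decoder
  (θ₁ above the maximal pre-learning drive), a half-max anti-neuron
  threshold, reward-gated updates `W₁ ← W₁ + δ·(X̄ ⊙ N)` (δ = 0.25), and a
  rectified `max(DN1 − DN2, 0)` POR readout that reproduces learning,
  generalization, and cross-learning from non-appetitive conditioning.

A synthetic-data module (`synth_config()`, `simulate_pn_spikes()`,
`simulate_por_matrix()`, `simulate_por_traces()`) generates
valence-structured Poisson populations (89 PNs × 22 odors × 10 trials), a
26-locust behavioral matrix, and POR traces with ON- vs OFF-paradigm
dynamics, so the entire pipeline runs and is tested without recordings.
The methods vignette (`vignettes/valence-coding.Rmd`) documents every
model, default, and design decision.

## Worked example

```r
library(pnvalence)

cfg <- synth_config(seed = 7)          # default study conditions
por <- simulate_por_matrix(cfg)        # 26 locusts x 22 odors
head(classify_valence(por), 4)
#>   odor_id        total norm_score preference_index p_upper p_lower valence_class
#> 1 hexanol_10pct     20      0.769            0.365 1.69e-4   1.000 appetitive
#> 2 hexanol_1pct      17      0.654            0.25  8.79e-3   0.997 appetitive
#> 3 isoamyl_aceta…    23      0.885            0.481 5.26e-7   1.000 appetitive
#> 4 hexanol_0.1pct    18      0.692            0.288 2.78e-3   0.999 appetitive

ds <- simulate_pn_spikes(cfg)          # Poisson PN population
feats <- valence_features(ds, epoch = "on")   # mean ON spike counts, odors x PNs
targets <- setNames(cfg$odor_panel$por_prob, cfg$odor_panel$odor_id)
fit <- loocv_valence(feats, targets[rownames(feats)], epoch = "on")
fit
#> <valence_loocv> 22 odors, epoch on; R2 = 0.926 (MSE 0.0037)
```

Held-out ensemble ON activity predicts the innate POR probability of each
odor (R² is the squared Pearson correlation between predicted and observed
probabilities; `autoplot(fit)` draws the predicted-vs-observed scatter).

```r
net <- init_hebbian_network(ds)        # four conditioning odorants
net
#> <hebbian_network> 89 PNs (45 in Ensemble 1); theta1 1.28, theta2 0.71; delta 0.25
post <- simulate_por_readout(hebbian_update(net, "benzaldehyde"))
tapply(post$por, post$odor_id, max)[conditioning_odors()]
#>    hexanol_1pct isoamyl_acetate    benzaldehyde          citral
#>           0.539           0.455           0.000           0.000
```

Before any conditioning the readout is silent for all four odorants; after
pairing *benzaldehyde* with reward the network produces PORs to the two
appetitive odors — cross-learning through the overlap between the
benzaldehyde ensemble and the plastic appetitive ensemble — while the
anti-neuron still vetoes responses to benzaldehyde and citral.

`run_pipeline(cfg, out_dir)` chains every stage on one dataset and writes
tidy CSV/JSON artifacts plus a seed-reproducible manifest.

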