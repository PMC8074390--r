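# semgintent

Online-adaptive prediction of lower-limb motion intention from surface EMG.

## What this package is for

Exoskeleton controllers need the wearer's motion *before* it happens —
the future knee angle, and the time to the next heel strike (initial
contact, IC) — because sensing, computation and actuation all add delay.
Surface electromyography (sEMG) leads limb motion by on the order of
100 ms, which makes genuine prediction possible; but sEMG is
high-dimensional, noisy, and non-stationary (fatigue raises its amplitude
and lowers its frequency content; electrode placement and anatomy differ
between subjects), so a predictor trained once degrades in use.

`semgintent` implements a complete pipeline for this problem, aimed at
researchers in myoelectric control and rehabilitation robotics:

1. **Feature extraction** — a convolutional autoencoder (CAE) compresses
   each 9×200 sEMG image (nine lower-limb muscles × 180 ms at
   1111.111 Hz) into 40 feature maps of size 3×7. Its encoder runs three
   temporal convolutions (kernels 1×105, 1×55, 1×30), then rearranges the
   muscle axis by **muscle synergies** — non-negative matrix factorization
   of the activation envelopes, V ≈ W·H with W the synergy activations and
   H the synergy weights — so that co-activating muscles sit adjacently
   under the following two 4×4 convolutions. Reconstruction fidelity is
   reported as the total variance accounted for,
   tVAF = 1 − ‖EMG − EMG_re‖² / ‖EMG‖².
2. **Prediction** — an LSTM network (per-step FC 120→100→1 on the feature,
   concatenated with the 7×5 motion sequence, three LSTM layers of 200
   units, FC 200→100→1) outputs a future knee angle at horizons of
   6.75/33.75/67.5/101.25 ms, or the time to the next heel strike. One
   independently trained instance per target.
3. **Online adaptation** — a meta-learned coordinatewise LSTM optimizer
   θ_{t+1} = θ_t + g(∇f, φ) watches the gradients of two fixed parameter
   subsets (the even FC3 input rows plus biases, 10,100 coordinates; every
   fourth input slice of encoder layer 4 plus biases, 12,840 coordinates)
   and emits increments that pull the frozen networks back toward a
   shifted sEMG distribution, using reconstruction error for the CAE and
   prediction error for the predictor. Gradients enter the optimizer as
   the preprocessed pair (log|∇|/p, sign ∇) for |∇| ≥ e^{−p}, else
   (−1, e^p·∇), with p = 10.

Because the human recordings behind this design are not publicly
available, the package includes a first-class synthetic gait-recording
generator (synergy-structured activation envelopes × spectrally shaped
stochastic carriers, periodic knee/segment kinematics, heel-strike events,
and distribution-shift knobs for amplitude, spectral compression and
envelope jitter), so the full pipeline is testable end to end. See the
methods vignette (`vignettes/methods.Rmd`) for the model details and every
numerical choice.

## Worked example

```r
library(semgintent)

# one synthetic subject, 26 s of treadmill walking
rec <- generate_recording(gait_params(duration = 26, seed = 1))
rec
#> Synthetic gait recording
#>   duration: 26.0 s, sEMG 9 ch x 28889 samples @ 1111.111 Hz
#>   motion/angle: 3852 samples @ 148.148 Hz, 24 heel strikes

# windows, motion sequences and labels
ds <- build_dataset(rec)
ds
#> intent_dataset: 1871 labeled samples, horizons 1/5/10/15 IMU samples

# muscle synergies from the rectified, low-pass-filtered envelopes
env <- semg_envelope(rec$semg, rec$rates$semg)
syn <- fit_nmf(t(env[, seq(1, ncol(env), by = 15)]), r = 5, seed = 2)
syn
#> synergy_model: r = 5, W 1926 x 5, H 5 x 9
#>   relative Frobenius reconstruction error: 0.0537
```

`fit_nmf()`'s relative error of 0.054 says the five synergies explain
about 94.6 % of the envelope's Frobenius norm; `derive_channel_orders(syn$H)`
turns the weight matrix into the five channel permutations the encoder
uses. The full study — train on eight subjects, hold out one shifted
subject, adapt online — is one call:

```r
rep <- run_experiment(experiment_config(), seed = 1)
round(c(intra = rep$tvaf$intra, inter = rep$tvaf$inter,
        adapted = rep$tvaf$adapted), 3)
#>   intra   inter adapted
#>   0.274   0.087   0.119
round(rep$angle$intra_max_err, 2)
#>   h1   h5  h10  h15
#> 0.50 0.63 0.66 0.85
```

which prints the reconstruction fidelity on held-out windows of the
training subjects (`intra`), on the shifted subject before adaptation
(`inter`), and after one adaptation iteration (`adapted`);
`rep$angle$intra_max_err` holds the stride-wise maximum angle error per
horizon (degrees; it grows with the look-ahead, here from 0.50 deg at
6.75 ms to 0.85 deg at 101.25 ms), and `rep$event` the time-to-IC
statistics. At the packaged desk scale the run takes a few minutes on one
CPU and is bit-reproducible from (config, seed).

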