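---
title: "Dual-attention graph convolutional EEG decoding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-attention graph convolutional EEG decoding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damgcn)
```

## The problem

Emotion decoding from scalp EEG classifies short signal segments into
affective states (high/low valence or arousal in rating-based designs;
positive/neutral/negative in stimulus-based designs).  Two structural
facts about EEG motivate the architecture implemented here: electrodes
form a fixed spatial graph on the head, so information mixes between
neighbouring sites; and emotional correlates concentrate unevenly across
the canonical frequency bands (delta 1--4, theta 4--8, alpha 8--13,
beta 13--30, gamma > 30 Hz).  The model therefore combines a graph
convolution over a 3-D electrode-distance graph with two transformer
self-attention stages, one over electrode channels and one over
frequency bands, so that the network both exploits and *reports* which
electrodes and bands carry the signal.

## Features: differential entropy

Each trial is band-limited, cut into non-overlapping segments (0.5 s for
the 128 Hz 32-channel layout, 1 s for the 200 Hz 62-channel layout), and
summarized per (segment, channel, band) by differential entropy under a
Gaussian assumption,

$$ H = \tfrac12 \log(2\pi e \hat\sigma^2), $$

with $\hat\sigma^2$ the maximum-likelihood variance of the band-limited
segment.  DE is a monotone function of band power on a decibel-like
scale; it is shift-invariant and turns signal gain $s$ into an additive
offset $\log|s|$, which is what makes the synthetic ground truth below
analytically tractable.  Numerical choices: natural logarithm (nats)
throughout; variance floored at $10^{-12}$ so silent segments yield a
finite feature; ML (divide-by-$n$) variance because $\sigma^2$ is a
distribution parameter, and at $\ge 64$ samples per segment the
difference from the unbiased estimator is negligible.

**Band realization.** The bands are realized by an exact zero-phase
FFT-mask band-pass applied to the whole trial before segmentation (bin
membership `low < f <= high`, so adjacent bands partition the spectrum
and DC is excluded).  A Hann-window STFT estimator
(`method = "stft"`) is provided as an alternative; the two agree in
expectation for stationary signals.  We chose the FFT mask over an IIR
design (e.g. Butterworth + forward--backward filtering) because it has
exactly zero phase shift, exact band edges, no warm-up transient at
trial starts, and lets the synthetic generator use *the same operator*,
so generator and analyzer agree on band definitions by construction.
The upper gamma edge is capped at the data's release-filter edge (45 Hz
for the 4--45 Hz band-passed 32-channel layout, which also drops delta;
75 Hz for the wide-band 62-channel layout), and any band reaching past
Nyquist is clipped with a warning.

Ratings on 1--9 scales are binarized at 5 with a *strict* inequality
(a rating of exactly 5 goes to the low class); the convention is
explicit and configurable because the published rule names only the
threshold.  Leading baseline seconds are dropped, not used for baseline
correction, matching the published preprocessing.

## The electrode graph

Electrode positions $(x_i, y_i, z_i)$ give Euclidean distances $d_{ij}$
and the fixed adjacency

$$ w_{ij} = 1/d_{ij} \ (i \ne j), \qquad w_{ii} = 1, $$

normalized for propagation as $\tilde D^{-1/2}(A + I)\tilde D^{-1/2}$.
Note the deliberate quirk: the adjacency already has a unit diagonal
*and* the identity is added again, so the self-looped matrix has
diagonal 2.  This follows the defining equations literally; a
`single_self_loop` flag exposes the conventional variant for ablation.
Distances are taken in montage-native units with no rescaling, because
the defining formula never normalizes $d_{ij}$ and any monotone rescale
would change the weights.  The bundled 32- and 62-channel montages use
idealized 10--20/10--10 positions on a unit sphere (great-circle
interpolation between midline and ring anchors) -- a synthetic stand-in,
since measured coordinates are not published; user montages load from
`name,x,y,z` CSV.

## The network

Input is a batch of $C \times F$ DE matrices.  Blocks, in order:

1. **Batch norm** with per-channel statistics over (batch, band) pairs
   ($\gamma, \beta$ of length $C$, $\epsilon = 10^{-5}$, running
   statistics for inference; training requires batch $\ge 2$).
2. **Residual graph convolutions** (2 layers of width $F$):
   $\mathrm{GELU}(P H W + H)$ with $P$ the normalized propagation
   matrix.  The defining equations, read literally, activate twice
   (once inside the convolution, once after the residual); the default
   applies one GELU after the residual add, and a `double_activation`
   flag restores the literal double application.  GELU is the sigmoid
   approximation $x\,\sigma(1.702x)$, used verbatim.
3. **Channel attention**: each channel's $F$-vector is embedded to
   $E = 64$ by a learned linear map + layer norm, then passes 2
   post-norm transformer encoders over $C$ tokens (feed-forward width
   $4E$, dropout 0.5 on attention weights and feed-forward
   activations).  With 6 heads and $E = 64$ the per-head dimension is
   $\lfloor 64/6 \rfloor = 10$ and the head concatenation (60) is
   projected back to 64.
4. **Band attention**: the channel-stage output is projected back to
   $C \times F$ by a learned linear map (the published block order
   requires some such bridge; it is not specified, so we add the
   minimal one), transposed to $F$ band tokens of dimension $C$,
   embedded to $E$, scaled by the **band gate** (below), and passed
   through 2 encoders over $F$ tokens.
5. **Classifier**: flatten $F \times E$, linear to 64, GELU, dropout,
   linear to the class count; trained with softmax cross-entropy.

No positional encodings by default (channels and bands keep identity
through their distinct feature patterns); a `positional` flag adds
learned ones.  Initialization is Xavier-uniform for weights, zeros for
biases and the gate, all driven by R's RNG so a seed fixes the model
bit-for-bit.  Ablation flags `use_gcn` / `use_dam` drop whole blocks;
with both off the model reduces to the two-linear-layer baseline.

**The band gate.** The published interpretability analysis reports
scalar per-band "weight coefficients" that equal $1/F$ before training,
yet the attention formalism contains no such parameter.  We implement
an explicit learnable gate $g$ (zeros-initialized) whose softmax scales
the band tokens; `band_proportions()` and `band_weight_trajectory()`
report $\mathrm{softmax}(g)$, which reproduces the stated uniform
initialization exactly.  An alternative extractor,
`band_attention_weights()`, scores each band by the mean attention mass
its token receives in the band encoders.  **Empirical caveat** (see
"what a green test establishes"): behind per-token layer norm a
multiplicative token scale is almost unidentifiable -- rescaling a
token barely changes the normalized representation downstream -- so the
gate receives a vanishing, noise-dominated gradient.  On synthetic data
with a known informative band the trained gate stays within about
$\pm 0.005$ of uniform and its argmax is close to chance.  The
attention-mass extractor responds to data (when it locks onto the
planted band it does so with a margin an order of magnitude larger than
the gate's drift) but is also not reliable run-to-run at desk scale:
once the clean synthetic task saturates, nothing forces band-level
attention to specialize, and with so few band tokens the classifier can
read band content directly from the flattened output.  Both extractors
are therefore reported descriptively; the test suite asserts band-level
recovery only where measurement showed it to be reliable, and the gate
trajectory is interpreted by trend (as its published counterpart, which
likewise moves only a few hundredths, had to be).

## Training and evaluation

Adam (learning rate $10^{-3}$, default moment constants, no weight
decay), batch size 64, at most 200 epochs, dropout 0.5.  The published
stopping rule ("no significant improvement after 200 epochs") is
operationalized as early stopping on validation accuracy with patience
30 and best-weight restore; the validation set is a stratified 10% of
the *training* split, never the test fold.  Divergence (non-finite
loss) aborts a fold with a diagnostic.

Three protocols: stratified 10-fold at the segment level (segments of
one trial may share a fold -- this mirrors the published within-subject
protocol and *inflates* accuracy through within-trial correlation);
leave-one-trial-out, provided precisely because it removes that
leakage; and leave-one-subject-out for cross-subject generalization.
Disjointness of train and test indices is asserted programmatically on
every split.  Accuracy is $(TP + TN)/\mathrm{total}$, reported as
mean $\pm$ sd over folds with pooled confusion matrices (counts and
row-normalized percentages).

## Interpretability

Channel importance follows the published recipe: extract the channel
attention matrices, average over heads, encoder layers and evaluation
samples, and score electrodes by degree centrality
$DC_i = k_i/(N-1)$.  Because attention matrices are row-stochastic but
asymmetric, the matrix is symmetrized ($ (A + A^\top)/2 $) and the
self-term excluded, so a complete unit-weight graph scores exactly 1
(raw in/out-strength variants are available).  Aggregation across
models (cross-validation folds) mirrors the published averaging across
participants.  Per-channel values export to CSV joined with montage
coordinates, plus a simple azimuthal scalp projection plot.

## The synthetic world

The generator emulates the published data layouts (e.g. 40 trials of
63 s at 128 Hz with a 3 s baseline and 8 zero-padded non-EEG channels
in the on-disk fixture; variable-length 62-channel trials at 200 Hz)
and plants class structure where DE can see it: every channel is a sum
over bands of band-limited Gaussian noise, and in informative
(band, channel) cells the variance is multiplied by
$\mathrm{effect}^{\mathrm{class}}$.  Since DE is
$\tfrac12\log(2\pi e\sigma^2)$, the planted DE separation is exactly
$\tfrac12\,\mathrm{class}\,\log(\mathrm{effect})$ nats -- an
analytically known signal the tests verify against sample means.  A
per-subject log-normal gain (sdlog 0.4 by default) shifts all of a
subject's DE cells by a common constant, making cross-subject
protocols meaningfully harder in direction (not calibrated magnitude).
Class labels are assigned round-robin over trials; the baseline
segment carries no class signal.

Defaults and the recovery world: the stated conditions fix an
informative gamma band, four informative electrodes (F3, F4, O1, O2), a
variance ratio of 4, two classes, two subjects and the default model.
Sizes the source leaves open were chosen for desk scale -- 12 trials of
11 s (1 s baseline) per subject at 128 Hz, 1 s segments, i.e. 240
samples -- so the full cross-validated run trains in minutes on one
CPU.

**What a green test establishes -- and what it does not.**  The
synthetic world is Gaussian, stationary within trials, artifact-free,
and linearly separable in DE space by construction.  Green recovery
tests therefore establish that the pipeline is *internally consistent*
(the model finds structure exactly where the generator planted it);
they do not establish that real EEG contains such structure, nor do
they reproduce published dataset accuracies, which require
license-gated recordings.  With an effect this clean even the
linear-only ablation can approach ceiling, so ordering comparisons
between variants are reported but expected to be tight.

## Known limitations

* The band gate is retained for fidelity to the published
  initialization story but is nearly scale-unidentifiable (above); use
  `band_attention_weights()` when you need a band-importance measure
  that responds to data.
* Montage coordinates are idealized, not digitized positions.
* The encoder internals (feed-forward width, post-norm placement, the
  channel-to-band bridge) fill gaps the source leaves open; each is
  flagged in this vignette and controlled by configuration where
  reasonable.
* Pure-R training with a compiled attention core is fast enough for
  desk-scale experiments (hundreds of samples, tens of electrodes),
  not for full-dataset replication.
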