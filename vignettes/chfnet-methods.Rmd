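---
title: "Methods: CHF detection from short RR segments with a 1-D UNet++"
author: "chfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CHF detection from short RR segments with a 1-D UNet++}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chfnet)
```

## The problem and the model

Congestive heart failure suppresses the autonomic modulation of heart
rate, so a CHF patient's RR-interval series (the tachogram) is typically
faster and much flatter than a healthy subject's. `chfnet` classifies
short tachogram segments — 500, 1000 or 2000 consecutive RR intervals —
as CHF vs non-CHF directly from the raw interval sequence, with a
one-dimensional UNet++ whose convolution units are squeeze-and-excitation
(SE) residual blocks.

The architecture is a triangular lattice of nodes $X(i,j)$,
$0 \le i \le L$, $0 \le j \le L-i$, with $L = 4$ by default. Column
$j = 0$ is a plain convolutional encoder: each level halves the time axis
by max-pooling (kernel 2, stride 2) and doubles the channel width
(16, 32, 64, 128, 256). A node at skip position $j > 0$ receives the $j$
same-level maps $x(i,0),\dots,x(i,j-1)$ concatenated with the up-sampled
output of $x(i+1,j-1)$ — a fan-in of $j+1$ — so the information gap
between encoder and decoder is bridged by progressively refined
intermediate maps rather than a single long skip. The final node
$X(0,L)$ is reduced by global average pooling and a single logistic unit
to a CHF score $p \in [0,1]$; training minimizes the mean squared error
$\frac{1}{N}\sum_i (y_i - p_i)^2$ with Adam.

Model assumptions worth keeping in mind: the input is an *annotated* RR
sequence (R-peak detection and beat typing happen upstream); segments
from the same subject are exchangeable training units; and the
discriminative signal is present in a few minutes of beats — the mean
level, the variability, and the short-range correlation structure of the
tachogram.

## Preprocessing

Two pointwise filters run before segmentation:

* intervals whose beat annotation is not `"N"` are removed (ectopic
  beats corrupt HRV measurement);
* intervals longer than 2 s are removed (they are almost always missed
  R peaks, i.e. two true intervals fused). The boundary is read
  strictly: exactly 2.0 s is kept.

Beats are annotated but intervals are removed; we resolve this by
labelling each interval with the annotation of its *terminating* beat
and removing the interval when that beat is abnormal. This is the
simplest consistent mapping; the alternative — invalidating both flanking
intervals — cannot be distinguished from it with published aggregate
segment counts, and is noted as an open choice. Both filters are
keep-predicates evaluated per interval, so they commute (a property the
test suite checks on random series). Survivors are simply concatenated:
no resampling, no gap markers. The consequence — a spuriously short
"interval" spanning each removal — is accepted because removals are rare
(about 1–2 % of beats) and the downstream model sees windows of hundreds
of beats.

Segmentation is non-overlapping and left-aligned with the trailing
remainder dropped; a cleaned series of $m$ intervals yields
$\lfloor m/n \rfloor$ segments. Each segment is then zero-padded at the
tail to the smallest multiple of $2^L$ at or above $n$, so that $L$
poolings divide evenly; for $L=4$ this maps 500, 1000, 2000 to 512,
1008, 2000 — the rule is the unique "round up to the $2^L$ grid" that
reproduces all three values. Tail padding (rather than symmetric or
head padding) keeps the physiological sequence causally intact.

Segments are fed in raw seconds. Mean heart rate is itself
discriminative for CHF, so amplitude normalization would discard signal;
`build_dataset(..., normalize = TRUE)` provides a per-segment z-score
for experiments that want the network to rely on shape alone.

## The convolution block

The residual unit is Conv1D → BN → ReLU → Conv1D → BN with the additive
shortcut taken from the *first convolution's output*, then a final ReLU.
Because the shortcut comes from inside the block, its channel width
always matches the branch and no projection is needed. In the SE variant
the branch is rescaled per channel before the addition by a gate built
from global average pooling, a bottleneck dense layer of width
$\max(C/r, 1)$ with $r = 16$, and a logistic unit; freezing that gate at
1 makes the SE block bit-identical to the plain residual block (a unit
test asserts this). An inception-style block (parallel convolutions of
widths 1/3/5 plus a max-pooled branch, concatenated and projected) is
available for architecture comparisons.

Numerical details that are implementation choices rather than
specification: the inner activation is the rectifier and the ordering is
Conv → BN → activation (the conventional reading); convolutions
immediately followed by BN carry no bias term, because BN subtracts the
per-channel mean and the bias gradient is *exactly* zero — the first
convolution keeps its bias since its output also feeds the
un-normalized shortcut; weights use variance-scaling (He) initialization
with zero biases, fully determined by the training seed.

Down-sampling is max-pooling with kernel 2 and stride 2. The source
design is described once with "stride 1", but the same source fixes the
quantitative contracts — each step halves the map and the encoder
bottleneck is 1/16 of the padded input — which only stride 2 satisfies;
the quantitative contracts win. Up-sampling is parameter-free
nearest-neighbour doubling; a learned transposed convolution was
considered and not implemented, keeping the up-sampling path free of
parameters and the checked surface small. No deep supervision is used:
only $X(0,L)$ feeds the head.

## Training protocol

The full-scale protocol is Adam with minibatches of 16, 70 epochs,
initial learning rate $10^{-4}$, multiplied by 0.1 when the validation
loss has not improved for 5 consecutive epochs (the patience counter
resets after each decay). Cross-validation is subject-wise: the subject
set is permuted under the seed and split into $k$ parts differing in
size by at most one; every subject's segments live in exactly one part.
Since scheduling on the test part would leak information, an inner
validation subset (default 10 % of the training subjects, at least one
per class when possible) is carved out of each fold's training subjects
to drive the plateau schedule. The test part is never touched until the
fold's final evaluation, and the package re-verifies the disjointness of
the three subject sets on every run.

Two numerical choices matter for short runs:

* **Exact BN recalibration.** Batch-norm running statistics start at
  (0, 1) and move with momentum 0.1, so after a handful of optimizer
  steps evaluation-mode outputs are computed under statistics that
  do not yet describe the network, which shifts all scores without
  changing their ranking (we observed AUC 1.0 with accuracy 0.5).
  At the end of every epoch the running statistics are therefore
  replaced by batch-averaged exact statistics from one pass over the
  training set — the "precise BN" practice.
* **Learning rate at reduced scale.** $10^{-4}$ belongs to the
  full-scale regime of roughly $70 \times 1100$ updates. A 10-epoch run
  on a 40-segment cohort performs ~30 updates, and since Adam steps are
  $\approx$ lr per coordinate, $10^{-4}$ cannot move the network
  anywhere. At the other extreme, 0.01 saturates the logistic output
  through the un-normalized shortcut chain in a single step, and the
  MSE gradient $2(p-y)\,p(1-p)$ vanishes at $p \in \{0,1\}$, so the run
  never recovers. The scaled-down demonstrations therefore use the
  framework-standard Adam default $10^{-3}$, which trains the synthetic
  task to zero loss within ~10 steps and stays stable.

Class imbalance is left unweighted by default (matching the full-scale
protocol, where non-CHF segments outnumber CHF roughly 1.8:1);
`train_config(balance_classes = TRUE)` reweights gradients inversely to
class frequency. The decision threshold is 0.5 with a tie classified
CHF-positive. Degenerate metric denominators (no predicted positives, or
no true positives) report the affected metric, and F1, as 0. ROC curves
are computed by threshold sweep over distinct scores with ties grouped;
trapezoidal integration makes the AUC equal to the probability that a
random positive outscores a random negative, ties counted half — the
identity the tests verify against exhaustive pair counting.

## The synthetic cohort: what it does and does not establish

The generator emulates the class contrast the model exploits, not
cardiac physiology. Each subject's tachogram is a first-order
autoregressive Gaussian process around a class mean with stationary SD
equal to the configured SDNN, clipped below at 0.2 s:

| class | mean RR (s) | SDNN (s) | lag-1 AR |
|---|---|---|---|
| NSR-like | 0.90 | 0.060 | 0.90 |
| CHF-like | 0.65 | 0.015 | 0.30 |
| AF-like  | 0.75 | 0.120 | 0.05 |

NSR-like series are slow, variable and strongly autocorrelated; CHF-like
series encode the clinical hallmark — reduced variability at elevated
rate; the AF-like class (fast, erratic, nearly uncorrelated) lets the
same binary pipeline exercise a CHF-vs-(NSR+AF) style experiment. Each
beat is independently flagged ectopic (annotation `"V"`) with
probability 0.01 and replaced by a pause drawn uniformly from (2, 3] s
with probability 0.005, so the two cleaning filters always have
seed-reproducible work to do; these default rates are the ones the
filter-cascade acceptance check runs at. AR(1) was chosen over more
realistic point-process models because its moments are analytic, which
is what the acceptance bounds (class-mean recovery within standard
errors, SDNN convergence within 10 % at 10⁴ beats) need.

The classes are separated by design — the NSR/CHF mean-rate gap is an
order of magnitude larger than either class's SD — so a green end-to-end
recovery test establishes that preprocessing, the network, backprop,
optimization and subject-wise evaluation are wired correctly, and
nothing more. It says nothing about performance on clinical data, where
the class overlap is substantial and no classifier approaches perfect
accuracy. Real tachograms also carry circadian drift, respiratory
sinus arrhythmia and nonstationary artefact bursts that an AR(1)
process does not model.

## Degenerate inputs and edge behaviour

Empty series clean to empty series; series shorter than $n$ yield zero
segments; an empty cohort yields an empty design with all-zero cascade
counts. Training demands both classes; `epochs = 0` returns the
initialized network untouched (useful for baselines). Max-pooling
rejects odd-length maps — by construction unreachable when the padding
rule was applied with the network's own depth, and a loud error when it
was not. Ties in pooling resolve to the earlier time step; ties in
score at the decision threshold resolve to CHF-positive.

## Known limitations

* Pure-R training: minutes for synthetic demonstrations, but the
  full-scale protocol (tens of thousands of segments, 70 epochs, 10
  folds) wants hours and would normally be run on a GPU framework.
* The generator's realism stops at second moments and lag-1
  autocorrelation (deliberately, see above).
* No R-peak detection or beat typing: the package starts from annotated
  RR intervals, as produced by PhysioNet-style annotation files.
* Severity grading (NYHA stages) is out of scope; the output is a
  binary CHF likelihood.
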