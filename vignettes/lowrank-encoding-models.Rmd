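---
title: "Low-rank tensor temporal response functions: model, fitting and evaluation"
author: "tensorTRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank tensor temporal response functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorTRF)
```

## The model

The package fits linear encoding models that map a sparse stream of word
events to a multichannel neural recording. Each story provides a recording
$M \in \mathbb{R}^{T \times C}$ ($T$ samples at a fixed rate, $C$ channels,
z-scored per channel per story) and a set of word events: onsets
$\tau_j \in [0, T)$ and per-word embeddings $E_j \in \mathbb{R}^N$. The
regressor is the event-sparse series $X \in \mathbb{R}^{T \times N}$ that
equals $E_j$ at row $\tau_j$ and zero elsewhere; two words landing on the
same sample contribute the sum of their embeddings, which linearity forces.

The forward model is a finite-impulse-response (FIR) filter, also called a
temporal response function, over $D$ post-onset delays:

$$\hat M_{t,c} = \sum_{d=0}^{D-1} \sum_{n=1}^{N} F_{d,n,c}\, X_{t-d,n},$$

with zero padding at the story start, so stories never couple. At a 50 Hz
grid, $D = 40$ delays cover the 0–800 ms window after a word where most
language-driven activity is expected; the synthetic benchmarks in the test
suite use smaller $D$ because their ground-truth filters are narrower.

The full-rank filter has $D \times N \times C$ free parameters. The
package's central object constrains $F$ to a rank-$R$ canonical polyadic
(CP) form:

$$F_{d,n,c} = \sum_{r=1}^{R} \alpha_r\, U^D_{r,d}\, U^E_{r,n}\, U^C_{r,c},$$

a sum of $R$ rank-1 components, each the outer product of a delay profile,
an embedding direction and a channel pattern. After fitting, each factor row
is rescaled to unit Euclidean norm and the scale is pulled into a single
non-negative coefficient $\alpha_r$ (any sign flip is absorbed into the
channel factor), so the factors are directly comparable across components
and $\alpha_r$ carries all magnitude. CP parameterizations are identifiable
only up to component permutation and paired sign flips; every recovery
comparison in the package therefore aligns components first
(`matchComponents()`, greedy on absolute channel-factor correlation).

## Loss and fitting

Both parameterizations minimize the same objective, mean squared error plus
a ridge penalty on the entries of the *expanded* tensor:

$$\mathcal{L} = \frac{1}{ITC} \sum_{i,t,c} (\hat M^i_{t,c} - M^i_{t,c})^2
  + \frac{1}{CDN} \sum_c \lambda_c \sum_{d,n} F_{d,n,c}^2.$$

**Full-rank baseline** (`fitRidge()`): per-channel ridge regression on the
lagged design matrix, solved in closed form through one SVD per
cross-validation fold and reused across the whole penalty grid. The penalty
is chosen per channel by 6-fold cross-validation over an exponential grid
spanning $[10^{-3}, 10^4]$ (8 points by default; the grid density is
configurable because only the span is canonical). Folds are *sequential*:
each story is cut into contiguous equal-length blocks and fold $k$ is the
union of block $k$ across stories, which respects the temporal correlation
the convolution induces. The solver works in the standard
$\lVert Xw - y\rVert^2 + \lambda\lVert w\rVert^2$ scaling; the normalized
form above matters only for the low-rank loss, where a single penalty
couples all channels. A ridge-less variant (`fitOLS()`) exists solely for
control residualization.

**Low-rank model** (`fitCP()`): the three factor matrices are optimized
jointly with Adam (learning rate $5 \times 10^{-3}$, mini-batches of 300,000
contiguous time samples — effectively full-batch at desk scale — random
Gaussian initialization with sd 0.1). A per-channel penalty search is not
feasible once channels share factors, so a uniform $\lambda = 0.1$ is used.
The penalty is evaluated on the expanded tensor exactly as written, but in
factorized form through the $R \times R$ Gram matrices of the factor rows,
never by materializing $F$; a configuration switch (`penaltyOn =
"factors"`) exposes the alternative of penalizing factor entries directly,
without making it the default. Factors are *not* norm-constrained during
fitting; `cpNormalize()` pulls the scales out afterwards and leaves the
expanded tensor bit-for-bit unchanged.

Numerical choices worth knowing:

* **Batches** are contiguous time blocks in reshuffled order, because the
  convolution couples neighboring samples; fully random sample batches
  would split events from the responses they cause.
* **Convergence** is declared when the relative change of the full-data
  loss across a 5-evaluation patience window falls below `convergenceTol`
  (default $10^{-6}$). The loss flattens before the component scales fully
  settle — the optimization valley is shallow along directions that trade
  scale between correlated components — so the parameter-recovery
  benchmarks tighten the tolerance to $10^{-8}$; prediction-oriented fits
  are insensitive to this and use looser settings for speed.
* **Divergence** (non-finite loss) aborts with the epoch number rather than
  returning garbage.
* The ridge penalty biases $\hat\alpha$ slightly toward zero, exactly as
  ridge shrinks regression coefficients; at the benchmark conditions the
  residual shrinkage after convergence is a few percent.

## Evaluation: noise ceiling and CCnorm

Repeated presentations of one held-out story give a noise ceiling per
channel. With $n$ repeats $y_1, \dots, y_n$, the signal power estimate is

$$SP = \frac{\mathrm{Var}_t\!\left(\sum_k y_k\right) - \sum_k \mathrm{Var}_t(y_k)}{n(n-1)},
\qquad CC_{max} = \sqrt{SP / \mathrm{Var}_t(\bar y)},$$

the maximum correlation any model of the repeat-shared signal could achieve
against the repeat mean. Channels whose estimate is non-finite,
non-positive, or below 0.2 are clamped to 0.2 and flagged — low-signal
channels otherwise produce wild normalized scores. Model performance is
$CC_{norm} = \mathrm{Corr}(\bar y, \hat M) / CC_{max}$ per channel;
estimator noise permits values slightly above 1 on well-fit synthetic data.
Mean CCnorm averages all channels by default (a flag restricts it to
unclamped channels, since the convention is not canonical).

The excess-predictability analysis (`excessCCmax()`) recomputes the ceiling
on concatenated subsets of samples falling in 100 ms windows after word
onsets (eight windows covering 0–800 ms by default) and subtracts the
whole-series ceiling: positive excess in a window means the signal is more
predictable at that latency. When words are closer than the maximum lag, a
sample belongs to every window it falls in for any word (the alternative —
nearest preceding word only — is a config option; neither convention is
canonical). PCA over channels of the windows-by-channels excess matrix
(`excessPCA()`) summarizes the dominant latency profiles.

Two significance tests accompany model comparisons: a bootstrap over
channels (`bootstrapCompare()`, resampling channels with replacement,
one-sided) and a permutation test against chance (`permutationTest()`,
circular time shifts of the prediction by at least `blockLen` samples, so
autocorrelation is preserved and the zero shift is never in the null; the
p-value uses the add-one convention, so a perfect prediction yields
$1/(n_{perm}+1)$). The resampling units — channels for the bootstrap,
circular shifts for the permutation — are the package's choice and are
recorded in its outputs.

## Interpretation

For a normalized filter, `componentWeights()` returns
$W_{r,t} = \alpha_r \sum_{n,d} U^D_{r,d} U^E_{r,n} X_{t-d,n}$, the strength
of component $r$'s channel pattern at time $t$; the prediction reconstructs
exactly as $\hat M_{t,c} = \sum_r W_{r,t} U^C_{r,c}$, which the tests assert
to $10^{-8}$. `looInfluence()` scores each component by the drop in mean
CCnorm when it is excluded; components are reported most-influential first.
`topContexts()` ranks corpus contexts (by default all sliding 5-word
windows of the transcripts, embedded externally) by the raw dot product of
their embedding with $U^E_r$ — cosine scoring is available but the raw dot
product is the default, matching the definition of the model's drive. Ties
break by corpus order. `delayPower()` and `channelPower()` summarize where
the model's energy sits: $Q^D_d = \sum_r \alpha_r^2 (U^D_{r,d})^2$
normalized to unit Euclidean norm (a sum-to-one option exists; the
Euclidean reading of the normalization is the default).

## Low-level controls and residualization

`buildControlDesign()` assembles an intercept, a log-mel spectrogram
lagged over 15 delays, and three binary event series (word onset, sentence
start, sentence end). The spectrogram path resamples audio to 16 kHz,
computes a Hann-windowed power spectrogram with a 25 ms hop, applies an
80-band triangular mel filterbank, takes a floored log (relative floor
$10^{-10}$, so silence is finite), and linearly interpolates frame centers
onto the 50 Hz recording grid. The 15 delays apply to the spectrogram only;
lagging the binary events equally is exposed as an option because the
convention is ambiguous. `residualize()` fits a ridge-less full-rank model
of the recordings on these controls over the *combined* train and test
stories — reproducing the reference procedure verbatim; a strict
`"train-only"` mode is provided and flagged, since joint fitting leaks test
data by conventional standards — subtracts the control prediction, and
re-z-scores the residuals per channel per story because all subsequent
fitting assumes z-scored inputs. With the intercept included,
residualization is a projection: repeating it changes nothing (exactly for
a single story; to numerical tolerance across stories, where per-story
rescaling perturbs joint orthogonality).

Re-z-scoring rescales each channel, so the generating filter of the
residual data has its channel factors divided by the applied scale; recovery
comparisons after residualization map the ground truth through that scale
before matching.

## The synthetic generator

No public recording accompanies the method, so `simulateDataset()` builds
datasets with the statistical structure the model assumes, and every
benchmark in the package runs on them:

* **Word timing**: inter-onset gaps are geometric (discrete, memoryless)
  with mean 20 samples (400 ms at 50 Hz) — the simplest stationary point
  process with natural-timing flavor; the first onset is forced into range
  so a story never has zero words.
* **Sentences**: lengths uniform on 4–15 words; first word flagged start,
  last flagged end. Only the flags' downstream use matters, so no richer
  prosodic model is attempted.
* **Embeddings**: zero-mean Gaussian with a diagonal covariance whose
  eigenvalues decay geometrically (ratio 0.85), mimicking the effective
  low-dimensionality of language-model embeddings.
* **Ground truth**: a normalized CP filter with smooth Gaussian-bump delay
  profiles, random unit embedding/channel directions, and well-separated
  positive scales (default $\alpha = (R, R-1, \dots, 1)$).
* **Noise**: white Gaussian per channel. Real MEG noise is neither white
  nor channel-independent; whiteness is sufficient for every property the
  benchmarks assert, and is stated here so nobody mistakes a passing test
  for evidence about correlated-noise robustness.
* **Repeats**: one held-out story is rendered `nRepeats` times with shared
  signal and independent noise.

Everything is deterministic given the seed; word streams are deterministic
given (seed, story index).

What passing tests show — and what they do not: the benchmarks establish
that the estimator recovers the generating process under the model's own
assumptions (well-specified filter, white noise, stationary timing) and
that the evaluation machinery is calibrated. They cannot certify behavior
under model misspecification, correlated sensor noise, or non-stationary
speech statistics.

## Benchmark problem sizes

The test suite and the acceptance script run at sizes chosen so each check
exercises the estimator meaningfully on one CPU:

* Oracle equivalence: 200 random instances with $T \le 200$, $C \le 8$,
  $N \le 10$, $D \le 6$, $R \le 4$.
* Parameter recovery: 3 stories of $T = 30{,}000$, $C = 20$, $N = 15$,
  $D = 10$, rank 3 with $\alpha = (3, 2, 1)$, noise sd 0.1.
* Noise-ceiling calibration: $T = 20{,}000$, 5 repeats, signal and noise
  sd 1, against the closed form $\sqrt{1/(1 + 1/5)} \approx 0.913$.
* Inductive-bias comparison: one story of $T = 10{,}000$, $C = 12$,
  $N = 10$, $D = 8$, rank-3 truth, noise sd 0.3, ranks $\{3, 5, 10\}$
  versus the full-rank ridge, five seeds. The noise level is the package's
  choice: much below it every model saturates the ceiling and the
  comparison degenerates; much above it the fixed $\lambda = 0.1$ lets the
  rank-10 model overfit this short training length and the rank sweep no
  longer saturates. 0.3 is the regime in which both phenomena of interest —
  the full-rank model's overfit and the early rank saturation — are
  expressed and measurable above seed-to-seed Monte-Carlo error.
* Latency detection: signal injected only 100–200 ms post onset, SNR 1,
  50 replicates.
* Residualization: control-driven plus CP-driven signal at equal power plus
  noise at the same scale, $T = 12{,}000$.
* Permutation-test calibration: 200 independent null datasets, 99 shifts
  each, nominal level 0.05.

## Known limitations

* The low-rank solver is first-order; no ALS or second-order alternative is
  provided, and badly conditioned problems (near-collinear components,
  $\alpha$ ties) converge slowly along scale-trading directions.
* `ccMax()` assumes repeats share a deterministic signal with independent
  noise; adaptation or drift across repeats biases the ceiling.
* The dataset container is a plain directory of CSV matrices with a JSON
  sidecar — robust and diff-able, but not suited to very large arrays.
* Embedding PCA rotates without whitening; whether whitening would be
  preferable is left open deliberately, and the reducer records enough to
  add it downstream.
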