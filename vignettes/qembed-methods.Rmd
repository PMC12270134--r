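---
title: "Methods: quantum feature embedding, fidelity kernels, and the evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantum feature embedding, fidelity kernels, and the evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qembed)
```

This vignette is the package's own account of the model it implements, the
numerical choices behind it, and what the shipped tests do and do not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The model

### 1.1 Quantum feature map

A feature vector $x \in \mathbb{R}^n$ (in practice: the top $n$ principal
components of an expression matrix) is encoded into an $n$-qubit state by

$$|x\rangle = \Big[ V(\varphi(x))\, H^{\otimes n} \Big]^{L} |0\cdots0\rangle,
\qquad
V(\varphi(x)) = \exp\Big( i \sum_k \varphi_k(x) Z_k
                          + i \sum_{j<k} \varphi_{jk}(x) Z_j Z_k \Big),$$

with $L$ repetitions (default `reps = 3`), $\varphi_k(x) = 2x_k$ and
$\varphi_{jk}(x) = (\pi - x_j)(\pi - x_k)$ — the standard ZZ feature map. All
phase factors commute (an IQP block), so their order inside a repetition is
irrelevant; the suite checks this by applying them in random order.

Conventions fixed once and used everywhere:

* $\exp(i\varphi Z)$ acts as the diagonal $(e^{+i\varphi}, e^{-i\varphi})$,
  with qubit value 0 in the $+1$ eigenspace of $Z$.
* Basis order is lexicographic with qubit 1 as the least significant bit.
* Each repetition carries its own Hadamard layer (the circuit is
  $(P H)^L$, not $P^L H$); two-qubit phases are realized as CNOT–RZ–CNOT.
* Default two-qubit topology is all pairs $j<k$, matching the double sum; a
  linear chain is available (`topology = "linear"`) and coincides with the
  full topology at $n = 2$.

Fidelities are global-phase-free, so the sign convention only matters for
amplitude-level tests; it is pinned by the one-qubit closed form
$|x\rangle = (e^{2ix}, e^{-2ix})/\sqrt2$ at $L = 1$, which also gives the
kernel oracle $K(u,v) = \cos^2 2(u-v)$ used throughout the suite.

Simulation is by exact statevector with a hard limit of 14 qubits: at the
4–12 qubit range this analysis targets, $2^n$ amplitudes stay desk-scale,
and shot noise is a choice rather than a necessity. `sampled_fidelity()`
mirrors hardware semantics (frequency of the all-zeros outcome of
$U^\dagger(v)U(u)|0\rangle$) and is checked against the binomial sampling
law, but every kernel in the pipeline uses exact fidelities.

### 1.2 Neural Quantum Embedding

Raw ZZ-embedded expression components separate the classes poorly. NQE
prepends a trainable network $g(x, w)$ — input $d$, one hidden layer of $2d$
tanh units, linear output of dimension $d$ (one angle per qubit) — and trains
$w$ under the fidelity loss

$$F\big((x_j, y_j), (x_k, y_k)\big)
  = \Big[\, |\langle x_j | x_k\rangle|^2 - \tfrac12 (1 + y_j y_k) \Big]^2,
  \qquad y \in \{-1, +1\},$$

so same-label pairs are pushed toward overlap 1 and different-label pairs
toward orthogonality. Labels are held internally as $-1/+1$ precisely so
that $\tfrac12(1 + y_j y_k) \in \{0, 1\}$ is exact.

Training is plain SGD (learning rate 0.01, 1000 iterations, 10 pairs per
step by default — the study configuration). Choices the loss description
leaves open, decided here:

* **Pair sampling.** Each iteration draws `batch_size` ordered pairs
  uniformly with replacement — an unbiased estimator of the all-pairs loss.
  At the zero-weight initialization (all samples embed identically) the
  expected batch loss is therefore exactly the different-label ordered-pair
  fraction $2p(1-p)$, which the suite verifies by Monte Carlo.
* **Gradients.** Exact, not estimated: backpropagation through the network
  composed with adjoint differentiation of the fidelity with respect to the
  embedding angles (the statevector is a smooth function of the diagonal
  phases; one forward pass caches the per-repetition states, one backward
  sweep accumulates $\langle \psi_{\text{other}} | \partial_m \psi \rangle$).
  A central-finite-difference check (step $10^{-6}$, agreement $10^{-4}$
  relative) is part of the suite.
* **Activation.** Smooth saturating tanh on the hidden layer, linear output:
  output angles need no bounding because phases are periodic.
* **Output dimension.** Defaults to the input dimension (one qubit per
  principal component, as in every experiment this package mirrors);
  compressive embeddings (`d_out < d_in`) are supported via `nqe_model()`.

### 1.3 Fidelity-kernel SVC

The quantum kernel $K(x,z) = |\langle 0|U^\dagger(z) U(x)|0\rangle|^2$ is a
Gram matrix of explicit statevectors, hence symmetric PSD with unit diagonal
up to floating error. The SVC is fitted in the dual on the precomputed
kernel:

$$\max_\alpha \sum_k \alpha_k - \tfrac12 \sum_{j,k} \alpha_j \alpha_k y_j y_k K_{jk}
  \quad \text{s.t.} \quad 0 \le \alpha_k \le C, \;\; \sum_k \alpha_k y_k = 0.$$

The box constraint is the standard soft-margin form: a hard-margin dual
($\alpha \ge 0$ only) would leave the tuned parameter $C$ meaningless.
The solver is SMO-style pairwise coordinate ascent on the maximally
KKT-violating pair (stopping tolerance $10^{-8}$); the contract is objective
agreement with a generic QP solution, which the suite checks against
`kernlab::ipop`. The bias $t$ of the decision function
$\mathrm{sign}(\sum_k \alpha_k y_k K(x, x_k) - t)$ is averaged over
unbounded support vectors. Numerical edges:

* **PSD repair.** Train-kernel eigenvalues in $[-10^{-8}, 0)$ are clipped to
  zero (a warning is raised above the $-10^{-13}$ float-dust level);
  anything below $-10^{-8}$ is an error, since a fidelity Gram matrix cannot
  be meaningfully indefinite.
* **Prediction ties.** A decision value of exactly zero resolves to the
  majority training class — deterministic and documented.

The fidelity kernel has no bandwidth parameter, so only $C$ is grid-searched
for the QSVC; inventing a "quantum gamma" would have no referent. The RBF
baseline searches both $C$ and $\gamma$.

### 1.4 Classifier baselines

The classical NN is a hand-rolled MLP (tanh hidden layers, logistic output,
full-batch gradient descent on cross-entropy) because its contract exposes
learning rate, epochs and hidden-layer count as SGD-style hyperparameters
and requires seed-reproducible untrained weights at `epochs = 0`. The QNN is
a sampler-style variational classifier: feature-map state, then per layer a
single-qubit $R_y(\theta)$ rotation on every qubit and a CNOT entangling
ring. Readout is bitstring parity (odd parity $\mapsto$ class $+1$) — the
standard basis-complete two-class readout for such circuits; the exact
ansatz/readout of published "SampleQNN" configurations is not specified, so
these are documented defaults, not reconstructions. Gradients use the
parameter-shift rule ($R_y$ generator has eigenvalues $\pm\tfrac12$, so
$\partial_\theta P = [P(\theta + \tfrac\pi2) - P(\theta - \tfrac\pi2)]/2$
exactly), checked against finite differences.

## 2. The evaluation protocol

Ten metrics are computed from the 2×2 confusion matrix (positive = the
internal $+1$ minority class): TPR, SPC, PPV, NPV, FPR, FDR, FNR, ACC, F1,
MCC. Conventions:

* **Zero denominators** set the metric to 0 and flag it in `undefined`
  rather than propagating NaN — silent NaNs would poison comparative scores
  on degenerate folds.
* **Comparative scoring** awards one point per metric to the strictly better
  side (lower is better for FPR/FDR/FNR) after rounding both values to 3
  decimals, matching published reporting precision; equality at that
  precision is a tie. This reproduces all four published scoreboard columns,
  including the tie ("tier") entries.
* **Cross-validation** is stratified; the fold standard deviation is the
  population form (divide by the fold count) — the mean±sd reporting
  convention is otherwise underdetermined.
* **Grid search** runs twice: a coarse logarithmic stage
  ($C \in 10^{-3..3}$, $\gamma \in 10^{-4..1}$), then 5 points per axis
  spanning one decade geometrically around the stage-1 winner. Ties break
  toward smaller $C$ — the weaker-regularization-last rule keeps winners
  deterministic on flat score surfaces.

### Ordering decisions

* **Split before everything.** PCA is fitted on the training partition only
  and applied to the held-out set; SMOTE sees only training samples. The
  published workflow draws PCA before balancing without specifying fit
  scope; train-only fitting is the leakage-safe reading and is the default
  (`fit_pca` on any dataset is available for the alternative).
* **SMOTE before NQE and before grid-search CV.** The embedding and the
  hyperparameter search both see the balanced training set, following the
  published oversample-then-cross-validate order. The known cost of this
  order is that validation folds contain synthetic samples, which tends to
  flatter cross-validated scores relative to fold-internal oversampling;
  held-out test metrics are unaffected because the test partition is split
  off first and never balanced. Training on the raw split is a one-line
  change (`balance = FALSE`).
* **Stratified splitting** preserves class proportions to rounding (a 2/3
  split of 424/78 gives 282/52). Published per-class counts (286/48) deviate
  from proportionality and the exact procedure is unrecoverable, so
  `split_dataset(class_counts = c(neg = 286, pos = 48))` reproduces them
  exactly when needed.
* **SMOTE neighbours** default to the canonical $k = 5$ (truncated to
  minority size minus one); synthetic points are uniform convex combinations
  of a minority sample and one of its $k$ nearest minority neighbours.

## 3. The synthetic benchmark

`generate_two_class()` draws two multivariate Gaussians with shared
(default diagonal) covariance, means separated by `separation` along the
first coordinate. Defaults emulate the motivating cohort's shape: 424/78
majority/minority (5.44:1), 48 features. This is deliberately the simplest
structure exhibiting the heavy class overlap seen in the real cohorts'
PCA plots; the distributional form of real post-selection expression values
is unknown, and the Gaussian stand-in is a modeling choice, not a claim
about them.

Problem sizes used by the shipped tests and acceptance script (chosen as the
package's own desk-scale benchmark conditions): the NQE benchmark is 15+15
samples in 2 dimensions at separation 3, $\sigma^2 = 0.25$, trained with the
study-default configuration (1000 iterations, batch 10, lr 0.01) across ten
seeds; kernel oracles run at $n \le 4$ qubits; SVC oracles on 12–14-sample
toys; the cohort-arithmetic checks at the published 502/334/286/48 sizes.

What passing these tests shows: the embedding circuit, loss, gradients,
dual solver, metrics and protocol arithmetic are correct, and NQE training
demonstrably increases intra- vs inter-class state fidelity on separable
low-dimensional data. What they do not show: that any classifier here
attains published absolute scores on the real TCGA/Xena cohorts (out of
scope to download), or that quantum kernels beat RBF kernels on Gaussian
synthetic data — on such data the RBF baseline usually wins, as its
smoothness assumptions exactly match the generator (see the README's worked
example, which prints a 10–0 scoreboard for the classical side).

## 4. Known limitations

* Exact simulation caps at 14 qubits; no tensor-network or hardware path.
* No noise models; `sampled_fidelity()` models shot noise only.
* The QNN ansatz/readout are minimal documented defaults, not tuned
  architectures; no architecture search is provided.
* No multiclass extension, probability calibration, ROC/AUC, or
  significance testing between classifiers — the protocol mirrors the
  ten-metric comparative design it implements.
* SMOTE interpolation assumes continuous features; count-scale expression
  should be transformed (e.g. log) upstream.
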