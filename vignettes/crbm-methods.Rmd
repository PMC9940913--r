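---
title: "Compositional RBMs for binary neural population activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional RBMs for binary neural population activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crbm)
```

## The model

`crbm` models the joint activity of `N` binary neurons $v \in \{0,1\}^N$
recorded over time together with `M` real-valued latent *hidden units*
$h \in \mathbb{R}^M$ through the energy

$$E(v, h) = -\sum_i g_i v_i + \sum_\mu U_\mu(h_\mu) - \sum_{i\mu} w_{i\mu} v_i h_\mu,
\qquad P(v,h) = \frac{1}{Z} e^{-E(v,h)},$$

a restricted Boltzmann machine on a bipartite graph: neurons couple only to
hidden units. The set of neurons with appreciable weight to a unit is its
*neural assembly*. Each hidden unit carries a double-rectified linear
(dReLU) potential

$$U(h) = \tfrac{1}{2}\gamma_+ h_+^2 + \tfrac{1}{2}\gamma_- h_-^2
       + \theta_+ h_+ + \theta_- h_-, \qquad h_\pm = \max/\min(h, 0),$$

which interpolates between quadratic ($\gamma_+=\gamma_-$,
$\theta_+=\theta_-$), ReLU-like, and double-well shapes. This choice
matters: with quadratic potentials the marginal $P(v)$ collapses to a
pairwise (Hopfield) model with interactions
$J_{ij} = \sum_\mu w_{i\mu}w_{j\mu}/\gamma_\mu$ — a fact the test suite
exploits as a closed-form oracle — whereas dReLU units produce the
higher-order interactions needed for assembly-style co-activation, and can
express the *compositional* operating regime in which each frame engages a
small-but-plural number of units.

Both conditionals are tractable. Given $v$, unit $\mu$ receives input
$I_\mu = \sum_i w_{i\mu} v_i$ and its conditional density
$\propto e^{-U(h) + hI}$ is a two-branch truncated Gaussian; given $h$,
neurons are independent Bernoulli with
$P(v_i = 1|h) = \sigma(g_i + w_i^\top h)$. All inference rests on the
cumulant generating function
$\Gamma(I) = \log \int e^{-U(h)+hI}\,dh$, for which `drelu_cumulant()`
evaluates the closed form

$$\Gamma(I) = \log(Z_+ + Z_-), \qquad
Z_+ = e^{b^2/2\gamma_+}\sqrt{2\pi/\gamma_+}\,\Phi(b/\sqrt{\gamma_+}),\quad
b = I - \theta_+,$$

(and the mirrored $Z_-$), with $\Gamma'(I) = \langle h|I\rangle$ and
$\Gamma''(I) = \mathrm{Var}(h|I)$ assembled from truncated-Gaussian
moments.

### Numerical choices

* All branch masses are computed in log space through
  `pnorm(log.p = TRUE)`, so inputs of order $\pm 10^3$ neither overflow
  nor return `NaN`.
* Truncated-Gaussian moments need $\lambda(\alpha) =
  \phi(\alpha)/\Phi(-\alpha)$; the naive variance formula
  $1 + \alpha\lambda - \lambda^2$ cancels catastrophically in the far
  tail. We instead compute the gap $d(\alpha) = \lambda(\alpha) - \alpha$
  (direct log-space difference up to $\alpha = 30$, an asymptotic series
  in $1/\alpha^2$ beyond) and use $\mathrm{mean} = \sigma d$,
  $\mathrm{Var} = \sigma^2(1 - d(\alpha + d))$. The mixture variance is
  assembled from within-branch variances plus the between-branch spread,
  never as $\langle h^2\rangle - \langle h\rangle^2$ across branches.
  Against adaptive quadrature of the defining integral the relative error
  stays below $10^{-12}$ over $I \in [-10, 10]$ for generic parameters.
* Sampling the conditional picks the branch by its exact mass and then
  inverts the truncated-Gaussian CDF via `qnorm(log.p = TRUE)`, which is
  stable arbitrarily far into the tail (rejection sampling is not).
* $U(0) = 0$ by both branch definitions; branch assignment exactly at 0
  has zero probability mass and is irrelevant.
* Exact enumeration (partition function, exact moments, enumerated
  $P(v)$) is guarded at $N \le 20$ ($\approx 10^6$ states) and chunked to
  bound memory; tests use $N \le 10$.

## Training

`fit_crbm()` maximizes the $L_1$-penalized likelihood
$\mathcal{L} = \langle \log P(v)\rangle_{\mathrm{data}} -
\lambda \sum_{i\mu} |w_{i\mu}|$ by persistent contrastive divergence:
gradients are moment differences
($\partial\mathcal{L}/\partial w_{i\mu} = \langle v_i h_\mu\rangle_{data}
- \langle v_i h_\mu\rangle_{model}$, and analogously for $g$,
$\theta_\pm$, $\gamma_\pm$ with the hidden branch moments), where
model-side moments come from persistent fantasy chains advanced by 15
Gibbs sweeps per update. On both sides the hidden layer is integrated
analytically given the visible states (conditional expectations from the
cumulant derivatives) — an unbiased, lower-variance estimator than using
raw hidden samples; the chains supply only the visible samples, which is
where the Monte Carlo difficulty actually lies. Correctness of the whole
gradient stack is pinned by a finite-difference test against the exact
enumerated log-likelihood on an $N=6$, $M=2$ system (relative error below
$10^{-5}$).

Updates use RMSprop ($\beta_2 = 0.999$, $\epsilon = 10^{-6}$) with the
learning rate decaying geometrically from $5\cdot10^{-3}$ to $10^{-5}$;
at the desk-scale default of 20000 updates the decay starts halfway
(the reference protocol decayed after a quarter of its $2\cdot10^5$
updates — constant-rate exploration phases should be compared in
updates, not fractions). How the $L_1$ term enters the adaptive update
turned out to be the single most consequential design choice, so both
treatments are implemented (`l1_mode`) and were dissected with a control
experiment that initializes PCD *at* a planted ground-truth model:

* `"rmsprop"` (default): the subgradient $-\lambda\,\mathrm{sign}(w)$ is
  added before the adaptive rescaling. Because RMSprop divides by the
  running gradient rms, the constant penalty is amplified into a
  learning-rate-scale force wherever the likelihood gradient is small.
  That force is exactly what breaks the rotational degeneracy of unit
  pairs that jointly span two assemblies (the likelihood's own
  preference for axis alignment is only fourth-order and resolves at a
  glacial $\sim 0.01$ cosine per thousand updates) — but the same
  amplification biases weights downward, and in the control experiment
  it can erode the weakest planted assembly entirely.
* `"proximal"`: the likelihood gradient alone is adaptive and sparsity
  is a decoupled soft-threshold of $\mathrm{lr}\cdot\lambda$ per update.
  Under this scheme the planted truth is numerically a fixed point (all
  similarities $\ge 0.994$ after 4000 updates started at it), but
  rotated unit pairs barely separate within a desk-scale run.

The default accepts the small shrinkage bias in exchange for
identifiability; the disconnection risk it carries is what the curvature
floor and the reseeding device (below) are for. Remaining defaults:
batch size 100, 100 chains, $\lambda = 0.02$. Divergent runs (weight
standard deviation beyond a bound) restart at half the learning rate, at
most three times. Everything is deterministic given `seed`: the whole run
consumes one explicitly-seeded generator, so two fits with the same
configuration are bit-identical.

### Hidden-unit normalization

The compositional regime requires that no unit dominates and none
disconnects; we enforce $\mathrm{Var}(h_\mu) \approx 1$ on the activity
traces $h_\mu(t) = \Gamma'_\mu(I_\mu(v_t))$. `hu_normalization()` applies,
every update, the *exact* reparameterization $h \to h/s$, $w \to ws$,
$\gamma_\pm \to \gamma_\pm s^2$, $\theta_\pm \to \theta_\pm s$ (which
leaves $P(v)$ untouched) with a damped, clipped per-step factor. An
optional $\theta_\pm$ nudge toward zero trace mean exists
(`hu_center_rate`) but is **off by default**: centering is not an
invariance, and a control experiment that initialized PCD at a planted
ground-truth model showed it actively degrades the fit — true units with
asymmetric well occupation (trace mean far from 0) get their well
balance forcibly driven toward one half, which the likelihood then has
to fight. Near-zero means are treated as a loose emergent property, not
a constraint. Two further safeguards matter in practice and were found
the hard way:

* the per-step factor is clipped to $[1/1.15, 1.15]$ — early in training
  all traces are nearly constant and an unclipped correction would
  instantly crush the curvatures into their floor;
* the factor never pushes $\gamma_\pm$ below the curvature floor
  (0.05). Without this, a weak unit's weights get scaled down while the
  clipped curvature no longer compensates, the trace never re-inflates,
  and the unit bleeds irreversibly to zero — we observed exactly one such
  dead unit per benchmark run before adding the bound.

RMSprop second moments are rescaled consistently with the
reparameterization so the optimizer state remains meaningful.

### Initialization

Fields start at the logit of each neuron's empirical rate (clipped to
$\pm 10$); $\theta_\pm = 0$, $\gamma_\pm = 1$. Weight columns start as
small i.i.d. noise **plus a faint copy (scale 0.05) of one randomly
drawn, centered data frame per unit**. The frame term matters: with pure
noise init, which assembly a unit commits to in the first few hundred
updates is a race settled by random overlaps, several units regularly
pile onto the same strong assembly, and — because an uncovered assembly
exerts no first-order gradient on units committed elsewhere (its neurons
are uncorrelated with those units' activities) — the redundancy never
resolves afterwards. Seeding each unit with a direction that actually
occurs in the data spreads the commitments across assemblies. The frame
scale is small enough to be overwritten within the first hundred updates
when it points nowhere useful.

Frame seeding reduces but does not eliminate duplication, so training
additionally performs **redundant-unit reseeding** during the
constant-learning-rate phase: every 500 updates, if two weight columns
exceed 0.8 absolute cosine similarity, the weaker unit is reinitialized
from a fresh random data frame (with its potential and optimizer state
reset). This is the RBM analogue of reinitializing an empty cluster in
k-means: a redundant unit contributes nothing its stronger twin does not
already model, so replacing it costs essentially no likelihood and gives
an uncovered assembly another chance to be found. Reseeding stops when
annealing begins, leaving the final convergence undisturbed.

The exact reparameterization used by the original implementation of this
model family is unpublished; only its target (unit variance, near-zero
mean) is testable, and the suite checks it post hoc
($\mathrm{Var}(h_\mu)$ on data within $[0.5, 2]$ after a benchmark fit,
and exact $\mathrm{Var} \to 1$ for the standalone operation). The $L_1$
penalty applies to the weights only, as written in its defining
expression; the fields $g$ are unpenalized.

## Generation and evaluation

`generate_model_statistics_dataset()` reproduces a fixed protocol for
estimating model statistics: 300 chains initialized on random training
frames, 50 configurations saved per chain, 20 sweeps apart, after a
burn-in of 100 *effective configurations*. We read "effective
configuration" as one save interval (so 2000 raw sweeps); the reading is
exposed as `burn_in_unit` because the phrase is ambiguous, and a
stationarity test confirms the default burn-in suffices on enumerable
systems.

Goodness of fit compares five statistic sets between train data, withheld
test data, and model samples: $\langle v_i\rangle$,
$\langle h_\mu\rangle$, $\langle v_i h_\mu\rangle$ (sparsity-corrected by
$+\lambda\,\mathrm{sign}(w_{i\mu})$, zero-weight pairs masked), and the
centered pairwise $\langle v_i v_j\rangle$, $\langle h_\mu h_\nu\rangle$.
Each is summarized by the normalized RMSE
$$\mathrm{nRMSE} = 1 - \frac{\mathrm{RMSE}_{ordinary} -
\mathrm{RMSE}_{shuffled}}{\mathrm{RMSE}_{optimal} -
\mathrm{RMSE}_{shuffled}},$$
anchored so shuffled statistics score 1 and the train-vs-test difference
scores 0 (negative values mean the model beats the train/test gap). The
shuffled reference permutes the model and test vectors independently with
one seeded permutation each, recorded in the report. Train/test splits
cut the recording into 10 chronological segments, score all
$\binom{10}{3} = 120$ held-out triples by train-test statistic RMSE, and
select the 10th-percentile split — robust without being the best case.

Reconstruction quality maps test frames through
$v \to \Gamma'(I(v)) \to \sigma(g + Wh)$ and scores each neuron's
Bernoulli log-likelihood, normalized so the constant mean-rate predictor
scores 0 and perfection scores 1. The probability floor ($10^{-7}$) is
applied only where the likelihood would vanish, so the perfect-prediction
anchor is exactly 0. The fully-connected baseline (`glm_baseline()`) is a
ridge logistic regression per neuron on all others (glmnet, with
intercept; penalty expressed as the total ridge coefficient of the
summed-loss objective).

Compositional-phase diagnostics: each unit's bimodal trace is
characterized by a 2-component Gaussian mixture (mclust; transition point
= midpoint of the component means, inactive peak = lower component;
degenerate fits flagged unimodal), and
$m(t) = \mathrm{PR}(h(t) - h_{inactive})$ counts effectively active units
per frame via the participation ratio
$\mathrm{PR}(x) = (\sum x^2)^2/\sum x^4$. As printed, PR lies in
$[1, n]$, yet the texts that multiply "PR" by a count only make
dimensional sense for the normalized variant $\mathrm{PR}/n$; we resolve
the inconsistency by using the normalized variant wherever a product with
a count appears, so $m(t) \in [1, M]$ (frames with no active unit are 0
by convention) and effective region counts lie in $[1, R]$. The
compositional criterion is $1 \ll \mathrm{median}(m) \ll M$.

Oscillation time constants segment traces into sign runs (hidden units,
after transition-point subtraction) or no-spike/spike runs (neurons, raw
binary — no subtraction) and report the median duration of consecutive
(inactive, active) run pairs, in seconds.

## Connectivity

The functional connectivity estimator perturbs one neuron in silico and
measures the log-odds response of another under the model marginal:
$$J_{ij}(v) = \log\frac{P(v_i{=}1|v_{\setminus ij}, v_j{=}1)}
{P(v_i{=}1|v_{\setminus ij}, v_j{=}0)} -
\log\frac{P(v_i{=}0|\ldots, v_j{=}1)}{P(v_i{=}0|\ldots, v_j{=}0)},
\qquad J_{ij} = \langle J_{ij}(v)\rangle_{data}.$$
It is symmetric, vanishes for independent models, and for a pairwise
model equals the Ising coupling for every $v$ — all three facts are
tested. The exact average costs $O(N^2MT)$ and is guarded; the production
estimator is the second-order form
$J_{ij} = \sum_\mu w_{i\mu} w_{j\mu} \langle\Gamma''_\mu\rangle_{data}$,
exact for quadratic potentials (equality to $10^{-8}$ in that limit) and
rank-correlated $> 0.95$ with the exact form on generic desk-scale
models. Neuron-level diagonals are 0 (self-coupling is meaningless under
the perturbation definition).

Region aggregation takes the mean absolute coupling over region-pair
blocks (within-region blocks exclude the diagonal; regions under 5
neurons are dropped); multi-animal averages weight each region pair by
recording length times mean regional neuron count. The structural
estimator turns single-neuron morphology into region-pair connection
strength: neurons with somata in $r$ contribute their neurite length in
$r'$ per unit volume, normalized by the soma count — anchored at the
soma, it credits no indirect pass-through connections, unlike the legacy
soma-agnostic variant that is also provided; symmetrization is the
arithmetic mean of the two directed values, falling back to the defined
direction when a region holds no somata (masked if neither does).
Regional occupancy uses absolute weights in $L|w_\mu|$ (the sign of a
coupling does not change which region an assembly occupies). Matrix
comparisons vectorize one strict triangle, drop masked pairs, optionally
drop exact structural zeros, and use Spearman for structure-function
comparisons (no linearity assumption) or Pearson (optionally on log10
values) between functional matrices.

## The synthetic benchmark

`planted_model()` builds ground-truth models whose weight matrices carry
index-contiguous, optionally overlapping assemblies with small background
noise, and calibrates the fields by short Gibbs runs until the sampled
mean activity sits in a target band. The default geometry — the study
condition for every recovery test — is N = 200 neurons, M = 10 assemblies
of 20 neurons, 10% overlap between neighbors, mean activity 0.05,
T = 20000 frames.

The dReLU defaults deserve explanation. Early designs made assemblies
bistable purely through visible-hidden feedback (quadratic-ish potentials,
strong weights); that regime is razor-thin — slightly strong couplings
lock assemblies permanently ON, slightly weak ones never activate. The
shipped defaults instead give every unit an intrinsic double-well
potential ($\gamma_\pm = 1$, $\theta_+ = -1.5$, $\theta_- = 3$: active
well at $+1.5$, inactive well at $-3$, the latter deeper) with moderate
coupling (scale 0.4). Units then switch between wells on telegraph-like
timescales regardless of the visible state, each assembly is ON in
roughly 20% of frames, members fire at $\approx 0.17$ versus
$\approx 0.02$ baseline, and the effective number of simultaneously
active assemblies sits near 2.4 of 10 — squarely the compositional
regime. Recordings are drawn from several independent chains (default 10)
so slow switching cannot trap a whole recording in one latent state.

What the generator emulates: sparse overlapping assemblies, bimodal
latent activity, low firing rates, compositional frame structure,
assembly-aligned anatomy with known structural ground truth. What it does
not: calcium-indicator dynamics and deconvolution noise (the model starts
at binarized spikes), spatially graded assembly membership,
heavy-tailed firing-rate distributions, non-stationarity, and
inter-animal variability. Passing the recovery benchmark therefore shows
the estimator chain is correct and well-conditioned at realistic scale —
not that real recordings satisfy the model.

`assembly_recovery_score()` matches learned to true weight columns by
sign-invariant cosine similarity under an optimal assignment (a compact
Hungarian solver, checked against brute-force enumeration), and the
acceptance benchmark requires at least 9 of 10 assemblies above 0.8
similarity, plus AUC > 0.9 for ranking truly coupled region pairs from
the region-aggregated fast couplings.

## Problem sizes and determinism

The test suite runs enumerable systems at $N \le 10$ (oracles at machine
precision), Monte Carlo checks at $10^6$ samples ($z < 4$), quadrature
comparisons over $I \in [-10, 10]$, and one full benchmark fit
(N = 200, M = 10, T = 20000, 30000 updates — minutes on one CPU, chosen
so recovery is nontrivial but routine). Every stochastic operation takes
an explicit seeded generator (`crbm_rng`), never the global RNG stream;
identical seeds give bit-identical results, including whole training
runs.

## Known limitations

* Training cost is dominated by Gibbs sweeps in interpreted vectorized
  code; whole-brain scale ($N \sim 10^4$, $2\cdot10^5$ updates) is out of
  desk scope, though nothing in the algorithm changes.
* Likelihoods are only exact on enumerable systems; at scale, moment
  matching and reconstruction scores are the (standard) proxies, and
  annealed importance sampling is deliberately not provided.
* The mean-centering part of hidden-unit normalization is a soft nudge,
  not an exact constraint; trained traces center near, not at, zero.
* The GLM baseline refits one regression per target neuron and is
  intended for subsets of neurons, not whole recordings.
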