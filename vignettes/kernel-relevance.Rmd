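---
title: "Kernel-alignment feature relevance: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-alignment feature relevance: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckalign)
```

## The model

`ckalign` treats feature selection as a supervised metric-learning problem.
For samples $x_n \in \mathbb{R}^P$ with class labels $l_n$, a linear
projection $A \in \mathbb{R}^{P \times M}$ defines a Mahalanobis-type
distance $d^2_A(x_n, x_{n'}) = (x_n - x_{n'}) A A^\top (x_n - x_{n'})^\top$,
equivalently the Euclidean distance between projected samples $x A$. A
Gaussian kernel on those distances, $K_X = \exp(-d^2_A / 2\sigma^2)$, is
compared against the class-membership kernel $K_l$ through the empirical
centered kernel alignment

$$\hat\rho(K_X, K_l) =
  \frac{\langle \bar K_X, \bar K_l \rangle_F}
       {\sqrt{\langle \bar K_X, \bar K_X \rangle_F
              \langle \bar K_l, \bar K_l \rangle_F}},
  \qquad \bar K = \tilde I K \tilde I,\;
  \tilde I = I - \tfrac{1}{N}\mathbf{1}\mathbf{1}^\top,$$

a normalized dependence measure in $[0, 1]$. The fit maximizes
$\log \hat\rho$ over $A$ (and by default $\sigma$). Everything is computed
at the kernel-matrix level; the implicit feature maps of the two kernels are
never materialized.

The projection's rows then score the input features: feature $p$'s
relevance is $\varrho_p = \mathrm{mean}_m\, |a_{pm}|$. Because the learned
metric must pull same-class samples together and push classes apart to
raise the alignment, features that support that geometry accumulate weight
and irrelevant ones are driven toward zero rows. The score is nonnegative
and keeps a one-to-one correspondence with input features, which is what
makes the result interpretable per channel / rhythm / descriptor after EEG
feature extraction.

Two assumptions matter. First, relevance is read from a *linear* map, so a
feature only scores highly if some linear combination involving it improves
the kernel geometry; purely marginal class differences are not required
(the xor family below exercises exactly that), but the class structure must
be expressible through a projected Gaussian kernel. Second, the alignment
compares *all* pairs, so strong class imbalance tilts the objective toward
the majority class; the package does not reweight pairs.

## The gradient

The ascent uses an analytic gradient obtained by the chain rule through the
centering, the Gaussian kernel, and the projected-distance form. With
$\mathrm{num} = \langle \bar K_X, \bar K_l\rangle_F$,
$\mathrm{den} = \langle \bar K_X, \bar K_X\rangle_F$,
$G = \bar K_l / \mathrm{num} - \bar K_X / \mathrm{den}$ and
$W = -(G \circ K_X) / 2\sigma^2$,

$$\nabla_A \log\hat\rho = 4\, X^\top \big(\mathrm{diag}(W\mathbf{1}) - W\big) X A,
\qquad
\frac{\partial \log\hat\rho}{\partial \log\sigma} =
  \frac{1}{\sigma^2} \sum_{n,n'} G_{nn'}\, K_{X,nn'}\, d^2_{nn'}.$$

The derivation was validated against central finite differences *before*
the optimizer was built, and stays continuously validated: the suite checks
20 random instances per run at relative error $<10^{-5}$, plus a frozen
worked fixture whose finite-difference values were computed once and stored
(`worked_fixture()`).

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `tolerance` | 1e-6 | change in log-alignment | stop when accepted steps no longer move the objective |
| `max_iterations` | 300 | iterations | ascent budget; typical runs use all of it without harm |
| `learn_sigma` | `TRUE` | — | bandwidth is a free kernel parameter; optimized jointly, log-parameterized to stay positive. `FALSE` pins the median-heuristic value |
| `step_rule` | backtracking | — | Armijo search (c = 1e-4, shrink 0.5) guarantees a nondecreasing objective trace; `fixed` retained for study |
| `n_dim` (M) | 95% PCA variance | columns of A | dimension of the learned projection, from the eigenvalue spectrum of the standardized features |
| selection rule | `variance_explained`, 0.95 | fraction of relevance mass | shortest ranked prefix holding 95% of total $\varrho$; `mean_threshold` (strictly above mean) and `top_k` also available |
| `segment_length`, `segment_overlap` | 1 s, 0.5 | seconds, fraction | standard piecewise-stationary EEG analysis windows |
| bands | $\alpha$ 8–13, $\beta$ 14–30 Hz | Hz | the informative range for sensorimotor rhythms |
| rhythm bands | $\delta<4$, $\theta$ 4–8, $\alpha$ 8–13, $\beta$ 14–30 Hz | Hz | canonical clinical rhythms for the cepstral bank |
| `k_grid` | 1, 3, 5, 7, 9, 11 | neighbours | k-NN capacity grid, tuned in the inner CV loop |

Two coexisting selection criteria (strict mean threshold and 95% of
relevance mass) are both implemented because both are defensible readings
of "keep the separability-contributing features"; the mass rule is the
default since it has an explicit, continuous parameter. When the strict
mean threshold degenerates (all relevances tied) the selection falls back
to the single top-ranked feature with a warning rather than emitting an
empty set.

The second-stage embedding dimension is chosen by the same
variance-explained rule on the selected columns and can never exceed the
number of selected features — the constructive constraint $M_E \le M_S$,
since $A'$ has one row per selected feature.

## Internal standardization

`cka_fit()` z-scores feature columns internally and stores the center and
scale in the model (applied again by `predict()`). The projection therefore
lives in standardized coordinates, which makes $\varrho$ unit-free —
essential when the bank mixes variances (raw power) with ratios (relative
wavelet energy) and log-domain cepstra — and makes the PCA initialization
well defined. The unsupervised baseline `vra_relevance()` deliberately does
*not* rescale: it is a variance-reading instrument, and being captured by
high-variance nuisance features is precisely the failure mode it exists to
demonstrate.

## What the synthetic generators emulate

`simulate_tabular()` builds a features-by-samples table with a known
informative support:

- **linear_means** — class-shifted Gaussians on the support (separation 5,
  within-class noise 1, alternating shift sign across columns);
- **xor_nonlinear** — informative pairs centered on $(\pm c, \pm c)$ whose
  sign product encodes the class, so each column's marginal is uninformative
  while the pair is decisive;
- **radial** — class by distance shell in the support subspace.

The non-informative block is drawn from a low-rank factor model (8 shared
factors plus idiosyncratic noise, sd 0.3) rather than i.i.d. columns. Real
trial feature banks are strongly correlated — dozens of descriptors per
channel, neighbouring channels — and that correlation is what makes
"dimensions holding 95% of the variance" a meaningful, small number. With
fully independent noise columns the rule returns $M \approx P$ and relevance
cannot concentrate. All columns are z-scored after construction, emulating a
normalized bank and guaranteeing that marginal variance carries no class
information (so any advantage of the supervised ranking over the variance
baseline is structural, not an artifact of scaling).

Effect sizes were fixed once at clearly separable values (separation 5,
noise 1): the generators define recovery *test-beds* with unambiguous ground
truth, not hard benchmarks. `simulate_eeg()` adds a 1/f background plus a
class-modulated band-limited oscillation on designated channels (10 Hz
attenuation mimicking event-related desynchronization, or gated 3 Hz bursts
mimicking ictal discharges).

What they do **not** emulate: volume conduction and channel mixing, ocular
and muscular artifacts, non-stationary drift across a session, class
imbalance, and inter-subject variability. Passing tests on these families
shows the estimator recovers planted structure under controlled conditions;
it does not certify performance on recorded EEG.

## Numerical choices

- Degenerate alignment (single-class labels, constant features) raises an
  explicit error before any iteration — a silent 0/0 would corrupt the
  ascent. Denominators are guarded at 1e-300; no jitter is ever added to a
  kernel, preserving exactness of the estimator.
- Distances are computed as Euclidean distances of $XA$ (never forming the
  $P \times P$ matrix $A A^\top$), clamped at zero against round-off, and
  symmetrized; the Gaussian kernel keeps a unit diagonal by construction.
- Ranking ties break by original feature index, and the PCA initialization
  fixes each component's sign by its largest-magnitude loading, so every
  stage is bit-reproducible across platforms given a seed.
- Backtracking tries up to 40 halvings; if no step satisfies the Armijo
  condition the current point is declared converged (a numerically flat
  optimum) rather than accepting a decrease.
- Hjorth parameters use untapered segments and first differences as the
  derivative convention, which makes the sinusoid closed forms
  (activity $\approx 0.5$, mobility $\approx 2\sin(\pi f/f_s)$,
  complexity $\approx 1$) hold and testable; spectral extractors use
  Hamming-tapered segments.
- The cepstral log is floored at $10^{-12}$ of the spectrum's full scale,
  so silent frames yield finite coefficients and amplitude scaling shifts
  only the 0th coefficient.
- Wavelet decomposition uses periodized (circular) boundaries, making the
  filter-bank oracle comparison exact to round-off.
- Nested CV draws stratified folds, z-scores with training-fold statistics
  only, and resolves inner-loop ties toward the smallest k; fold seeds and
  these choices are echoed in every report.

## Problem sizes

The test suite and the acceptance script run the full method at 200 samples
and 40 features (6 informative) with 20 and 5 replicates respectively, and
the accuracy-vs-rank curve uses a stride schedule above 50 features (every
size up to 50, then geometric steps; `full_resolution = TRUE` disables it).
These sizes were chosen to characterize the estimator's behaviour cleanly at
desk scale; the algorithm itself is $O(N^2)$ per iteration in samples and
linear in features.

## Known limitations

- The alignment objective is non-convex; the PCA start is deterministic and
  worked well across the tested families, but it is one basin. Multi-start
  is not implemented.
- Relevance is read from a linear projection: interactions must be
  expressible through the projected kernel geometry. Fully kernelized
  (nonlinear-map) relevance is out of scope.
- Pair weighting is uniform, so heavy class imbalance biases the alignment
  toward the majority class.
- The $O(N^2)$ kernel limits direct use to a few thousand samples; no
  low-rank kernel approximation is provided.
- The EEG bank consumes already-preprocessed trials; artifact rejection,
  re-referencing and spatial filtering are upstream concerns.
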