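---
title: "Coupled GP dynamical models with collapsed variational inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled GP dynamical models with collapsed variational inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vcgpdm)
```

# The model

`vcgpdm` models multivariate movement time series as a small number of
interacting latent dynamical systems ("parts"), each observed through its
own block of columns.  For part $i$ with latent state
$x^i_t \in \mathbb{R}^{Q_i}$ and observed columns $y^i_t \in \mathbb{R}^{D_i}$:

* **Kinematics.**  $y^i_t = g^i(x^i_t) + \varepsilon$, with each component
  of $g^i$ drawn from a GP prior with an RBF (ARD squared-exponential)
  kernel and isotropic noise variance $\beta_i$.
* **Dynamics.**  Every ordered pair of parts $(i,j)$ carries a coupling
  function $f^{i,j}$ with a GP prior over part $i$'s stacked past states
  $(x^i_{t-2}, x^i_{t-1})$ (second-order autoregression by default; any
  order is supported by stacking more states).  Part $i$ predicts part
  $j$'s next state as a Gaussian with mean $f^{i,j}$ and variance
  $\alpha^{i,j}$.
* **Product of experts.**  The $M$ predictions for part $j$ are fused by
  multiplying the Gaussian densities and renormalizing, giving variance
  $\alpha_j = (\sum_i 1/\alpha^{i,j})^{-1}$ and a precision-weighted mean.
  A small $\alpha^{i,j}$ therefore means a strong influence of part $i$
  on part $j$; the $\alpha^{i,j}$ are learned, which lets the model
  discover the coupling structure, and can be modified after learning to
  recombine parts into new movements.

All GPs are sparsified with inducing points (IPs) and inducing values
(IVs): $P$ pseudo-inputs per function whose function values carry the
posterior.  IPs are variational parameters; IVs have the GP prior.  This
makes training linear in the sequence length and the stored model size
independent of it.

# The evidence lower bound

The latent posterior is restricted to a fully factorized Gaussian
$q(x) = \prod_{t,i,q} \mathcal{N}(\mu^i_{t,q}, \sigma^{2,i}_{t,q})$.
With this choice every bound term reduces to closed-form expectations of
kernel entries under diagonal Gaussians — the psi statistics

$$\psi_0 = \textstyle\sum_t E_q[k(x_t,x_t)],\quad
\Psi_1[t,p] = E_q[k(x_t, z_p)],\quad
\Psi_2[p,p'] = \textstyle\sum_t E_q[k(x_t,z_p)k(x_t,z_{p'})],$$

implemented in `psi0()`, `psi1()`, `psi2()` together with analytic
adjoints for gradient-based training.  The ELBO decomposes as

$$\mathcal{L} = \sum_i \mathcal{L}^i_{\mathrm{kin}} + \mathcal{L}_{\mathrm{dyn}}.$$

$\mathcal{L}^i_{\mathrm{kin}}$ (`collapsed_bound()`) is the standard
collapsed sparse-GP regression bound with uncertain inputs: the optimal
free-form Gaussian posterior over kinematics IVs is integrated out
analytically.  At full capacity (IPs at the inputs, point-mass beliefs)
it equals the exact GP log marginal likelihood; the test suite verifies
this against a direct Cholesky computation.

$\mathcal{L}_{\mathrm{dyn}}$ (`dynamics_bound()`) is the coupled
counterpart.  For target part $j$, write the expected log
product-of-experts likelihood as a quadratic form in the stacked IVs
$\tilde u = (u^{1,j}, \dots, u^{M,j})$.  Because $q(x)$ factorizes over
parts, the cross terms between two couplings $i \ne i'$ factor into
products of $\Psi_1$ rows, while same-coupling second moments involve
$\Psi_2$.  Maximizing over the free-form joint $q(\tilde u)$ and
integrating it against the block-diagonal GP prior
$\tilde K = \mathrm{blockdiag}(K_i)$ gives, with
$B_{ii} = \Psi_2^{i}/\alpha_i^2$,
$B_{ii'} = \Psi_1^{i\top}\Psi_1^{i'}/(\alpha_i\alpha_{i'})$ and
$h_q = \mathrm{stack}_i(\Psi_1^{i\top}\mu^j_q/\alpha_i)$:

$$\mathcal{L}^j_{\mathrm{dyn}} =
\tfrac12 \sum_q h_q^\top (\tilde K + \alpha_j B)^{-1} h_q
- \tfrac{Q_j}{2}\log\frac{|\tilde K + \alpha_j B|}{|\tilde K|}
- \tfrac{T_m Q_j}{2}\log 2\pi\alpha_j
- \frac{\sum(\mu^2{+}\sigma^2)}{2\alpha_j}
- \tfrac{\alpha_j Q_j}{2}\sum_i \frac{\psi_0^i - \mathrm{tr}(K_i^{-1}\Psi_2^i)}{\alpha_i^2}.$$

The derivation is validated three ways in the tests: (i) the collapsed
value equals the explicit expected log-likelihood minus the KL of the
optimal joint $q(\tilde u)$; (ii) the expected log-likelihood matches a
$10^5$-sample Monte-Carlo estimate; (iii) with $M = 1$ the expression
reduces (to machine precision, though not necessarily bit-for-bit, since
the algebraic arrangement differs) to an independently coded single-part
path built from `collapsed_bound()`.

The full dynamics bound adds the expected log-prior of the first `order`
states of every sequence under unit Gaussians, and the entropy of
$q(x)$.  The entropy belongs to the ELBO exactly once; we book it inside
$\mathcal{L}_{\mathrm{dyn}}$, and $\mathcal{L}^i_{\mathrm{kin}}$
excludes it, which avoids double counting in the sum over parts.

Because the targets of the dynamics likelihood, $x^j_t$, are themselves
random under $q$, the data-fit terms use the full second moment
$\mu^2 + \sigma^2$, and the overlap of autoregressive inputs across time
(each $x_{t-1}$ appears in two input tuples) is handled exactly: the log
likelihood decomposes per time step, so linearity of expectation applies
under the factorized posterior.

# Parameters that matter

* `latent_dim` ($Q$ per part, default 3 for mocap-like data; 2 for the
  synthetic system): dimensionality of each part's latent space.
* `n_dyn_ips`, `n_kin_ips`: inducing points per coupling / kinematics
  GP.  More IPs buy capacity at quadratic-in-$P$ cost; around 8–15 is
  typically enough for cyclic movement data.
* `order` (default 2): autoregressive order.  Second order captures
  velocity information; the input space of each coupling is
  `order * Q` dimensional.
* `alpha` ($\alpha^{i,j}$, initialized at 1): coupling variances, always
  trainable, optimized in log space.  Ratios of alphas into the same
  part are what matters; severing a coupling corresponds to
  $\alpha \to \infty$.
* Kernel lengthscales are stored as squared lengthscales $\lambda_q$
  (the divisor of the squared distance).  The coupling kernels have unit
  signal variance — the coupling scale is carried by the alphas — while
  the kinematics kernel learns a signal variance so observed columns
  need not be normalized.
* `beta` ($\beta_i$): kinematics noise variance, initialized at 1% of
  the part's data variance.

# Training

`fit_vcgpdm()` initializes latent means with the first $Q$
principal-component scores of the part's columns (`init_latent`), latent
variances at 0.1, inducing points by time-stratified sampling from the
initial latent trajectory (`init_inducing`), and lengthscales by the
median pairwise squared distance heuristic.  It then runs L-BFGS-B
(analytic gradients assembled from the psi-statistic adjoints) jointly
over all parameters — at most 500 iterations by default — followed by
blocked cycles over three groups: latent moments; kernel parameters,
noise and couplings; inducing points.  Cycles stop when the relative
ELBO change falls below `tol` ($10^{-6}$) or after `max_cycles`
(default 4).  When a composed model contains frozen, trained parts, the
new latent posterior is initialized by least-squares inversion of the
frozen kinematics map rather than by PCA: a trained part defines its own
latent coordinate frame, and PCA scores of the new data live in an
unrelated frame from which coupling-only retraining may never recover.  Positive parameters travel in log space with box bounds at
$\pm 30$; block coordinate ascent makes the trace non-decreasing up to
line-search tolerance, which the tests assert.  Multiple training
sequences are concatenated; the dynamics terms skip the first `order`
steps of every sequence and each sequence contributes its own
initial-state term.

# Generation and evaluation

`rollout()` iterates predictive means only (no sampling): each
coupling's sparse predictive mean at the stacked previous states, fused
by `poe_combine()`, then mapped through the kinematics predictive mean.
Stochastic rollout and uncertainty propagation are out of scope.
`dtw_mse()` scores generated against reference trajectories as the mean
squared frame difference along the optimal dynamic-time-warping path —
symmetric step pattern (diagonal/horizontal/vertical, unit weights), no
window, squared-Euclidean local cost, MSE = path cost / path length.
The MSE averages over time steps and degrees of freedom jointly.  Among
equal-cost paths the shortest is selected via a lexicographic dynamic
program, which makes results deterministic and lets the implementation
match an exhaustive path-enumeration oracle exactly on small alphabets.
`cross_validate()` holds out one complete trial per fold, initializes
generation from the held-out trial's first two frames (latents found by
least-squares inversion of the kinematics mean map), and reports the
fold mean and its standard error.

# The synthetic generator

`make_synthetic_dataset()` reproduces a two-part coupled construction
with known ground truth: transition functions $g^1, g^2$ are single
consistent draws from an RBF GP prior (`gp_function_sampler`, by
incremental conditioning on all previous evaluations), latents evolve as
first-order systems

$$x^1_t = g^1(x^1_{t-1}), \qquad
x^2_t = 0.1\, g^1(x^1_{t-1}) + 0.9\, g^2(x^2_{t-1}),$$

at $T = 300$ steps by default, and each part is observed through 10
GP-drawn output functions plus isotropic noise ($10^{-4}$ variance).
System 1 is autonomous; system 2 is weakly driven by system 1.  The
generator stays first-order while the fitted model defaults to second
order, matching how the construction is used as a learning target.
Draw lengthscales default to 1 on latent coordinates of order-one scale;
the generator is a pure function of its specification and seed.
`variant > 0` redraws $g^2$ and system 2's initial state while keeping
system 1 bitwise identical, which is what the modular-recombination
experiments need.

What this emulates — and what it does not: the data are smooth,
low-dimensional, noiseless-by-comparison trajectories with a planted
one-way coupling.  Passing the recovery tests shows the inference
machinery identifies such structure; it does not certify performance on
real motion capture, where observation noise, non-stationarity and
marker artifacts are substantially harsher.

# Numerical choices

* Gram matrices receive a diagonal jitter of $10^{-6}$ times the signal
  variance before factorization (configurable); Cholesky failures
  escalate the jitter to $10^{-4}$ before giving up.
* The full-capacity exactness check uses jitter $10^{-10}$, since the
  identity with the exact marginal likelihood holds only in the
  jitter-free limit.
* Finite-difference gradient checks use a step of $10^{-3}$ on the
  packed (log-transformed) scale: the ELBO is order $10^3$–$10^4$, so
  smaller steps are dominated by cancellation noise.  The relative-error
  denominator carries a unit floor, because a gradient component smaller
  than about 1 on this scale sits at the finite-difference noise floor
  (absolute $\approx 10^{-5}$) and can only be compared absolutely.
* Zero-variance beliefs are valid inputs (point masses) everywhere
  except `entropy()`, which requires strictly positive variances.
* Degenerate data columns (zero variance) are dropped from the PCA
  initialization rather than failing.

# Problem sizes used by the tests

Unit tests run on $T \le 60$ synthetic sets with 4 dynamics / 5
kinematics IPs.  The end-to-end recovery checks train at $T = 150$ with
8 dynamics and 10 kinematics IPs over three seeds (majority vote), and
the capacity comparison uses 4 vs 10 dynamics IPs; the recombination
experiment trains two variants at $T = 100$ with two trials each.  These
sizes keep a full training run in the tens of seconds while leaving the
qualitative behaviour of the full-scale construction intact.

# Known limitations

* The factorized $q(x)$ ignores temporal posterior correlations; the
  bound is correspondingly loose and latent variances tend to be
  underestimated — the price of a fully collapsed, sampling-free bound.
* The PoE-marginalized kernel of the coupled model is implemented only
  as a cross-check oracle (`marginalized_kernel`); training always uses
  the explicit sparse couplings, which are what make recombination
  possible.
* Archives store IPs/IVs and hyperparameters; re-evaluating an ELBO
  after loading requires saving with `latents = TRUE` (size then grows
  with $T$) or re-inferring the latent posterior on data.
* `compose()` supports both sharing kinematics IPs across movements and
  per-dataset training; which is preferable is data-dependent and left
  to the user.
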