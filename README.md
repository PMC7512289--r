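# vcgpdm

Modular movement-primitive models: coupled Gaussian-process dynamical
systems learned with sparse, collapsed variational inference.

## What problem this solves

Full-body movements (walking, walking while waving, manipulating an
object) can be described as a few interacting *parts* — e.g. upper and
lower body — each with its own low-dimensional latent dynamics mapped
into joint-angle space.  Classical GP dynamical models capture one such
system but scale cubically with the recording length, store the whole
training set as their "parameters", and cannot be taken apart and
recombined.  `vcgpdm` implements a coupled, sparse, variational version
for researchers in computational motor control, animation and robotics
who want movement primitives that are

* **learnable** — free-form GP transition and kinematics functions,
* **scalable** — training cost linear in the sequence length,
* **compact** — a trained part is a handful of inducing points/values,
  independent of the data size,
* **modular** — parts and their couplings can be frozen, re-used and
  recombined, relearning only the coupling strengths.

## The model in brief

Part $j$'s latent state $x^j_t \in \mathbb{R}^{Q_j}$ follows
second-order autoregressive dynamics.  Every part $i$ predicts every
part $j$ through a GP-distributed coupling function with variance
$\alpha^{i,j}$, and the predictions are fused by a product of experts:

$$p(x^j_t \mid f^{:,j}, \alpha^{:,j}) =
\mathcal{N}\!\Big(\alpha_j \sum_i f^{i,j}(x^i_{t-2}, x^i_{t-1})/\alpha^{i,j},\;
\alpha_j I\Big), \qquad \alpha_j = \Big(\sum_i 1/\alpha^{i,j}\Big)^{-1}.$$

Observations arise through GP kinematics functions $g^i(x^i_t)$ plus
isotropic noise $\beta_i$.  All GPs are sparsified with inducing points;
inference maximizes a fully collapsed evidence lower bound (ELBO) over a
factorized Gaussian posterior on the latent trajectories, with analytic
gradients throughout.  Small $\alpha^{i,j}$ = strong influence of part
$i$ on part $j$; the alphas are learned, so the model discovers the
coupling structure.  See `vignettes/vcgpdm-methods.Rmd` for the bound
and its derivation.

## Worked example

Two coupled two-dimensional latent systems — system 1 autonomous,
system 2 weakly driven by system 1 (weights 0.9 / 0.1) — observed
through ten GP-drawn output channels per part:

```r
library(vcgpdm)

data <- make_synthetic_dataset(synthetic_spec(T = 150, seed = 1))
model <- vcgpdm(data$column_map, latent_dim = 2, n_dyn_ips = 8, n_kin_ips = 10)
cfg   <- training_config(max_joint_iters = 300, max_block_iters = 60,
                         max_cycles = 2, seed = 1)
fit   <- fit_vcgpdm(model, data, cfg)
fit$model
#> vCGPDM: 2 part(s), order 2
#>   part 1: D=10 Q=2 kin IPs=10 beta=0.000167
#>   part 2: D=10 Q=2 kin IPs=10 beta=0.000112
#>   coupling variances alpha[i,j] (rows = source):
#>          [,1]   [,2]
#> [1,] 2.08e-03 0.0297
#> [2,] 2.47e+06 0.0107

gen <- rollout(fit$model, 150)
dtw_mse(gen$observed, data$sequences[[1]])
#> [1] 0.4654485
```

The learned coupling matrix recovers the planted structure:
$\alpha^{2,1} \approx 2.5\times 10^6 \gg \alpha^{1,1} \approx 0.002$
(part 2 has essentially no influence on part 1), while
$\alpha^{1,2} \approx 2.8\,\alpha^{2,2}$ (part 1 weakly drives part 2).
The DTW-warped mean squared error of the generated versus training
trajectories drops from about 1.7 at PCA initialization to 0.47 after
training.

A command-line interface covers the same pipeline
(`exec/vcgpdm synth | train | generate | evaluate | compose`), reading
and writing delimited-text trajectory tables with a
`part:first-last` column map, e.g. `--parts 0:0-9,1:10-19`.

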