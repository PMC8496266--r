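---
title: "Methods: Bayesian neural networks with Bayesian Alphabet priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian neural networks with Bayesian Alphabet priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`nnbayes` fits a single-hidden-layer Bayesian neural network for a
quantitative trait measured on genotyped individuals. For individual $i$ with
dosage vector $x_i \in \{0,1,2\}^p$,

$$y_i = \mu^{(1)} + \sum_{j=1}^{l_1} w_j^{(1)} g(z_{ij}) + e_i,
\qquad e_i \sim N(0, \sigma_e^2),$$

where the $l_1$ hidden nodes $z_i$ are latent *intermediate traits* linked
linearly to the markers through a multi-trait whole-genome regression,

$$z_i = \mu^{(0)} + \sum_{m=1}^{p} x_{im} w_m^{(0)} + \epsilon_i,
\qquad \epsilon_i \sim N(0, \Sigma),$$

and $g(\cdot)$ is an elementwise activation, $\tanh$ by default. Setting
`n_hidden = 0` drops the hidden layer and fits the ordinary single-trait
Bayesian Alphabet linear model, which doubles as the comparison baseline.
Dosages enter raw (0/1/2), without centering or scaling.

Marker effects $w_m^{(0)}$ carry Bayesian Alphabet priors. Writing
$w_m^{(0)} = D_m \beta_m$ with $D_m$ a diagonal 0/1 inclusion matrix:

* **RR-BLUP** — all markers included, normal effects with a common variance;
* **BayesA** — per-marker variances with scaled-inverse-$\chi^2$ priors
  (a scaled-$t$ marginal);
* **BayesB** — point-mass mixture with per-marker variances;
* **BayesC$\pi$** — point-mass mixture with a common variance; in
  multi-trait mode the $2^{l_1}$ inclusion configurations of $D_m$ are
  sampled jointly and $\beta_m \sim N(0, G)$ with an inverse-Wishart prior
  on $G$;
* **BayesL** — double-exponential effects through the exponential
  scale-mixture representation, with a Gamma hyperprior on the LASSO rate.

Throughout the package $\pi$ is the prior probability that a marker effect
is **nonzero**; summaries print both $\pi$ and $1-\pi$ because the symbol is
used both ways in the literature.

Residual and node variances have scaled-inverse-$\chi^2$ priors
($\Sigma$ inverse-Wishart in multi-trait mode). Hidden-node means and
output-layer coefficients are unpenalised except for the weakly-informative
output prior discussed below.

## Inference

One Gibbs iteration updates, in this order:

1. **Layer 1 given $Z$** (these conditionals do not involve $y$): $\mu^{(0)}$,
   a full sweep over markers in ascending index order with incremental
   residual updates (so a chain is reproducible from its seed), the
   effect-variance hyperparameters, $\pi$ (Beta or Dirichlet update when
   sampled), and $\Sigma$.
2. **Hidden nodes by Hamiltonian Monte Carlo.** Each $z_i$ has log full
   conditional
   $-\tfrac12 (z-\mu)^\top \Sigma^{-1} (z-\mu) - (y_i - \mu^{(1)} -
   w^{(1)\top} g(z))^2 / 2\sigma_e^2$ with $\mu = \mu^{(0)} + W^{(0)\top}
   x_i$. A momentum refresh $\phi \sim N(0, M)$, $L$ leapfrog steps of size
   $\epsilon$, and a Metropolis accept/reject with ratio
   $r = \exp\{\log p(z^*) + \log p(\phi^*) - \log p(z) - \log p(\phi)\}$
   complete the update. Defaults $L = 10$, $\epsilon = 0.1$, $M = I$.
   Because the $z_i$ are conditionally independent, all individuals are
   updated in one batched matrix sweep (momentum matrix filled column-wise,
   then one uniform per individual); non-finite trajectories count as
   ordinary rejections. $\Sigma^{-1}$ is factorised once per outer
   iteration.
3. **Output layer**: $(\mu^{(1)}, w^{(1)})$ jointly from the Gaussian
   linear-model conditional on the design $[1, g(Z)]$, then $\sigma_e^2$
   from its scaled-inverse-$\chi^2$ conditional.

The marker sweeps (single-node families and the multi-trait configuration
sampler) are compiled C++; they use R's RNG, so a chain is bit-identical
given `(data, model, seed)`.

### Numerical and design choices

* **Output-layer prior.** With several hidden nodes the $\tanh$ outputs can
  become nearly collinear (all nodes track the trait), and under a strictly
  flat prior the conditional for $(\mu^{(1)}, w^{(1)})$ then wanders an
  ill-conditioned ridge: weights of magnitude $10^5$ and beyond that cancel
  in-sample but destroy out-of-sample prediction. The engine therefore uses
  a weakly-informative normal prior with variance $25\,\mathrm{var}(y)$ on
  the output coefficients — flat for all practical purposes over the
  identified region (it bounds $|w^{(1)}|$ near 5 standard-deviation units
  of a coefficient that maps a bounded $\tanh$ output onto $y$) — and
  `nnbayes_control(coef_prior_var = Inf)` restores the exact flat prior.
  `sample_output_coeffs()` itself defaults to the flat conditional.
* **Hidden-node mean prior.** A second soft ridge is the node location:
  a node can drift into saturation ($\mu^{(0)}_j$ of several units, with
  $\mu^{(1)}, w^{(1)}$ compensating) at almost no likelihood cost.
  Prediction is invariant to this, but the window statistic is not — window
  genotypic values exclude $\mu^{(0)}$ by definition, so a saturated node's
  loosely-constrained marker effects leak spurious variance into every
  window and can flag the whole genome. The hidden-node means therefore get
  a normal prior with variance 1 on the standardized latent scale — wide
  within the activation's dynamic range, negligible mass in the saturated
  region where the location is unidentified (`mu_prior_var`; `Inf` restores
  the flat prior, and the linear model's intercept stays flat).
* **Hidden-node initialisation.** Nodes start at the standardized phenotype
  plus $N(0, 1)$ noise. Anchoring at $y$ gives the output layer signal from
  iteration one; the unit-variance noise decorrelates the nodes, which
  otherwise start on the collinearity ridge above. `z_init_sd` controls the
  noise.
* **Hyperparameter defaults** (all overridable in `bayes_prior()`):
  $\nu_e = 4$ with the residual scale set so the prior mean is half the
  phenotypic variance; marker-effect scales assume an a-priori 50/50
  genetic/residual split of the (hidden-node) variance spread over the
  expected number of included markers; inverse-Wishart dfs $l_1 + 4$.
* **Mixture families** sample the indicator with the effect integrated out,
  then the effect; excluded markers carry effect zero and BayesC$\pi$'s
  common variance is updated from included effects only. Multi-trait mode
  instead instantiates the full $\beta_m$ vector (its exact multivariate
  normal conditional) so $G$ can be updated with all $p$ rows.
* **Degenerate inputs**: monomorphic markers are dropped at load (their
  effects are unidentifiable and break variance updates); a rank-deficient
  output design falls back to a logged $10^{-8}$ ridge jitter;
  non-positive-definite covariance draws are retried with jitter.
* **Multi-trait cap**: the configuration sampler enumerates $2^{l_1}$
  patterns, so multi-trait mode is limited to 10 nodes and the automatic
  mode switches to independent nodes above 5 — the model's own fallback for
  many hidden nodes, where each node gets a single-trait sampler.

## Prediction and GWAS

Genotypic values per saved posterior record are
$\hat g = g(1\mu^{(0)\top} + X w^{(0)}) w^{(1)}$ — the output intercept is
excluded, which leaves Pearson prediction accuracy against validation
phenotypes unchanged. The per-marker PIP is the posterior frequency that a
marker's effect is nonzero on at least one node (families without
indicators report PIP 1 with a caveat).

For window-based association, markers are partitioned into non-overlapping
half-open physical windows (1 Mb by default). Per record, the genotypic
values attributed to window $t$ are $\hat g_t = g(X_t w_t^{(0)}) w^{(1)}$ —
window markers only, no $\mu^{(0)}$ — and
$q_t = \mathrm{var}(\hat g_t)/\mathrm{var}(\hat g)$ over the reference
individuals (the training set by default, so validation data never touch
the GWAS; sample variances use $n-1$). WPPA$_t$ is the fraction of records
with $q_t > T$ (default $T = 0.01$, "explains more than 1% of the genetic
variance"), and windows with WPPA $> 0.95$ are flagged significant.
$q_t$ is computed per record, not from posterior-mean effects, and is not
clamped: under a nonlinear activation the window contributions need not sum
to $\hat g$, and $q_t$ can exceed 1. The omission of $\mu^{(0)}$ inside
$g(\cdot)$ for windows is deliberate fidelity to the estimator's
definition; a leave-one-window-out contrast would be a different statistic
and is out of scope.

## The trait simulator

`sim_genotypes()` draws dosages as Binomial(2, $f_m$) with
$f_m \sim U(0.05, 0.5)$ and induces local LD through a first-order
haplotype-copying chain (`ld_rho = 0.6`, roughly the adjacent-marker
correlation; 50 kb spacing so a 1-Mb window holds about 20 markers —
comparable to a medium-density livestock array). It does **not** emulate
coalescent LD block structure, realistic frequency spectra, or multiple
chromosomes; conclusions drawn from it about real data are correspondingly
limited (see below).

`sim_trait()` selects 5% of markers as QTL and builds, per QTL $q$,
additive effects $a_q \sim N(0,1)$; dominance factors
$\delta_q \sim N(1.2, 0.3^2)$ giving dominance effects
$d_q = \delta_q |a_q|$ expressed at heterozygotes; and per unordered QTL
pair an epistatic factor $\gamma \sim N(0,1)$ giving effect
$\gamma |a_i a_j|$ expressed under **complementary** gene action — only
when both loci carry at least one alternative allele
($u_q = 1[x_q \ge 1]$, the classical 9:7 model). The functional form of the
genotype gating is the package's own choice (the effect magnitudes are
fixed, the combination rule is plugged through the indicator coding above);
dominance factors are not truncated, so a rare negative $\delta$ is
possible. Genetic components are rescaled and the Gaussian residual is
orthogonalised against the genetic values in sample, so every simulated
data set has phenotypic variance exactly 1 and realized broad-sense $H^2$
exactly equal to the target (0.5 by default) — not merely in expectation.
For window-level truth, a window's genetic contribution sums the additive
and dominance terms of its QTL plus half of each epistatic term involving
one of its QTL; a window is causal when its contribution's variance share
exceeds $T$.

`sim_nn_trait()` instead simulates from the network's own generative
process (sparse effects in a few causal windows, Gaussian node residuals,
tanh output layer), which is the right ground truth for calibration
studies of the WPPA rule under a correctly specified model.

## What the checks do and do not show

The test suite validates each full-conditional against an independent
oracle (closed-form ridge solutions, numerical integration over the
marker-effect prior, conjugate moment identities, finite differences,
leapfrog reversibility), checks the composite kernel by a
successive-conditional prior-reproduction (Geweke) run at toy scale
($p=5$, $n=8$, $l_1=2$, with proper output/mean priors of variance 1 since
the flat-prior joint is improper), and verifies the WPPA false-positive
control: 10 replicates simulated from the generative network model
($n=400$, $p=600$, $l_1=2$, 30 windows, 3 causal), fit with
NN-BayesC$\pi$-2 for 4,000 iterations (1,500 burn-in), must yield at most
5% false positives among windows flagged at WPPA $> 0.95$. Because the
calibration data come from the model's own generative process, the fits fix
$\pi$ at the generative causal fraction (15 of 600 markers per node,
$\pi = 0.025$) — the correctly-specified known-$\pi$ protocol; with
$\pi$ sampled instead, chains of this length occasionally linger in a
dense-inclusion mode whose spread-out genetic variance puts every 1-Mb
window above $T$. The residual false positives under the 4,000-iteration
protocol are themselves finite-chain artifacts — single null markers whose
effects co-adapt with the latent nodes — and dissolve when the same
replicate is run four times longer; the pooled false-positive proportion at
the short protocol sits at the nominal bound (0.03–0.07 across seeds)
rather than safely under it.

The prediction comparison against the linear baseline runs 12 replicates at
$n=600$, $p=400$ with 2,000-iteration chains — problem sizes chosen as the
package's own desk-scale study — on the dominance + epistasis trait
($H^2 = 0.5$). Two caveats apply. First, although the simulated trait is
strongly non-additive (the best additive fit at the true QTL leaves roughly
a third of the genetic variance unexplained), at these sample sizes no
nonlinear method we tried — including a classical weight-decay neural net —
outperforms a sparse linear whole-genome regression on these synthetic
genotypes, so a strict-majority win for the network is a property of larger
samples and richer LD than this simulator provides. Second, the network's
advantage reported on real data rests on genotype structure (long-range LD,
realistic frequency spectra) that the copying-chain simulator deliberately
does not reproduce. A parity result here therefore bounds the simulator,
not the method.

## Known limitations

* Multi-trait BayesB (multivariate-$t$) is not implemented; BayesA/B/L run
  per node in independent mode.
* No BayesR, no extra fixed/random input nodes, no multiple chains or
  convergence diagnostics beyond a per-scalar effective sample size.
* PIP is reported but, as a marker-level statistic under strong LD, behaves
  close to a random classifier; window statistics are the intended
  inference tool.
* Chains are stored densely in memory; at `p` in the tens of thousands with
  long chains, increase `thin`.
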