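---
title: "Latent-variable community models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable community models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentord)
```

## The model

Community data arrive as an $n \times m$ matrix of records $y_{ij}$ —
counts, presence–absence, or percent cover — for species $j$ at site $i$,
usually with covariates $x_i$, sometimes with traits $t_j$, a phylogeny, and
a structured sampling design. A generalized linear latent variable model
(GLLVM) regresses the conditional mean through a link $g$:

$$g(\mu_{ij}) = \eta_{ij} = \alpha_i + \beta_{0j} + x_i^\top \beta_j +
u_i^\top \gamma_j,$$

where the $d \ll m$ latent variables $u_i$ (site scores) and loadings
$\gamma_j$ induce low-rank residual correlation between species — this is
simultaneously a joint species distribution model and a model-based
ordination. The package supports three latent-variable regimes, which can
be mixed:

* **unconstrained** (`num_lv`): $u_i \sim N(0, I)$, optionally correlated
  across time points via an AR1 prior per dimension (`lv_cor`), and
  optionally entering quadratically,
  $\eta_{ij} = \ldots + u_i^\top\gamma_j - u_i^\top D_j u_i$ with
  $D_j \succeq 0$ diagonal, giving unimodal species responses;
* **constrained** (`num_RR`): $u_i = B^\top x_i$ — reduced-rank regression;
* **informed/concurrent** (`num_lv_c`): $u_i = B^\top x_i + \epsilon_i$,
  $\epsilon_i \sim N(0, \mathrm{diag}(\sigma^2))$, so measured and
  unmeasured drivers share the same loadings.

Row effects $\alpha_i$ are declared by formula: fixed terms, random
intercepts `(1|G)`, nesting `(1|SITE/TRANSECT)` (expanded to SITE plus
SITE:TRANSECT blocks), and correlation wrappers `corAR1`, `corCS`,
`corExp`, `corMatern` around a random intercept. Species covariate effects
can follow the fourth-corner decomposition
$\beta_j = \beta_e + B_{et} t_j + b_j$ with random slopes
$b_j$; per covariate $l$ the slopes across species may be phylogenetically
structured, $(b_{1l}, \ldots, b_{ml})^\top \sim
N(0, \sigma_l^2[C\rho_l + (1-\rho_l)I])$, where $C$ is the Brownian-motion
correlation from the tree and $\rho_l \in [0,1]$ is the signal.

## Estimation: VA and EVA

The marginal likelihood integrates over all latent blocks; the package
maximizes a Gaussian variational lower bound (ELBO) instead. Writing
$\tilde\eta_{ij}$ and $v_{ij}$ for the mean and variance of $\eta_{ij}$
under the variational distribution,

$$\mathrm{ELBO} = \sum_{ij \in \mathrm{observed}}
E_q[\log f(y_{ij}\mid\eta_{ij})] - \sum_{\text{blocks}} KL(q \,\|\, p).$$

The per-cell expectation has a closed form for gaussian/identity
(exact — the expansion is exact for a quadratic log-density), poisson/log
($y\tilde\eta - e^{\tilde\eta + v/2} - \log y!$), and bernoulli/probit.
For the probit case we use the latent-normal augmentation
$y = 1\{z > 0\}$, $z \sim N(\eta, 1)$, with the variational factor for $z$
fixed at the truncated-normal conditional evaluated at $\tilde\eta$; the
resulting bound is $\log\Phi((2y-1)\tilde\eta) - v/2$, a genuine ELBO of
the augmented model that is exact at $v = 0$.

Every other family/link uses the **extended variational approximation**
(EVA): a second-order expansion of the expected log-density around
$\tilde\eta$,

$$E_q[\log f(y\mid\eta)] \approx \log f(y\mid\tilde\eta) +
\tfrac{1}{2} v\, \partial^2_\eta \log f(y\mid\tilde\eta),$$

whose curvature is implemented analytically per family
(`eva_curvature()`), differentiating the branch containing the observed
value for the mixed discrete–continuous families. EVA yields a closed-form
objective for any response type; unlike the plain VA it is not guaranteed
to be a lower bound, but the gap $|EVA - VA|$ vanishes as $v \to 0$ (the
test suite checks both properties against an adaptive Gauss–Hermite
quadrature oracle on tiny instances).

### Variational family

Gaussian with block structure: per-site means and unstructured
lower-triangular covariance factors for unconstrained and informed latent
variables; one triangular factor of size $T$ per latent dimension for
AR1-structured latent variables over $T$ time levels; per-level means with
diagonal factors for iid random row effects and full triangular factors
for correlated blocks; diagonal factors for species random slopes and for
random canonical coefficients. The diagonal choice for the slope and
canonical-coefficient blocks trades some tightness of the bound for
scalability and was preferred over a sparse triangular factor mirroring
the nearest-neighbour precision; the KL term against the phylogenetic
prior still uses the sparse precision, so the cost stays
$O(m \cdot nn^3)$ per evaluation.

### Optimization

All parameters are packed into one vector with smooth reparameterizations:
variances and dispersions on the log scale, probabilities on the logit
scale, AR1 coefficients through $\tanh$, quadratic coefficients on the log
scale, ordered-beta cutoffs as $\zeta_{1j} = \zeta_2 - e^{\delta_j}$ to
enforce ordering. The objective is maximized by L-BFGS-B (memory 25; BFGS
selectable) with analytic gradients: the family supplies
$\partial E/\partial\tilde\eta$ and $\partial E/\partial v$ per cell, and
every upstream block (coefficients, loadings, canonical coefficients,
variational means and factors) follows by chain rule. Two classes of
parameters use exact central differences instead: scalar structural
parameters that enter only the cheap KL terms (variances, correlation and
signal parameters), and auxiliary family parameters ($\phi_j$, $\pi_j$,
$\zeta$), for which one vectorized two-sided difference per block suffices
because each cell depends only on its own species' auxiliaries. Quadratic
models fall back to a full finite-difference gradient and are intended for
modest dimensions.

Convergence: relative objective change below `reltol` ($10^{-8}$ by
default) and gradient max-norm below `grad_tol` ($10^{-3}$); the final
optimization restarts L-BFGS-B up to seven times while the gradient norm
still exceeds tolerance and the objective improves. With `n_init > 1`,
short jittered runs (standard normal $\times$ 0.1 on latent-related
coordinates only, seed offset by restart index) are compared by objective
and gradient magnitude before the long run; restarts execute serially, so
results are reproducible bit-for-bit given the seed.

Starting values: mode `"zero"` sets latent quantities to zero and
intercepts to link-transformed species means; mode `"res"` (default) fits
independent per-species GLMs, seeds loadings and scores from a truncated
SVD of the Pearson residual matrix, and for fourth-corner models seeds
$\beta_e$, $B_{et}$, and the slope predictions by regressing the
per-species GLM slopes on traits. Missing cells never enter the expected
log-likelihood (missing-at-random), and the observed-cell count $N$ is
used as the effective sample size below.

## Identifiability and parameter counting

For unconstrained latent variables the upper triangle of the loading
matrix is fixed to zero ($d_0(d_0-1)/2$ constraints) with the diagonal
sign resolved at reporting time. For constrained and concurrent
ordination the constraints total $d(d-1)$ across $(B, \Gamma)$, allocated
as: the leading $d \times d$ block of $B$ is unit-lower-triangular
($d(d+1)/2$ constraints), the loadings' upper triangle is zero
($d(d-1)/2$), and the $d$ residual variances of informed latent variables
are free. Hence a concurrent ordination with all $k$ covariates reduced
to $d$ informed dimensions, $m$ species, and $s$ auxiliary parameter
vectors (0 Poisson, 1 negative binomial or ZIP, 2 ZINB) has

$$df = m(1+s) + kd + dm - d(d-1)$$

freely estimated parameters — the rule `count_free_parameters()`
implements and the test suite pins cell-by-cell (e.g. 236 for a Poisson
model with $m = 68$, $k = 17$, $d = 2$, against $m(k+1) = 1224$ for the
full-rank GLM). The constraint allocation between $B$ and $\Gamma$ is not
uniquely determined by the total; the allocation above is this package's
convention and is verified through the df accounting rather than assumed
elsewhere. With `randomB`, $B$ is random and the fixed-coefficient count
is replaced by its variance parameters (one per latent dimension for
`"LV"`, plus one per covariate for `"P"`, a single one for `"single"`).

Information criteria use the maximized lower bound $\hat\ell$ in place of
the log-likelihood: $AIC = -2\hat\ell + 2\,df$,
$BIC = -2\hat\ell + df\log N$, $AICc = AIC + 2df(df+1)/(N-df-1)$ with $N$
the number of observed cells. Wald standard errors come from inverting the
finite-difference Hessian of the joint objective at the optimum and
extracting the fixed-parameter block; p-values are reported raw, with no
multiplicity adjustment. Residuals are randomized quantile (Dunn–Smyth)
residuals, standard normal under a correctly specified model even for
discrete families. Variance partitioning computes, per species, the
empirical variance across sites of each component's contribution to
$\eta$ (estimates for fixed terms, predictions for random terms),
normalized to proportions. Environment-driven species correlations are
defined as the correlation across species of the fitted random
environmental part of $\eta$ evaluated over the empirical covariate
distribution — a definition chosen here because the weighting over
covariates is otherwise underdetermined.

## Families

Auxiliary parameterizations: the negative binomial uses
$\mathrm{Var} = \mu + \phi_j\mu^2$, so $\phi_j \to 0$ recovers the Poisson
(pinned by a limit test); zero-inflated counts use the mixture
$P(0) = \pi_j + (1-\pi_j)p(0)$, $P(c) = (1-\pi_j)p(c)$; the beta families
use mean–precision with a logit link. Dispersion parameters may be shared
across species groups (`disp_groups`), e.g. one $\phi$ for all
invertebrates. The ordered beta has point masses
$P(y{=}0) = 1 - \mathrm{logistic}(\eta - \zeta_1)$,
$P(y{=}1) = \mathrm{logistic}(\eta - \zeta_2)$ and a beta density scaled
by the remaining mass on $(0,1)$, all sharing one predictor; the density
is normalized by construction (verified by numerical integration), with
`zeta_struc = "species"` giving species-specific lower cutoffs and one
common upper cutoff. The hurdle beta is the two-part variant on
$[0, 1)$ — the hurdle is the sole source of zeros, exact ones are out of
scope — and is fitted internally by doubling the species dimension
(presence columns, then positive-cover columns) so that the two parts
share latent scores but keep separate coefficients and loadings.

## Correlation structures

AR1 over integer-indexed ordered levels gives
$\Sigma_{ts} = \rho^{|t-s|}$ (unequal spacing maps to $\rho^{\Delta t}$);
compound symmetry requires $\rho \in (-1/(T-1), 1)$; `corExp` is
$\exp(-d/\mathrm{range})$; Matérn uses smoothness 1.5 by default — the
structure is standard but its smoothness is a free choice here, and it is
configurable. Trees are reduced to the Brownian correlation (shared branch
length, unit diagonal) and cophenetic distances; taxonomic tables become
trees with one unit of branch length per rank, a convention that makes
correlations proportional to the number of shared ranks. The
nearest-neighbour approximation is a Vecchia factorization: under a given
species ordering (default: distance from the root) each species conditions
on at most `nn` predecessors, chosen as nearest by cophenetic distance;
`nn = m - 1` reproduces the exact precision, and the KL error to the exact
Gaussian decreases (on average) in `nn`.

## The simulator

`generate_dataset()` draws covariates as independent standard normals (a
correlation knob exercises the multicollinearity rationale for
`randomB`), then latent variables, row effects, and slopes from their
declared structures, and responses through the same generative code used
by `log_density()`. Two named scenarios bracket the data types the package
targets: a beetle-like scenario (87 sites, 68 species, 17 covariates,
zero-inflated negative binomial counts) and a kelp-like scenario (44
transects nested in 11 sites over 21 years, ordered-beta percent cover
with AR1 latent variables at $\rho = 0.9$, and the lower cutoff tuned by
bisection against the Monte-Carlo zero rate to a zero fraction of 0.88,
with 30 species by default so that fitting stays tractable). Recovery
checks in the test suite use Poisson data at $n = 200$, $m = 30$, $d = 2$
(linear-predictor correlation above 0.9 in every replicate) and a
fourth-corner design at $n = 300$, $m = 40$, $q = 2$ traits, interaction
scale 0.5, with $k = 2$ covariates and coefficient/slope scales 0.3 —
moderate effect scales chosen so that simulated counts stay in a
realistic range.

What the simulator does not emulate: covariate measurement error, spatial
autocorrelation of covariates, species interactions beyond low-rank
covariance, gradients in sampling effort, or taxonomic misassignment.
Passing recovery tests therefore demonstrates internal consistency of
model, fitting, and inference under the model's own assumptions — not
robustness to the many ways field data violate them.

## Known limitations

* EVA is not a guaranteed lower bound; model comparison across estimation
  methods should hold the method fixed.
* Quadratic models use a delta-method variance for $\eta$ and a numeric
  gradient, so they are practical only at small dimensions here.
* `lv_cor` currently supports `corAR1` only; richer structures apply to
  row effects.
* The species random-slope covariance across covariates is diagonal
  (no between-covariate correlation), matching the per-covariate
  phylogenetic prior.
* Laplace approximation, MCMC, ordinal and Tweedie families, binomial
  with multiple trials, and mixed response types across columns are out
  of scope.
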