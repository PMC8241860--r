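---
title: "Bayesian melting-curve models for thermal proteome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian melting-curve models for thermal proteome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(tppbayes)
```

# The problem

Thermal proteome profiling (TPP) heats aliquots of a cell lysate or intact
cells at a ladder of temperatures, removes aggregated protein, and quantifies
what remains soluble by multiplexed mass spectrometry. After normalization to
the lowest temperature, each protein contributes a *melting curve*: relative
solubility as a function of temperature, measured for a control and a treated
condition with a small number of replicates (typically 2 x 2 x 10
measurements per protein). A compound that binds a protein usually shifts or
reshapes its melting curve, so comparing curves between conditions screens
thousands of proteins for drug targets and downstream effects at once.

`tppbayes` models these curves four ways - a frequentist sigmoid F-test
baseline (NPARC), a Bayesian sigmoid model, and a Bayesian semi-parametric
model in which a Gaussian process (GP) absorbs reproducible departures from
sigmoid shape - and decides per protein whether the treatment changed the
curve.

# Models

## The sigmoid mean function

Thermodynamic theory predicts a sigmoidal decay of solubility with
temperature. We use the 3-parameter form standard in TPP analysis,

$$S_{a,b,p}(T) = \frac{1-p}{1 + \exp(b - a/T)} + p,$$

where $p \in (0,1)$ is the lower plateau and $a, b > 0$ are shape
parameters; the curve crosses $(1+p)/2$ at $T = a/b$ (the melting midpoint)
and is strictly decreasing for $a > 0$. Temperatures are handled in degrees
Celsius throughout, matching the reference NPARC parameterization; no Kelvin
conversion is applied.

## Hypotheses

For each protein, the shared-curve model `M0` fits one parameter set to both
conditions' stacked replicates; the condition-specific model `M1` gives each
condition its own parameters (including its own residual standard deviation).
Under `M1` the two conditions share no parameters, so the joint posterior
factorizes and each condition is fitted as an independent block; marginal
likelihoods then add across blocks.

## NPARC baseline

Least-squares fits of the two hypotheses give residual sums of squares
RSS$_0$ and RSS$_1$ and the statistic
$F = (d_2/d_1)\,(\mathrm{RSS}_0-\mathrm{RSS}_1)/\mathrm{RSS}_1$. TPP
residuals are correlated across temperatures (see
`residual_correlation_matrix()`), so the counting degrees of freedom misstate
the null. We therefore fit effective degrees of freedom
$(\tilde d_1, \tilde d_2)$ to the observed F statistics by maximum likelihood
of the central-F density, optionally truncating at an upper empirical
quantile (default: the 95th) with the proper truncated-likelihood
normalization, since treatment-affected proteins inflate the tail. This is an
approximation to the original NPARC estimation scheme, whose exact formulae
live in its own reference implementation. Two caveats are documented rather
than hidden: the denominator dof is weakly identified (the fit constrains the
implied p-values well but $\tilde d_2$ itself has wide sampling variability),
and when an atypically large fraction of proteins is treatment-affected the
null fit is contaminated and NPARC loses power - precisely the assumption
("most proteins are null") that the Bayesian route avoids.

## Bayesian sigmoid model

Observations are modelled as
$y_{jk} \sim \mathcal{N}(S_{a,b,p}(T_j), \sigma^2)$, i.i.d. across
temperatures and replicates, with priors

| parameter | prior | default | role |
|---|---|---|---|
| $a$ | Gamma(shape, rate) | $\mathcal{G}(7, 0.01)$ (mean 700) | shape; midpoint $a/b$ |
| $b$ | Gamma(shape, rate) | $\mathcal{G}(7, 0.4)$ (mean 17.5) | shape; slope scale |
| $p$ | Beta | $\mathcal{B}(1, 20)$ | plateau, usually near 0 |
| $\sigma$ | folded normal, scale | $\mathcal{FN}(0, 0.05)$ | residual sd, shrunk to 0 |

The Gamma second parameter is a **rate** (so the prior mean of $a$ is 700,
consistent with fitted values around 400-900 on real data), and the folded
distributions' second/third parameter is a **scale** (standard-deviation
like). The source publication writes only the symbols; both conventions are
therefore stated prominently here and are configurable through
`prior_defaults()`.

## Semi-parametric model

Some proteins reproducibly deviate from sigmoid shape - hypersolubilisation
(solubility rising with temperature) and biphasic curves with multiple
inflexions. The semi-parametric model adds a deviation function with a
centred GP prior,

$$y_{k}(T_j) = S_{a,b,p}(T_j) + \mu(T_j) + \epsilon_{jk}, \qquad
\mu \sim \mathcal{GP}\!\left(0,\; v^2 \exp\!\big(-\tfrac{(T-T')^2}{2\ell^2}\big)\right),$$

with one $\mu$ realization per condition shared by its replicates.
Marginalizing $\mu$ gives a correlated Gaussian likelihood
$y \sim \mathcal{N}(S, C + \sigma^2 I)$ over the concatenated replicate
vector, where replicate copies at equal temperatures share the full
covariance $v^2$. The GP hyperpriors are $v \sim \mathcal{FT}(3, 0, 0.5)$
(folded Student-t: strong shrinkage to 0 with heavy tails, so the
non-parametric term only acts when the data support it) and
$\ell \sim \mathcal{LN}(-0.5, 0.5)$ (log-normal, °C units: the sharp left
tail blocks data-interpolating short length-scales, the moderate right tail
discourages uninformative long ones). The model is weakly non-identified -
the GP can partially explain the sigmoid - which these priors deliberately
resolve in favour of the parametric term.

Because replicate copies make the covariance a Kronecker-plus-diagonal
matrix, the likelihood and its gradient are computed exactly on the
$D$-dimensional replicate-mean block instead of the full $n_iD$ system; a
Hilbert-space reduced-rank approximation (`reduced_rank_loglik()`, default
32 basis functions on a domain expanded by a factor 2) is provided as an
optional backend but is unnecessary at per-protein sizes, where the dense
computation is exact and cheap.

# Inference

## Sampler

Posteriors are explored by adaptive Hamiltonian Monte Carlo written for this
package: positive parameters are log-transformed and the plateau
logit-transformed (with Jacobian terms included, so the sampled density is
the posterior on the unconstrained scale); warmup adapts a dual-averaging
step size towards a target acceptance of 0.9 and a dense metric estimated in
two expanding windows; trajectory lengths are jittered over the upper half
of `1..max_L` (default 32) to decorrelate draws; transitions with energy
error above 1000 count as divergences. Defaults are 4 chains of 1000 warmup
and 1000 retained draws. All randomness flows through R's RNG, so results
are reproducible from a single seed; pipeline runs derive per-protein seeds
from the master seed and the protein id, making results independent of
protein order.

Chains are initialized at the least-squares sigmoid fit (jittered), falling
back to prior draws filtered to a finite log posterior. Diffuse prior starts
occasionally trap a chain in a minor secondary mode created by the
sigmoid/GP non-identifiability; anchoring at the dominant mode removes this
failure without changing the target distribution.

Convergence is summarized by rank-normalized split-$\hat R$ and bulk
effective sample size - rank normalization is the modern robust form of
these diagnostics and matters here because the plateau's logit scale has an
exponential tail that inflates the classical $\hat R$ without affecting any
reported quantity. A fit is flagged unreliable when any $\hat R > 1.01$ or
divergences exceed 0.1% of draws; flagged fits are refitted once (at target
acceptance 0.99 after divergences, at doubled length after pure mixing
flags) and the flag is carried into the results table, where flagged
proteins are reported separately but never dropped.

## Evidence and hit calling

The marginal likelihood of each model is estimated by the Laplace-Metropolis
identity: $\log p(y|\mathcal M) \approx \tfrac{P}{2}\log 2\pi + \tfrac12
\log|\hat H| + \log p(y, \hat\theta)$, with $\hat H$ the sample covariance
of the unconstrained draws (ridge-guarded at $10^{-10}$) and $\hat\theta$
the draw maximizing the recorded log posterior. Evaluating on the
unconstrained scale with Jacobian-corrected priors keeps the estimate
invariant to the parameterization choice. The posterior probability of a
treatment effect combines the two evidences with prior model probabilities
$p(\mathcal M_0) = 0.99$, $p(\mathcal M_1) = 0.01$, which control
multiplicity across the proteome without any empirical null estimation; a
protein is a hit when this probability strictly exceeds 0.99.

## Model checking

Posterior predictive checks simulate replicate datasets from the fitted
observation model and report 50%/95% pointwise bands plus the fraction of
observed points inside them. PSIS-LOO estimates out-of-sample log predictive
density: importance ratios are smoothed per observation by a
generalized-Pareto fit to the largest $\min(0.2S, 3\sqrt S)$ ratios
(Zhang-Stephens profile estimator with the standard weak prior towards
$k=0.5$), with $\hat k > 0.7$ flagged. For the semi-parametric family the
pointwise term is the exact leave-one-out conditional density
$p(y_i \mid y_{-i}, \theta)$ of the multivariate normal, computed from the
precision matrix - the correct pointwise quantity when observations are
correlated.

Non-sigmoid behaviour is flagged when the semi-parametric model explains at
least 5 percentage points more variance than the sigmoid model:
$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ computed from the posterior-median
condition-specific (`M1`) curves, pooled over conditions and replicates with
TSS around each condition's own mean. The `M1`/pooled convention is a
documented choice: the flag concerns curve shape, not the treatment effect,
and the condition-specific curves are the ones a user inspects.

# Synthetic data

`simulate_dataset()` generates ground-truthed datasets that mirror the
standard design: 10 temperatures evenly spanning 37-67 °C (real TMT10
ladders span this range; the published description of the grid is
arithmetically self-inconsistent, so an even 10-point span is used), two
conditions with two replicates, solubility near 1 at 37 °C. Truths draw
$b \sim U(8, 20)$ and the melting midpoint $T_m \sim U(44, 58)$ °C with
$a = b\,T_m$ - drawing the midpoint directly (rather than $a$ and $b$
independently) is what actually keeps simulated midpoints in the
biologically sensible 44-58 °C window; plateaus are $U(0, 0.2)$ and noise is
0.03 or 0.08 depending on the protein. Scenarios:

* `null_sigmoid` - identical sigmoids in both conditions;
* `shifted_sigmoid` - the treatment midpoint moves by $U(2, 5)$ °C (random
  sign), implemented as $a \mapsto a + b\,\Delta$ with $b$ fixed;
* `gp_deviation` - a smooth GP deviation ($v = 0.1$, $\ell = 5$ °C) drawn
  once and shared by both conditions and all replicates;
* `biphasic` / `biphasic_shifted` - a deterministic Gaussian bump (amplitude
  $U(0.3, 0.6)$ solubility units, centre $U(48, 56)$ °C, width 5 °C) shared
  by both conditions, without/with an additional midpoint shift;
* `hypersolubilised` - a rising ramp of amplitude $U(0.3, 0.6)$.

The bump/ramp amplitudes are sized to match the reproducible non-sigmoid
excursions seen in real melting curves (several tenths of a solubility
unit) and deliberately place the biphasic class above the 5%
variance-explained threshold, so the flag's behaviour on truths is sharp:
smaller bumps are largely absorbed by the sigmoid's own flexibility and by
the dominance of the melting transition in the total variance, and would
define a class the flag is not meant to capture. What the generator does
*not* emulate: TMT reporter-ion and peptide-level noise, co-isolation
artefacts, temperature-dependent heteroscedasticity, and missingness
mechanisms. Passing tests on these simulations therefore demonstrates the
statistical machinery under the stated observation models, not robustness
to every artefact of real mass-spectrometry data.

# Numerical choices

* Covariance factorizations add a jitter of $10^{-10} v^2$ to the diagonal
  only when Cholesky fails, escalating tenfold at most three times; states
  where the covariance is numerically singular (condition number beyond
  $\sim 10^{14}$, reachable only in far prior tails) evaluate to $-\infty$
  and are rejected as divergences.
* Least-squares fits use multi-start Levenberg-Marquardt (9-point grid over
  $a \in \{200, 550, 1200\}$, $b \in \{5, 10, 20\}$, $p = 0.05$, box
  constraints $p \in [0, 1]$); the `M0` solution seeds the `M1` starts so
  nesting RSS$_1 \le$ RSS$_0$ holds up to optimizer tolerance.
* The effective-dof optimizer is bounded ($\tilde d_1 \in [0.5, 100]$,
  $\tilde d_2 \in [2, 1000]$) to keep the fitted null proper.
* Evidence requires at least 200 draws; the covariance ridge is $10^{-10}$.
* Out-of-support prior evaluations return $-\infty$ rather than raising.

# Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so the full suite completes in minutes on one core: per-protein fits
use 2 chains of 400 warmup / 400 retained draws (800 draws per block; the
conjugate-evidence check uses 4000), the multiplicity study uses 200 null
proteins, the sensitivity benchmark 150 proteins (100 null, 30 shifted, 20
biphasic-shifted), and calibration studies 50 proteins. These sizes are the
package's own choices for its reference experiments; the defaults users get
(4 chains, 1000/1000) are larger.

# Known limitations

* The Laplace-Metropolis estimator assumes an approximately Gaussian
  posterior; for multimodal or strongly skewed per-protein posteriors the
  evidence is approximate (the diagnostics flag the clearest failures).
* The effective-dof fit inherits NPARC's assumption that most proteins are
  null; heavily perturbed datasets contaminate it.
* Proteins with missing cells are excluded from model fitting for the
  comparison (and logged), not imputed - the handling of partially missing
  melting curves in the original analyses is unstated.
* Under `M0` a single residual sd is shared across conditions; under `M1`
  each condition has its own, following the observation model as written.
* The semi-parametric `M0` shares one GP realization across conditions, the
  `M1` one per condition, matching the hypotheses' exchangeability logic.
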