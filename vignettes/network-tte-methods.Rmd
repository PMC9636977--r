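---
title: "Methods: total treatment effect estimation under unknown network interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: total treatment effect estimation under unknown network interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netTTE)
```

## The problem

A randomized experiment on a finite population of $n$ units aims to estimate
the total treatment effect
$$\mathrm{TTE} = \frac{1}{n}\sum_{i}\big(Y_i(\mathbf{1}) - Y_i(\mathbf{0})\big),$$
the average change in outcomes if everyone were treated versus no one. When
units interfere — one unit's treatment shifts another's outcome through a
social, contact or communication network — the classical
difference-in-means analysis is biased, and the network that mediates the
interference is typically unobserved and expensive to measure. This package
implements a design-based framework in which the TTE can nonetheless be
estimated without any knowledge of the network, provided baseline outcome
levels can be estimated beforehand.

## Outcome model and assumptions

The heterogeneous additive network effects (HANE) model asserts
$$Y_i(z) = \alpha_i + \beta_i z_i + \sum_{(k,i) \in E} \gamma_{ki} z_k,$$
with a baseline $\alpha_i$, a direct effect $\beta_i$, and an edge-specific
interference effect $\gamma_{ki}$ for each directed edge. The assumptions
this encodes:

* **Additivity.** Treating a set of units shifts outcomes by the sum of the
  individual shifts; there are no interactions between treatments. Models
  where effects saturate, kick in only past a threshold, or act on a binary
  outcome violate this, and the package deliberately does not represent them.
* **Heterogeneity.** Every edge has its own coefficient; nothing is pooled.
  With $2n + |E|$ parameters and one observed outcome vector, the model is
  unidentifiable from data — which is exactly why the analysis is
  design-based (all randomness comes from the treatment assignment, with the
  parameters held fixed) rather than model-fitting.
* **Static baselines.** Baselines are treatment-independent constants. The
  framework conditions on them; pre-experiment measurements estimate them.

In `hane_model()` the edge set is the support of the stored `gamma` values:
zero entries and self-loops are construction errors, not silent
conventions, because the outdegree statistic and the bias formulas depend on
the direct/interference separation. Self-effects belong in `beta`.

### Linear contagion as a special case

Peer-effects processes where *outcomes* (not treatments) propagate,
$$Y_i(z) = a_i + b_i z_i + \sum_k c_{ki} Y_k(z),$$
are HANE models in disguise: the equilibrium is linear in $z$, with
generally dense, multihop-induced interference coefficients.
`contagion_to_hane()` performs the reduction by a single matrix solve
against $I - C^\top$ — never by truncating the geometric series, which
would introduce an arbitrary accuracy knob. A spectral radius of $C$
strictly below 1 is required for the equilibrium to exist and is enforced at
construction (the recursion itself does not state this condition, but the
series solution diverges without it). The row/column orientation of $C$ is
pinned by taking the elementwise recursion as ground truth;
`simulate_contagion_fixed_point()` iterates that recursion directly and
serves as the oracle that would expose any transpose error. Conversion
entries below `1e-12` in magnitude are dropped so the produced edge set
remains the effective support; the fixed-point comparison tolerance in the
tests is `1e-10`, comfortably above accumulated solve error for contractive
instances and far below any real coefficient.

## Designs and their exact moments

All bias and variance results are functions of the first two moments of the
treatment vector, so each design object carries exact closed forms
(`design_marginals()`, `design_second_moment()`, `design_covariance()`):

| design | $E[z_i]$ | $E[z_i z_j]$, $i \neq j$ |
|---|---|---|
| Bernoulli($p$) | $p$ | $p^2$ |
| completely randomized, $m$ of $n$ | $m/n$ | $\frac{m(m-1)}{n(n-1)}$ |
| cluster, $k$ of $T$ clusters | $k/T$ | same cluster $\frac{k}{T}$; else $\frac{k(k-1)}{T(T-1)}$ |
| saturation, level $p_\tau$ | $p_{\tau(i)}$ | same cluster $\frac{p_\tau(n_\tau p_\tau - 1)}{n_\tau - 1}$; else $p_\tau p_\sigma$ |

Two contracts worth noting. The completely randomized constructor takes an
integer treated count `m` and *reports* `p = m/n`; a fractional budget must
be rounded by the caller, since silent rounding would change every moment
the formulas rely on. Saturation levels must give integer per-cluster
counts; the overall budget constraint $\sum_\tau n_\tau p_\tau = np$ is
checked only as a warning, because the estimator and its variance are well
defined without it. Size-1 saturation clusters have no within-cluster pairs,
so the same-cluster second-moment formula (with its $n_\tau - 1$
denominator) is never evaluated for them.

`design_support()` enumerates the full assignment distribution for small
instances; it backs the `exhaustive_moments()` oracle.

## Why simple estimators fail without baselines

Within the individually weighted linear class
$\sum_i (w_i z_i + v_i(1-z_i)) Y_i(z)$ — weights fixed before
randomization — matching coefficients on each parameter of the outcome
model forces $w_i = 1/(nE[z_i])$ and $v_i = -1/(nE[1-z_i])$ (the
Horvitz–Thompson form) and, for the interference coefficients, the
condition $P(z_k = z_i) = 1$ on every edge. Unbiasedness without baseline
information therefore requires jointly assigning every connected pair —
impossible under any design with real randomness on a connected network.
The residual bias has the closed form implemented in `bias_ht()`:
$$\frac{1}{n}\sum_{(k,i)\in E}\Big(\frac{\mathrm{Cov}[z_i, z_k]}{\mathrm{Var}[z_i]} - 1\Big)\gamma_{ki},$$
which interpolates between $0$ (perfectly correlated edges) and
$-\frac{1}{n}\sum \gamma$ (independent assignment: all interference lost).
`check_unbiasedness()` reports this `joint_assignment` condition, the
`equal_marginals` condition below, and the intermediate `common_ratio`
condition, edge by edge.

## The baseline-adjusted estimator

Subtracting baseline estimates removes the constraints that made
unbiasedness impossible. The resulting estimator
$$\widehat{\mathrm{TTE}}^{-\alpha} = \frac{1}{n}\sum_i \frac{Y_i(z) - \alpha_i}{E[z_i]}$$
is unbiased whenever marginal treatment probabilities are equal across
every edge — satisfiable for *any* network, known or not, by any
equal-marginal design. With a common marginal $p$ it collapses to
$\frac{1}{p}(\bar{Y} - \bar{\alpha})$ and needs only the population-average
baseline. The two baseline modes (per-individual vector vs. population
average) are distinct input states of `experiment_record()`; requesting the
average-baseline shortcut under unequal marginals is an error rather than
an approximation, because the shortcut is only an identity under equal
marginals. Under unequal marginals the bias is
`bias_baseline_adjusted()`:
$\frac{1}{n}\sum_{(k,i)\in E}(E[z_k]/E[z_i] - 1)\gamma_{ki}$.

### The ratio-adjusted form

Between "equal marginals" and full generality sits a symmetry condition:
for each unit $i$, the ratio
$\rho_i = E[z_i(1-z_k)]\,/\,E[(1-z_i)z_k]$ must be common across all of
$i$'s interference sources $k$. Deriving the weights from the
coefficient-matching constraints gives $w_i = 1/(nE[z_i])$ and
$v_i = \rho_i/(nE[z_i])$, i.e.
$$\widehat{\mathrm{TTE}}^{-\alpha}(\rho) = \frac{1}{n}\sum_i
\big(z_i + \rho_i(1 - z_i)\big)\frac{Y_i(z) - \alpha_i}{E[z_i]}.$$
This parameterization was a genuinely open design point: an equivalent
expression can be written with the control weight scaled by
$E[1-z_i]$ and a conditional-probability ratio absorbing the odds factor.
We fixed the convention by two requirements: $\rho_i$ must be the quantity
whose cross-edge constancy *is* the unbiasedness condition (the joint-moment
ratio above, which equals 1 exactly when $E[z_i]=E[z_k]$), and
$\rho \equiv 1$ under equal marginals must reduce the estimator literally to
the baseline-adjusted form. Both are enforced as tested identities, and the
enumeration oracle certifies unbiasedness under a varying-saturation design
that satisfies the condition with $\rho_i \neq 1$. The package verifies the
condition for a given design (`check_unbiasedness()`, `rho_from_moments()`)
but does not construct designs that satisfy it, as no general recipe exists
beyond equal marginals.

## Influence and variance

Substituting the outcome model into the estimator shows
$\widehat{\mathrm{TTE}}^{-\alpha} = \frac{1}{n}\sum_i L_i z_i / E[z_i]$ with
the *influence*
$$L_i = \beta_i + \sum_k \frac{E[z_i]\,\gamma_{ik}}{E[z_k]}$$
(`influence_vector()`; note $\gamma_{ik}$ — outgoing edges — where the model
stores incoming ones; the transpose relationship is tested explicitly since
it is the classic direction bug). Estimation of a network-interference
quantity thereby reduces to estimating the population mean of $\{L_i\}$
from the treated sample, and the variance under each design follows from
the treatment covariance:

* general: $\sum_{i,j} L_i L_j \mathrm{Cov}(z_i,z_j) / (n^2 E[z_i]E[z_j])$,
  computed in $O(n)$ through each design's block structure
  (`variance_general()`);
* completely randomized: $\frac{1-p}{p(n-1)} \mathrm{popvar}(L)$
  (`variance_crd()`);
* cluster-randomized (uniform sizes $n/T$): the same form over cluster-mean
  influences $L'_\tau$ with $T$ in place of $n$ (`variance_cluster()`;
  non-uniform clusters are an error there and are served by
  `variance_general()`);
* saturation: $\sum_\tau \frac{(1-p_\tau) n_\tau^2}{p_\tau n^2 (n_\tau-1)} V_\tau$
  with $V_\tau$ the within-cluster influence variance
  (`variance_saturation()`); the uniform-level display is its
  $p_\tau \equiv p$ specialization, a tested identity. Direct derivation
  (each cluster is an independent within-cluster completely-randomized
  draw) reproduces this display exactly, and enumeration on toy instances
  confirms there is no missing cross-cluster correction.

The practical readings: under the completely randomized design the variance
scales as $B^2 d_{\max}^2 / pn$ for effects bounded by $B$ and outdegrees by
$d_{\max}$ — consistency as soon as the treated count outgrows a constant —
and saturation designs with influence-homogeneous clusters dominate the
completely randomized design, which is the variance rationale for matched
designs when auxiliary covariates exist. Variance *estimation* from a single
realized experiment is out of scope: the formulas are population quantities
in the unobserved $L_i$.

## Certification strategy

Every closed form is certified two ways:

1. **Exhaustive enumeration** (`exhaustive_moments()`): every assignment in
   the support with its exact probability, outcomes through
   `evaluate_outcomes()`, estimator evaluated per assignment. On the
   fixed-count designs the support is equiprobable, so with model parameters
   chosen as dyadic rationals (the test generators draw from
   $\{-8,\dots,8\}/8$ and $/4$) every accumulated sum is exact in double
   precision; "exact equality" assertions use a `1e-12` tolerance that only
   absorbs the final division by the support size. No rational-arithmetic
   dependency is needed for this to be a genuinely exact check on these
   instances. Production comparisons between alternative formula routes use
   `1e-10`.
2. **Monte Carlo** (`run_monte_carlo()`): seeded design draws with empirical
   mean/variance and their Monte-Carlo standard errors (the variance SE via
   the fourth central moment). Agreement thresholds are fixed at 4 standard
   errors: tight enough to catch a wrong formula, loose enough that the
   suite's false-failure probability is negligible across all comparisons.

Problem sizes in the tests were chosen so that each property is checked on
the smallest instance that exercises it fully: enumeration instances use
$n = 8$ (supports of 70–4900 points) across 50 random models, formula
cross-checks run at $n = 200$, and Monte-Carlo agreement uses an
Erdős–Rényi instance with $n = 30$, $q = 0.2$ and 5000 replications. The
whole suite runs in well under a minute.

## The synthetic generator

`scenario_spec()` / `generate_instance()` define the study conditions. The
defaults — $n = 30$, directed Erdős–Rényi network with edge probability
$q = 0.2$, $\alpha_i \sim N(1,1)$, $\beta_i \sim N(1, 0.5^2)$, per-edge
$\gamma \sim U(0.1, 0.5)$ with a 25% chance of sign flip, completely
randomized design at $p = 1/2$, 5000 replications — describe a moderately
connected population whose spillovers are individually a few times smaller
than direct effects but collectively comparable to them (expected total
interference per unit $\approx n q \bar{\gamma}$), with both positive and
negative spillovers as in the motivating public-health examples. These are
the conditions under which the certification suite runs; they were fixed
once, not tuned.

What the generator emulates: network sparsity patterns (random, planted
clusters, star, chain, empty), heterogeneous signed edge effects,
cluster-aligned and cluster-misaligned designs. What it does not: degree
heavy-tails, effects correlated with network position, baseline drift over
time, nonlinear or threshold responses, and outcome measurement noise.
Passing tests therefore certify the mathematics of the framework under its
stated assumptions — they do not validate the additivity assumption itself
against any real intervention, and a real application should stress the
baseline-stability assumption in particular (`baseline_noise_study()`
quantifies the cost: a constant baseline misestimate $\delta$ propagates to
a bias of exactly $-\delta/p$, and zero-mean noise of standard deviation
$\sigma$ inflates the variance by exactly $\sigma^2/p^2$).

Seeding: a master seed drives instance generation; the Monte-Carlo harness
and the baseline-noise stream are seeded separately (the noise stream at a
fixed offset from the draw stream), so changing the replication count never
changes the generated instance and every result is bit-reproducible.

## Known limitations

* Additivity is load-bearing: binary outcomes, saturating effects and
  threshold effects are outside the model class, and no diagnostic in the
  package can detect them from a single experiment.
* The estimators require baseline estimates collected before any treatment;
  time-varying baselines violate the framework silently.
* The $\gamma$ matrix is never estimated; nothing here recovers the network.
* Variance formulas are population quantities; plug-in variance estimation
  from one realization is deliberately not offered.
* `check_unbiasedness()` verifies conditions for a *given* edge set — in
  practice the true edge set is unknown, and the equal-marginals condition
  is the only one that can be guaranteed network-free (it holds for every
  edge set when all marginals are equal).
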