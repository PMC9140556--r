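---
title: "Methods: multicomponent stress-strength reliability under GPHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicomponent stress-strength reliability under GPHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgphc)
```

## The model

An *s*-out-of-*j* system has *j* exchangeable components with i.i.d.
strengths $X_1,\dots,X_j$ and is exposed to a single common stress $Y$;
it functions while at least $s$ strengths exceed the stress.  Strengths
follow a Gompertz law with shape $\alpha>0$ and scale $\eta>0$,

$$G(x) = 1 - \exp\{-(\alpha/\eta)(e^{\eta x}-1)\},$$

which degenerates to the exponential law with rate $\alpha$ as
$\eta \to 0$.  The stress follows a Chen law with shapes
$\theta, \beta > 0$,

$$F(y) = 1 - \exp\{\theta(1 - e^{y^\beta})\},$$

whose hazard is bathtub-shaped for $\beta < 1$.  The system reliability
is

$$R_{s,j} = \sum_{i=s}^{j}\binom{j}{i}\int_0^\infty
  \bar G(y)^i\, G(y)^{j-i}\, dF(y).$$

The assumptions that matter are (i) independence of the strengths from
each other and from the stress, (ii) a *common* stress per system, and
(iii) the parametric forms above.  Nothing in the package relaxes (i)
or (ii); dependence between components is out of scope.

## Generalized progressive hybrid censoring

Both samples arise from GPHC life tests.  A design
$(n, m, c, T, R_1,\dots,R_m)$ places $n$ units on test, withdraws $R_i$
surviving units at the $i$-th observed failure, guarantees at least $c$
observed failures, allows at most $m$, and is clocked by the limit $T$;
the realized end is $T^* = \max\{X_{c:m:n}, \min\{X_{m:m:n}, T\}\}$.
Three cases result: the clock cuts in before the $c$-th failure
(case I: exactly $c$ failures observed, everything else removed at
$X_{c:m:n}$), between the $c$-th and the $m$-th (case II: observation
stops at $T$), or never (case III, which is ordinary progressive
type-II censoring).  `gphc_termination()` resolves the case by strict
comparison of $T$ with the realized order statistics; the boundary
event $T = X_{i:m:n}$ has probability zero under a continuous law, and
tied failure times are rejected by default for the same reason.
Recorded datasets rounded to a coarse grid can legitimately contain
ties, so the replay path (`progressively_censor()`, used when imposing
a design on real complete samples) passes `ties = "allow"`.

Simulation uses the exponential-spacings construction: with
$Z_i \sim$ Exp(1) i.i.d.,

$$Q_1 = Z_1/n, \qquad
  Q_i = Q_{i-1} + \frac{Z_i}{n - \sum_{j<i} R_j - i + 1},$$

then $W_i = 1 - e^{-Q_i}$ are the progressively censored uniform order
statistics and $X_i = F^{-1}(W_i)$ the target sample.  The denominator
of each increment is the number of units still at risk; in particular
the first spacing is scaled by $n$, since all $n$ units are at risk
before the first failure.  This normalization is not a free choice:
only with it are the at-risk-scaled gaps i.i.d. standard exponential,
which the exact-interval theory below requires, and a property test
enforces exactly that.  No explicit survivor bookkeeping is needed; an
explicit-withdrawal brute-force simulator lives in the test suite as
the independent oracle.

## The reliability integral

Expanding $G^{j-i}$ binomially and collecting equal powers
$l = i + k$ of the survival function turns $R_{s,j}$ into
$\sum_{l=s}^{j} c_l I_l$ with *integer* coefficients $c_l$ and

$$I_l = \int_0^\infty \theta\beta y^{\beta-1}
  \exp\{-l(\alpha/\eta)(e^{\eta y}-1) + \theta(1-e^{y^\beta}) +
  y^\beta\}\, dy .$$

Carrying out the alternating sum in integer arithmetic before any
quadrature removes the cancellation risk of summing signed
floating-point integrals; only $j-s+1$ adaptive quadratures are needed.
Each $I_l$ is computed after the substitution $t = y^\beta$, which
absorbs the density prefactor ($\theta\beta y^{\beta-1}dy = \theta\,dt$)
and removes the integrable singularity at the origin when $\beta < 1$ —
without it the adaptive rule occasionally misjudges the spike near zero
for small $\beta$.  Integration stops where the Chen survival falls
below $10^{-14}$; the default tolerances are $10^{-9}$ relative and
$10^{-10}$ absolute, and the accumulated error estimate is attached to
the result.  Values within $10^{-8}$ of 0 or 1 are clamped to the
boundary; anything further outside signals a real problem and is left
visible.  Two independent checks back the quadrature: a direct
integration of the unexpanded binomial-tail form, and Monte Carlo
simulation of the defining event (`rsj_mc()`).

## Maximum likelihood

The likelihood factorizes over the strength pair $(\alpha,\eta)$ and
the stress pair $(\theta,\beta)$, and within each pair one parameter is
conditionally linear: $\hat\alpha(\eta) = N_x\eta / K(\eta)$ with
$K(\eta)$ the weighted sum of $e^{\eta x}-1$ terms, and
$\hat\theta(\beta) = M^*/L(\beta)$ likewise.  `mss_mle()` therefore
profiles each pair down to one dimension, localizes the profile
maximum on a 61-point grid (the profile can be $-\infty$ on overflow
plateaus, which defeats plain golden-section search), refines it by
`optimize()`, and finishes with a damped Newton polish in
log-parameter space using analytic gradients and Hessians.  Iteration
stops when the log-scale gradient norm falls below $10^{-8}$ or the
step below $10^{-12}$, with at most 200 iterations; near the optimum
the predicted improvement drops below the floating-point noise of the
log-likelihood, so the monotonicity line search is bypassed once the
gradient norm is under $10^{-4}$ (the pure Newton step is then safe and
quadratically convergent).

Derivatives are coded from the log-likelihood expression itself, and an
independent central-difference Hessian oracle in the test suite guards
them.  Two non-obvious situations are handled explicitly:

* **Exponential boundary.**  For some censored samples the likelihood
  is decreasing in $\eta$ everywhere, so the supremum sits at
  $\eta \to 0$ (a Gompertz degenerating to Exponential($\alpha$)).
  The fit pins $\eta$ at a tiny floor ($5\times10^{-7}/\max x$,
  i.e. $10^{-9}$ of the overflow bound) and flags the result with
  `boundary = TRUE` instead of reporting non-convergence.
* **Flat profiles.**  Near-exponential data make the profile in
  $\eta$ extremely flat; different convergence rules can stop at
  visually different $\eta$ values whose log-likelihoods agree to
  $10^{-6}$.  The package iterates to its stated gradient tolerance
  and reports the corresponding maximizer.

Standard errors come from inverting the observed information (the
analytic negative Hessian; its cross blocks between the two pairs are
exactly zero).  The asymptotic interval for a parameter is
$\hat\Omega \pm z_{\tau/2}\,\mathrm{se}(\hat\Omega)$, deliberately not
truncated at zero — near-boundary parameters legitimately produce
negative lower endpoints, and hiding that would misrepresent the
normal approximation.  The interval for $R_{s,j}$ uses the delta
method with the gradient of the reliability surface obtained by
central differences on the quadrature (relative step $10^{-4}$); it
may exceed $[0,1]$, and clipping is opt-in.

## Exact pivotal intervals

With $V_j = \theta(e^{Y_j^\beta}-1)$, the transformed ordered stresses
are progressively censored standard-exponential order statistics, so
their at-risk-scaled spacings are i.i.d. Exp(1).  Two functions of the
data are then parameter-free pivots:
$B_1 \sim F(2M^*-2,\,2)$, free of $\theta$ and strictly increasing in
$\beta$, and $B_2 = 2\sum_j (S_j+1)V_j \sim \chi^2(2M^*)$, independent
of $B_1$.  Inverting $B_1$ at the upper $1-\tau/2$ and $\tau/2$ F
percentiles gives an interval for $\beta$ whose coverage is exact at
every sample size, in contrast with the normal-theory intervals.  The
strength side is identical in structure with
$T_1 \sim F(2M^*(J^*-1),\,2M^*)$ and $T_2 \sim \chi^2(2M^*J^*)$,
requiring a common number $J^* \ge 2$ of observed failures across
systems.

Root-finding uses bracket expansion (start $[10^{-8}, 1]$, quarter the
lower end or double the upper until the sign changes, at most 200
doublings) and bisection to machine tolerance; far above the root the
pivot evaluates as Inf/Inf through overflow, which is treated as "past
the root" since the map is strictly increasing.  Feasibility at the
lower end differs between the two sides, and the limits are derived
from the pivots actually used: as $\beta \to 0^+$,
$e^{y^\beta} \to e$ for every $y$, so $B_1 \to 0$ and every positive
F percentile has a root; as $\eta \to 0^+$, $e^{\eta x}-1 \to \eta x$
and $T_1$ tends to the strictly positive floor
$\sum_i\sum_t (R_t+1)x_{it} / [n_1(J^*-1)\sum_i x_{i1}] - 1/(J^*-1)$.
An F percentile below that floor has no positive root; the affected
endpoint is reported as 0 and the interval flagged one-sided.  This
collapse enlarges the interval and never costs coverage.

The joint region for $(\beta,\theta)$ splits the level between the two
independent pivots via $\tau_1 = (1+\sqrt{1-\tau})/2$,
$\tau_2 = (1-\sqrt{1-\tau})/2$ (each pivot event then has probability
$\sqrt{1-\tau}$).  The region is a curved band, not a rectangle; the
package reports the conservative bounding rectangle obtained by
extremizing the $\theta$ (or $\alpha$) bounds over the $\beta$ (or
$\eta$) interval endpoints — legitimate because the bound denominators
are monotone in the profiled parameter — and also returns the exact
region as a membership predicate for users who want it.

The distributional claims behind the pivots hold *conditionally on a
fixed number of observed failures*.  Under a finite time limit the
count $M^*$ (or $J^*$) is random, so a Kolmogorov–Smirnov check against
a single F or $\chi^2$ reference, and a coverage study at fixed degrees
of freedom, are only meaningful for designs whose count is constant
across replicates.  The package's property studies therefore use
time-unbounded (case III) designs of the study sizes
($n_1=8, m_1=6, c_1=4$ strength; $n_2=10, m_2=5, c_2=3$ stress) at the
study truth $\alpha=0.0061,\ \eta=0.009,\ \theta=0.009,\ \beta=0.2922$;
2000 replicates put the empirical 95% coverage of both exact intervals
inside $[0.93, 0.97]$ and pass the four pivot K-S checks at level 0.01.

## Bayesian route

The four parameters carry independent gamma priors.  The full
conditionals of $\alpha$ and $\theta$ are gamma — their shapes are the
observed counts plus the prior shapes, their rates the coefficient of
$-\alpha$ (resp. $-\theta$) in the log-likelihood plus the prior rates
— so they are updated by exact Gibbs draws.  (A sampler that instead
treated $\theta$ by Metropolis–Hastings would be harmless but wasteful;
the conditionals, not labels, decide the update type.)  The
conditionals of $\eta$ and $\beta$ have no standard form and are
updated by Gaussian random-walk Metropolis–Hastings in the original
parameterization, with non-positive proposals rejected outright
(equivalent to zero prior mass) and acceptance ratios computed in log
space.

Unstated pieces of the procedure were fixed once as follows:

* **Hyperparameters** default to $a_i = b_i = 10^{-4}$, near-flat in
  the usual practice.  Note that a gamma shape below 1 is *not* flat
  near zero (the density has a $p^{a-1}$ spike), so posterior modes of
  poorly identified parameters can sit visibly below the MLE; the
  prior-washout test therefore uses shape-1 priors, for which the
  posterior mode provably coincides with the MLE up to the $e^{-bp}$
  factor.
* **Proposal scales** default to 2.4 times the asymptotic standard
  errors from an internal ML fit, then adapt during a 400-sweep
  pre-phase (halving or doubling per 100 sweeps toward 20–50%
  acceptance).  Adaptation ends before the recorded chain starts, so
  the kept chain is a genuine fixed-kernel Markov chain.
* **Chain length** defaults to 4000 sweeps with the first 1000
  discarded.  The reliability is evaluated by quadrature at every kept
  draw, so its posterior summaries need no extra machinery.

Point estimates under squared-error loss are post-burn-in means.  The
HPD interval is the empirical shortest window: among all contiguous
windows of the sorted draws containing $\lceil \gamma n \rceil$ points,
the narrowest.  By construction it is never wider than the equal-tailed
interval on the same draws, and an exhaustive-window oracle verifies
the implementation.

## The synthetic-data generator

`simulate_mss()` reproduces the designed two-stage experiment: the
stress test runs first ($n_2$ systems under the stress design), and a
strength test under the strength design is run for each of the $M^*$
systems whose stress was observed.  Each system's strength test
realizes its own termination case; the matrix view with a common
$J^*$ — which the exact strength pivots require — is available exactly
when all systems realize the same count, which is guaranteed for
time-unbounded designs.  Defaults throughout the studies are the truth
$\alpha=0.0061,\ \eta=0.009,\ \theta=0.009,\ \beta=0.2922$ (giving
$R_{1,6}=0.5181$) and the design family above.

What the generator emulates: designed removals, the three-case
termination, the two-stage coupling of sample sizes ($M^*$ stresses
drive $M^*$ strength rows).  What it does not emulate: measurement
rounding (and hence ties), heterogeneity of the censoring design
across systems, dependence between components, or model
misspecification.  Passing tests therefore certify the estimators
under the model's own assumptions, not robustness to their violation.

## Problem sizes and runtime choices

The simulation-backed checks use sizes chosen to make Monte Carlo
error small relative to the asserted bands while keeping the default
suite fast: 2000 replicates for pivot distributions and exact-interval
coverage at the small study design; 500 replicate fits at a large
design ($J^*=20$ observed failures per system, $M^*=300$ systems) plus
one 4000-sweep chain for parameter recovery; 400 replicates per design
for the MSE-shrinkage comparison between $(n_1,n_2)=(8,10)$ and
$(15,20)$.  The full suite runs in about a minute.

## Known limitations

* No exact pivotal interval exists for $R_{s,j}$ itself — the
  reliability mixes all four parameters and the pivot algebra does not
  compose — so interval estimates for the reliability come only from
  the delta method and the posterior draws.
* The exact-interval machinery for strengths assumes the common-design,
  common-$J^*$ layout; datasets whose systems realized different
  counts are rejected by `strength_matrix()` rather than silently
  pooled.
* Asymptotic intervals can extend outside the parameter space by
  design; users wanting truncated reports must opt in.
* The Gompertz scale is estimated poorly when data are near
  exponential: its profile is almost flat, the reported standard error
  is large, and the boundary fit ($\eta$ pinned near 0) is the honest
  outcome for some censored subsamples.
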