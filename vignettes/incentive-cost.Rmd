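---
title: "Costing thresholded institutional incentives: models, formulas, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing thresholded institutional incentives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopcost)
```

## The model

A well-mixed population of $N$ individuals plays a cooperation dilemma
and evolves by imitation. The state of the population is the number of
cooperators $j \in \{0, \ldots, N\}$. In each time step two players are
sampled; the focal player adopts the model's strategy with the Fermi
probability $\left(1 + e^{-\beta(f_{\text{model}} -
f_{\text{focal}})}\right)^{-1}$, where $\beta \ge 0$ is the intensity of
selection: $\beta \to 0$ is neutral drift (payoffs are ignored),
$\beta \to \infty$ is strong selection (the better strategy is copied
almost surely).

Two games are supported, and they share the feature the whole analysis
rests on: the difference between the average cooperator and defector
payoffs,
$$\delta = \Pi_C(j) - \Pi_D(j),$$
does not depend on $j$ and is strictly negative.

* **Donation Game** (`game_spec("dg", ...)`): cooperation gives the
  partner $B$ at own cost $c$, with $B > c > 0$;
  $\delta = -(c + B/(N-1))$.
* **Public Goods Game** (`game_spec("pgg", ...)`): groups of size $n$
  are drawn by multivariate hypergeometric sampling; contributions $c$
  are multiplied by $r \in (1, n)$ and shared;
  $\delta = -c\left(1 - r(N-n)/(n(N-1))\right)$. The constraint
  $r < n$ already forces $\delta < 0$; the constructor also verifies it
  directly and `force = TRUE` lifts the parameter checks for
  exploration (e.g. the boundary case $r = n$).

Games where $\delta$ depends on $j$ (snowdrift, general prisoner's
dilemma, collective-risk games) are outside the model class: the
tridiagonal reduction below does not apply to them.

## Incentives and their cost

The institution observes $j$ and intervenes only while cooperation is
rare: for $1 \le j \le t$ (threshold $t \le N-1$) it pays per
generation
$$\theta_j = \frac{j}{a}\theta \;\; (\text{reward}), \qquad
  \theta_j = \frac{N-j}{b}\theta \;\; (\text{punishment}), \qquad
  \theta_j = \min\!\Big(\frac{j}{a}, \frac{N-j}{b}\Big)\theta
  \;\; (\text{mixed}),$$
and nothing for $j > t$ or at the homogeneous states. Here $\theta$ is
the per-capita incentive (payoff units) and $a, b > 0$ are efficiency
ratios: paying $\theta/a$ changes one cooperator's payoff by $\theta$.
The threshold reflects a budgeting intuition: once cooperation is
frequent it sustains itself, and spreading the budget thin helps no
one.

Inside the Fermi exponent the incentive enters as a shift $\theta_j/j$
added to the cooperator–defector gap, for all three schemes — this is
the transition-matrix convention the analytical results are built on,
and `transition_matrix()` reproduces it exactly. For punishment and
mixed schemes this differs from shifting the gap by the per-individual
payoff effect $\theta$; the alternative is available as
`exponent_shift = "per_capita"` and is documented rather than silently
substituted, because the reference behaviour of the punishment curves
follows the $\theta_j/j$ form. For reward with $a = 1$ the two
conventions coincide.

## Expected total cost

With mutation negligible, $S_0$ and $S_N$ absorb and the fundamental
matrix $n = (I - U_{\text{transient}})^{-1}$ counts expected sojourns:
$n_{ij}$ is the expected number of generations spent at $j$ cooperators
when a single mutant starts the process at state $i$. The expected
total cost is
$$E(\theta) = \sum_{j=1}^{N-1}\big(w_D\, n_{1j} + w_C\,
n_{N-1,j}\big)\,\theta_j$$
with three starting conventions (`evolution_params(start = ...)`):

* `"equal"` — $w_D = w_C = 1/2$: mutants are equally likely to invade
  either homogeneous state (the usual assumption on intermediate
  timescales);
* `"alldef"` — $w_D = 1$: the population starts from universal
  defection, the natural state in the absence of incentives;
* `"weighted"` — $w_D = 1/(r+1)$, $w_C = r/(r+1)$ with
  $r = e^{\beta(N-1)(\delta+\theta)}$: homogeneous states weighted by
  the long-run fixation balance. We implement this weighting exactly as
  stated; note that its exponent applies $\theta$ at all $N-1$ steps
  while the thresholded fixation ratio (below) carries $t\theta$ — an
  inconsistency inherent in the convention, which we document and do
  not resolve. At $\beta \to 0$ it collapses to `"equal"`.

## The tridiagonal reduction and closed forms

Because $\delta$ is constant, $I - U$ factors as
$\mathrm{diag}\{i(N-i)/N^2\} \, W$ with $W$ tridiagonal and built from
four logistic coefficients
$$a = \frac{1}{1+e^{-\beta(\delta+\theta)}}, \quad
  b = \frac{1}{1+e^{-\beta\delta}}, \quad c = 1 - a, \quad d = 1 - b$$
(`logistic_coefficients()`; the `_co` field suffix keeps them apart
from the efficiency ratios that share their letters). Rows up to the
threshold carry $(-c, 1, -a)$, rows above it $(-d, 1, -b)$, and
$n_{ij} = (W^{-1})_{ij}\, N^2 / (j(N-j))$, so
$$E_r(\theta) = N^2\theta \sum_{j=1}^{t}
  \frac{w_D (W^{-1})_{1j} + w_C (W^{-1})_{N-1,j}}{N-j}$$
for the reward scheme (with $\theta/a$ substituted for $\theta$ when
$a \neq 1$).

The inverse of a tridiagonal matrix obeys second-order recurrences
(`tridiag_inverse_entry()` implements the classical $z$/$y$ recurrence
and product form). For $W$ they reduce to a single polynomial family
$$\hat y_j = \hat y_{j-1} - (bd)\,\hat y_{j-2}, \qquad
  \hat y_0 = \hat y_1 = 1,$$
with three interchangeable evaluators in `yhat()`: the recurrence, the
binomial closed form $\hat y_j = \sum_k (-1)^k \binom{j-k}{k}(bd)^k$
(exact integer coefficients from `yhat_coefficients()`), and the
root form over $x^2 - x + bd = 0$ (`root_pair()`); the root form is
rerouted to the recurrence within $10^{-8}$ of the repeated root at
$bd = 1/4$. The index convention is $\hat y_j = y_{N-j}$, i.e.
$y_2 = \hat y_{N-2}$, $y_3 = \hat y_{N-3}$; it was fixed by validating
every formula against direct dense inversion rather than trusting any
single derivation.

Explicit costs (`cost_t1()`, `cost_t2()`, dispatched by
`cost_closed_form()`):

* $t = 1$:
  $(W^{-1})_{11} = y_2 / (y_2 - ad\,y_3)$ and
  $(W^{-1})_{N-1,1} = d^{N-2} / (y_2 - ad\,y_3)$. The all-defector
  variant uses the reciprocal form with prefactor
  $N^2\theta/(N-1)$ — a prefactor we carry consistently in the
  $t = 2$ all-defector cost as well, where the dense-solve oracle
  confirms it is required.
* $t = 2$ (for $N \ge 4$): the four edge entries of $W^{-1}$ share one
  denominator; the row-2 coupling makes $y_2 = y_3 - ad\,y_4$. For
  $N = 3$, $t = 2$ *is* the full-invest threshold $t = N-1$ and is
  routed to the generic path with a warning.
* any other $t$: generic evaluation through the tridiagonal-inverse
  recurrences on $W$.

`cost_t1_derivative()` implements the exact derivative; it is strictly
positive, so for $t = 1$ the constrained minimisation below is solved
by its boundary.

## Asymptotic limits

At $bd = 1/4$ (neutral drift) the recurrence has the repeated root
$1/2$ and $\hat y_j(1/4) = (j+1)/2^j$ *exactly*. Hence
$P(N) = \hat y_{N-2}(1/4) = (N-1)/2^{N-2}$ and
$Q(N) = (N-2)/2^{N-3}$ in closed form, and `neutral_drift_limit()`
evaluates the $\beta \to 0$ limits with no alternating-sum
cancellation — which is why no exact rational arithmetic is needed
here; the binomial sums serve as the independent oracle in the test
suite instead. The limits simplify to $N^2\theta/(N-1)$ (equal start)
and $2N\theta$ (all-defector start).

`strong_selection_limit()` gives the $\beta \to \infty$ limit, which is
the same for both starts: $+\infty$ if $\delta + \theta > 0$ (the
incentive overturns the dilemma and the rewarded state is revisited
endlessly), $2N^2\theta/(N-1)$ on the knife edge, and
$N^2\theta/(N-1)$ if $\delta + \theta < 0$.

## Cooperation frequency and the cheapest policy

In the small-mutation limit the long-run dynamics hops between the two
homogeneous states at rates given by the fixation probabilities
$\rho_{D,C}$, $\rho_{C,D}$ of single mutants
(`fixation_probabilities()`, computed from the standard birth–death
products in log space; the step ratio for an invading cooperator is
$T^-_k/T^+_k = e^{-\beta(\delta + \theta_k/k)}$ with the incentive
active only for $k \le t$). The products telescope to
$$\frac{\rho_{D,C}}{\rho_{C,D}} = e^{\beta[(N-1)\delta + t\theta]},$$
so the cooperation frequency $\rho_{D,C}/(\rho_{D,C} + \rho_{C,D})$ is
the logistic of $\beta[(N-1)\delta + t\theta]$ and
`theta_min()` inverts it exactly:
$\theta_0(\omega) = \big(\log(\omega/(1-\omega))/\beta -
(N-1)\delta\big)/t$.

`optimise_cost()` solves $\min_{\theta \ge \theta_0(\omega)} E(\theta)$
with $\theta$ clamped to $[0, \infty)$ (negative incentives are not
part of the scheme; $\theta_0 < 0$ simply means the target is free).
For $t = 1$ the proven monotonicity gives
$\theta^* = \max(\theta_0, 0)$ analytically. For other thresholds
monotonicity is only conjectured below a critical threshold, so a
deterministic dense grid (2001 points by default on
$[\max(\theta_0,0),\ \theta_0 + 10|\delta|(N-1)/t]$) with
golden-section refinement is used and reported as `method = "grid"`.

## General mutation rates

With $\mu > 0$ no state absorbs, so "total cost" needs a stopping
rule. Matching how such costs are accumulated in simulation practice,
we define $E^i(\theta)$ as the expected cost from start $S_i$ until the
population *first visits a homogeneous state* — strictly after leaving
the start when the start itself is homogeneous. This is computable from
the interior-restricted transition matrix: for interior starts
$E^i = \sum_j n_{ij}\theta_j$ over the stopped chain, and a homogeneous
start dwells at zero cost (the per-generation budget vanishes at
$j \in \{0, N\}$) before entering the adjacent interior state with
probability one. A literal unrestricted "inverse over all states" does
not exist for $\mu > 0$ — the full transition matrix is stochastic and
$I - U$ is singular — so the stopped-chain definition is the
computable reading, and the Monte-Carlo simulator (which implements the
stopping rule directly) validates it. The threshold gate
$\theta_j = 0$ for $j > t$ is applied under mutation exactly as
without: the sweeps that vary $t$ under $\mu > 0$ require it.
As $\mu \to 0^+$, $E^1$ converges to the absorbing-chain all-defector
cost, which the tests verify on a $\mu$-ladder.

## Numerical design

**Subtraction-free linear solves.** Under strong selection the
transient system $I - U$ is an M-matrix whose pivots cancel almost
completely: at, say, $N = 11$, $t = 2$, $\beta = 10$, $\theta = 5$ the
meaningful residue is of order $10^{-33}$ while the matrix entries are
of order one, so any ordinary factorisation (partial-pivoted LU
included) returns noise, and even 107-bit compensated arithmetic is
insufficient. `expected_cost()` therefore normalises each row by its
total rate, so up- and down-coefficients are exact complements, and
runs the Thomas elimination in the rearranged form
$$p_i = \mathrm{up}_i + h_i, \qquad h_i =
  \frac{\mathrm{dn}_i\, h_{i-1}}{p_{i-1}}, \qquad h_1 = \mathrm{dn}_1,$$
in which every operation is a sum, product or quotient of positive
quantities — the same idea that makes the Grassmann–Taksar–Heyman
algorithm subtraction-free. Forward elimination of the right-hand side
and back substitution are likewise all-positive. The result carries
full relative precision in plain doubles at any selection intensity;
across the 3000-cell verification grid the closed-form and matrix
routes agree to better than $10^{-14}$ relative. The exported
`fundamental_matrix()` (whose job is the full sojourn matrix, used for
visit-count diagnostics) keeps a conventional LU solve with a
conditioning guard.

**Cancellation-free closed forms.** The same hazard appears in the
explicit denominators $y_2 - ad\,y_3$. The recurrence implies the exact
identity $\hat y_k - d\,\hat y_{k-1} = b^k$, giving
$$y_2 - ad\,y_3 = b^{N-2} + cd\,y_3, \qquad
  y_2 - ac\,y_3 = c^2 y_3 + a\,b^{N-3} \;\; (t = 2),$$
sums of positive terms evaluated directly. With these forms (and
log-space evaluation of $\beta e^{-\beta(\delta+\theta)}a^2$ in the
derivative) no multiple-precision arithmetic is needed anywhere: the
strong-selection checks at $\beta = 50$ hold to $10^{-6}$ and the
closed forms were cross-checked during development against a 60-digit
reference evaluation of the same formulas.

**Other choices.** Fermi probabilities and the four logistic
coefficients are computed with `plogis` (piecewise-stable logistic), so
they saturate to exact 0/1 rather than overflowing; $bd$ uses the
symmetric form $1/(2 + e^{\beta\delta} + e^{-\beta\delta})$. Fixation
products are accumulated as log-sum-exp, making $\beta = 500$
unremarkable. Binomial coefficients follow the convention
$\binom{m}{k} = 0$ outside sampling support, matching hypergeometric
draws. Degenerate tridiagonal systems (zero pivots in the $z$/$y$
recurrences) raise explicit errors.

## The Monte-Carlo simulator

`simulate_cost()` is the package's independent oracle: it realises the
exact chain, accumulates $\theta_j$ at every generation spent in an
interior state, and stops at the first homogeneous visit (the same
stopping rule as the $\mu > 0$ cost, whose definition it validates).
Two samplers are provided. The default `"jump"` method samples the
embedded jump chain with geometric sojourn times — an exact
reformulation, since the time spent in a state between moves is
geometric with the state's total move probability — and advances all
replicates in lock-step, which makes $2 \times 10^5$ replicates per
parameter cell take well under a second. The `"step"` method is the
literal per-generation walk, kept for one-step frequency checks. Both
are driven by a single seeded base-R stream (the package is
single-threaded; identical seed, identical result, bit for bit), and
`pool_simulations()` merges runs by sufficient statistics so that two
pooled runs are statistically identical to one concatenated run. A
`max_steps` guard (default $10^7$ generations) censors runaway
replicates and *reports* them via `guard_hits`; it never truncates
silently.

What the simulator emulates is exactly the model: sampled imitation
with the thresholded incentive shift in the exponent, optional
mutation, hypergeometric-average payoffs through $\delta$. What it does
not emulate — network structure, asynchronous multi-mutant dynamics,
payoff noise, finite observation error of $j$ by the institution —
bounds what agreement between simulation and formulas can show about
field data: the validation is internal to the model class.

**Problem sizes.** The verification suite uses $N \le 12$, thresholds
$t \in \{1, 2\}$ for the closed forms, $\beta \in [10^{-3}, 50]$,
$\theta \le 5$, $2 \times 10^5$ replicates per Monte-Carlo cell on a
64-cell grid, and $10^5$–$2\times10^5$ replicates for the
general-mutation checks — sizes at which the exact and stochastic
routes separate cleanly (3-standard-error bands of width a few parts
per thousand) while the whole suite stays fast.

## Known limitations

* Closed forms cover the reward scheme (the gap shift must be constant
  across incentivised rows); punishment and mixed schemes go through
  the matrix route.
* The `"weighted"` start convention carries the $t$-inconsistency noted
  above; it is reproduced as specified.
* The stopped-chain cost under mutation is one of several defensible
  definitions (e.g. whether post-absorption dwell should count); it is
  the one consistent with fixation-terminated simulation practice, and
  the simulator validates precisely this definition.
* The critical threshold $t^*$ below which the cost stays monotone is
  explored numerically only (the acceptance script reports monotone
  fractions for $t < N-1$ and the non-monotone full-invest curve); no
  proof is attempted for general $t$.
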