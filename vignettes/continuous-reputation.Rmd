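---
title: "Continuous reputations in the donation game: model, stability toolkit, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous reputations in the donation game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrep)
```

## The model

In the donation game a donor pays a cost $c$ to give a co-player a benefit
$b > c$. Indirect reciprocity sustains cooperation in such games through
reputation: third parties observe interactions, judge the donor, and future
partners condition their own giving on those judgements. Classic analyses
make everything binary — reputations are good or bad, actions cooperate or
defect — but real assessments are graded and noisy. This package treats
both as continuous variables on $[0,1]$.

A *social norm* is a pair of maps:

* an **assessment rule** $\alpha(x, y, z) \in [0,1]$: the reputation
  assigned to a donor whose current reputation (in the observer's eyes) is
  $x$, who performed action $y$, toward a recipient with reputation $z$;
* a **behavioural rule** $\beta(x, y) \in [0,1]$: the degree of cooperation
  of a donor with self-reputation $x$ toward a co-player with reputation
  $y$.

Opinions are private: the state of a population of $N$ players is an
$N \times N$ *image matrix* $m$, where $m_{ki}$ is observer $k$'s opinion
of player $i$ (diagonal entries are self-images). When an interaction
between donor $i$ and recipient $j$ is observed (each observer sees it
independently with probability $q$), observer $k$ stores
$\alpha_k(m_{ki}, a, m_{kj})$ where $a = \beta_i(m_{ii}, m_{ij})$ is the
realized action. Averaging over recipients and observation events gives the
deterministic mean-field map implemented by `meanfield_step()`:
$$
m_{ki} \leftarrow (1-q)\,m_{ki} + \frac{q}{N-1}\sum_{j \neq i}
  \alpha_k\!\left[m_{ki},\, \beta_i(m_{ii}, m_{ij}),\, m_{kj}\right].
$$

Binary norms are embedded by multilinear interpolation
(`interpolate_norm()`): the eight assessment corners and four behaviour
corners are interpolated trilinearly/bilinearly, which reproduces every
corner exactly and keeps all values inside $[0,1]$. For Simple Standing
(preset `"L3"`), the best-known member of the leading eight, this yields
the closed forms $\alpha(x,y,z) = yz - z + 1$ and $\beta(x,y) = y$.

## Recovery from disagreement

A norm is *cooperative* if $\alpha(1,1,1) = \beta(1,1) = 1$, so the
all-good matrix ($m_{ki} \equiv 1$) is a fixed point. Whether small
disagreements heal is decided by the first partial derivatives at that
corner, $A_x, A_y, A_z$ of $\alpha$ and $B_x, B_y$ of $\beta$
(`norm_slopes()`; for interpolated norms these are exact corner
differences). Linearizing the map in the deviations
$\varepsilon_{ki} = 1 - m_{ki}$ gives an $N^2 \times N^2$ system
(`jacobian_matrix()`) whose spectrum collapses into four families
(`eigen_spectrum()`) with multiplicities $(N-1)^2$, $N-1$, $N-1$, $1$. The
largest eigenvalue (for non-negative slopes) is $q\,Q$ with
$$
Q = -1 + A_x + A_z + A_y (B_x + B_y),
$$
the scalar computed by `compute_Q()`. $Q < 0$ guarantees local recovery of
full cooperation; $Q > 0$ means disagreement is amplified. The four-family
pattern is known in closed form for small $N$ and conjectured in general;
the package treats the numeric Jacobian eigendecomposition as the oracle
and verifies the closed forms against it for $N \le 6$ over random slope
sets at tolerance $10^{-10}$ (this dual route — formula versus `eigen()` —
is a core part of the test suite).

The leading eight split cleanly: the four norms with
$\alpha_{1C0} = 1$ (helping an ill-reputed partner is not penalized) have
$A_z = 0$ and $Q = 0$, while the strict ones (Stern Judging, Judging,
and kin) have $A_z = 1$ and $Q = 1 > 0$. At $Q = 0$ recovery still occurs,
but only through higher-order terms — a slow decay without a single
exponential scale, which `recovery_trajectory()` exhibits directly.

## Mutant suppression

The second stability notion asks whether a norm punishes nearby variants of
itself. A mutant uses $\alpha - \delta$ and $\beta - \eta$ with small
offset functions ($\delta_1 = \delta(1,1,1) \ge 0$,
$\eta_1 = \eta(1,1) \ge 0$; `mutant_offset()`, `offset_norm()`). In the
stationary state of a mutant/resident population the four block
reputations $m_{00}, m_{01}, m_{10}, m_{11}$ deviate from 1 by amounts
that are linear in the offsets; `first_order_epsilons()` and
`finite_p_epsilons()` implement the closed forms for a rare mutant and for
a finite mutant fraction $p$. The payoff difference between a mutant and a
resident is, to first order and for every $p$,
$$
\Delta\pi_0 = -\frac{b A_y B_y - c(1 - A_x)}{1 - A_x - A_y B_x}
  \left[\frac{B_x + B_y}{1 - A_x - A_z}\,\delta_1 + \eta_1\right],
$$
so mutants are penalized exactly when
$b/c > (1 - A_x)/(A_y B_y)$ (`bc_threshold()`). Cooperation cannot be
stabilized when reputation ignores the donor's action ($A_y \approx 0$) or
when behaviour ignores the co-player's reputation ($B_y \approx 0$).

Three numerical subtleties shaped the design here:

* **Singularities.** The closed forms require $A_x + A_z < 1$,
  $A_x + A_y B_x < 1$, and (at finite $p$) $Q < 0$. Every leading-eight
  norm violates the last condition, so `finite_p_epsilons()` raises a
  typed error (`contrep_singularity`) pointing to the numeric oracle
  rather than returning infinities.
* **The numeric oracle.** `stationary_numeric()` iterates the full
  nonlinear four-equation stationarity system with damping
  $\lambda = 0.5$, tolerance $10^{-12}$, cap $10^5$ iterations, from the
  all-ones state. Damping guards oscillatory maps; the all-ones start
  matches the cooperative initial condition of the theory. The tests
  verify Richardson-style that its deviations differ from the first-order
  closed forms at $O(\delta_1^2)$.
* **Second order.** No closed-form second-order solution is tabulated
  anywhere, so the package exposes the second-order expansion as a
  residual (`second_order_residual()`, using the curvatures from
  `norm_curvatures()` and the offset derivatives) plus a Newton solver
  (`solve_second_order()`). Its root agrees with the numeric oracle at
  $O(\delta_1^3)$ for smooth norms, and remains usable — with only
  percent-level accuracy, as expected near the finite-$p$ singularity —
  for the leading eight.

The default offset form, $\delta(x,y,z) = \delta_1(2yz - 2z + 1)$, is the
one used in the reference mutant experiments. Its choice away from the
cooperative corner matters only at second order; treating it as the
default full functional form is an explicit modelling assumption of the
residual-based solver.

## The stochastic simulator

`run_simulation()` is an agent-based implementation of the same
micro-dynamics, with three noise channels: observation probability $q$
(incomplete information), perception error $e$ (a stored opinion is
replaced by a uniform draw), and implementation error $\gamma$ (the
realized action is replaced by a uniform draw — a single realized action,
which is what payoffs use and what all observers judge). Design choices:

* Observers are all $k \neq i$, the recipient included; the donor's
  self-image is updated by the same rule behind a default-on flag
  (`self_update`), mirroring the mean-field map's equal treatment of
  diagonal entries. The recipient's update is probabilistic in $q$ like
  everyone else's; a certain-update variant would differ only at finite
  $N$.
* Accumulated payoffs are divided by $M/N$, the expected number of donor
  appearances, so a fully cooperative error-free run scores exactly
  $b - c$ per player. Only signs and relative magnitudes of payoff
  differences are compared across configurations.
* The hot loop is compiled (Rcpp) but consumes R's random number stream,
  so any run is bit-reproducible under `set.seed()`. Replicas within
  `mutant_experiment()` consume the same stream sequentially.
* The simulator requires corner-representable (multilinear) norms, which
  covers every interpolated norm and every multilinear offset — in
  particular the default mutant offset. `as_corner_norm()` checks
  representability on a grid and refuses silently curved norms; those are
  still usable in all mean-field routines.

The ensemble-averaged one-round update of the simulator (with a pinned
donor and no errors) equals one application of `meanfield_step()` on the
donor's column; the test suite checks this against $1.5\times 10^4$
replicas, which ties the stochastic and deterministic engines together.

## What the synthetic experiments emulate — and what they do not

The package's experiments generate all their data internally:
`perturbed_image_matrix()` (a random 20% of opinions dropped to 0.9)
emulates a society shortly after a burst of disagreement;
`random_corner_norm()` (seven uniform assessment corners,
$\alpha(1,1,1) = 1$ fixed, Simple Standing's behaviour rule) emulates the
space of "slope mutants". These are idealizations: real reputational data
would have correlated, non-uniform disagreements, norms that differ across
observers, and population structure — none of which the generators
produce. Passing tests therefore demonstrate internal consistency of the
model and its analysis at the stated conditions, not empirical claims
about human reputation systems. The model also excludes, by scope:
strategy updating between rounds, gossip/communication mechanisms, network
structure, and global (non-local) evolutionary stability.

## Problem sizes and test design

The analysis-scale defaults follow the reference experiments: $N = 50$,
$q = 0.4$, $b = 2$, $c = 1$, $\delta_1 = 0.02$, $e = \gamma = 0.1$,
$p = 0.5$, $M = 10^4$. Where the package's own checks need different
sizes, the choices are deliberate:

* Spectrum validation uses $N = 2..6$ — large enough to exercise all four
  eigenvalue families well beyond the symbolically verified range, small
  enough that the dense $N^2 \times N^2$ eigenproblem is instant.
* Mean-field recovery runs at $N = 20$, 400 steps: the asymptotic decay
  rate of the $Q<0$ norm then matches $q|Q|$ within a few percent, and
  the $Q=0$ slowdown is already unambiguous.
* The half-and-half mutant experiment has a genuinely small effect
  ($\Delta\pi_0 \approx -2\times10^{-3}$ with both error channels on —
  an error-averaged mean-field fixed point predicts the same magnitude),
  so the suppression checks average 4000–8000 replicas, partway toward
  the $5\times10^4$ used in the source experiments, to resolve the sign
  at three standard errors.
* The slope-mutant scatter runs 50 mutants at $M/N = 100$ rather than
  $\sim 10^3$; the negative rank correlation between $Q$ and
  $\Delta\pi_0$ is already stable at that fidelity.
* The benefit-cost sweep test uses $\delta_1 = 0.06$: the sign-change
  location is offset-independent at first order, and the larger offset
  buys Monte-Carlo power without changing the claim under test.

## A worked example

```{r example}
ss <- interpolate_norm("L3")
norm_slopes(ss)
compute_Q(ss)
bc_threshold(norm_slopes(ss))

# a graded variant with sensitivity 0.9 has Q < 0 and a finite threshold
sv <- standing_variant(0.9)
compute_Q(sv)
bc_threshold(norm_slopes(sv))

# first-order deviations and payoff difference for a delta1 = 0.02 mutant
first_order_epsilons(norm_slopes(sv), delta1 = 0.02)
payoff_difference_first_order(norm_slopes(sv), delta1 = 0.02,
                              game = game_params(b = 2, c = 1))

# the numeric oracle captures the higher-order corrections
mut <- offset_norm(sv, mutant_offset(delta1 = 0.02))
stationary_numeric(sv, mut, p = 0.5)
```

## Known limitations

* The closed-form spectrum is validated numerically up to $N = 6$ (and by
  construction at the tested random slopes); it is not proven for general
  $N$ here.
* Finite-difference slopes/curvatures for non-interpolated norms are
  one-sided (the cooperative point is a domain corner) with accuracy
  $O(h)$; interpolated norms always use exact corner differences.
* The stochastic simulator is restricted to multilinear norms; curved
  norms require the mean-field path.
* `second_order_residual()` needs the offset's functional form away from
  the corner; results for mutants specified only by $\delta_1$ inherit
  the default form's assumption.
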