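---
title: "Queuing-network models of cancer screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queuing-network models of cancer screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenq)
```

## The model

`screenq` models a screenable disease as an open network of
infinite-server queues. Each queue counts the people currently in one
disease state; "service" is the random time spent in that state, and
"exiting the network" is death. Infinite servers are not an
approximation here but a phenomenological choice: disease progression
in one person does not wait on anyone else, so all agents are served in
parallel with mutually independent durations.

A network of $J$ queues is specified by a routing matrix $R$ (entry
$r_{ij}$ is the probability of moving to queue $j$ on leaving queue
$i$; the residual mass $r_{i0} = 1 - \sum_j r_{ij}$ exits), exogenous
Poisson arrival rates $\eta = (\eta_1,\dots,\eta_J)$, and arbitrary
service-time distributions with finite means $1/\mu_j$. Waiting times
are *not* assumed exponential; only arrivals are Markovian. The
aggregate arrival rates solve the traffic equations
$\lambda = \eta + \lambda R$ (row vectors), i.e.
$\lambda = \eta (I-R)^{-1}$, and with loads
$\rho_j = \lambda_j / \mu_j$ the joint stationary law factorises into
independent Poisson marginals:

$$P(N_1^* = n_1, \dots, N_J^* = n_J) = \prod_{j=1}^{J}
  e^{-\rho_j} \frac{\rho_j^{n_j}}{n_j!}.$$

The law depends on the service distributions only through their means
(the insensitivity property), which is why empirical waiting-time
samples can stand in for parametric fits. Little's law converts
occupancy to time: the expected sojourn — interpreted as expected
residual lifetime — is
$E(W^*) = \frac{1}{\eta}\sum_j \rho_j$ with $\eta$ the total exogenous
rate. Tail probabilities such as
$P(N_j^* > x) = 1 - e^{-\rho_j}\sum_{k=0}^{\lfloor x\rfloor}
\rho_j^k/k!$ come out exactly, which matters for peak-load questions
that averages cannot answer.

## The screening comparison

The three-state subgroup model (`build_screening_network`) has queues
for undetected early disease, early-treated disease, and late-stage
symptomatic disease. Undetected early disease (mean sojourn $1/\mu_1$)
resolves three ways: death with probability $r_{10}$, early detection
and treatment with probability $r_{12} d$ (where $d$ is the screen's
detection probability), and symptomatic progression with the remainder
$r_{13} + r_{12}(1-d)$. Early-treated patients survive $e \cdot L$ on
average, where $L$ is the subgroup's conditional residual life
expectancy and $e \in [0,1]$ is the treatment *effectiveness*;
late-stage patients survive $1/\mu_3$.

The no-screening counterfactual reassigns the screened mass $r_{12}$
to progression rather than to death: screening catches people who
would otherwise have presented symptomatically, while
death-before-diagnosis is already carried by $r_{10}$. (The
counterfactual topology is a genuine design choice; this is the one we
consider clinically coherent.) The expected residual-lifetime gain is
the difference of the two expected sojourns, which reduces to the
closed form $r_{12}\, d\, (eL - 1/\mu_3)$ for this topology — linear
in $e$ at fixed $d$ and non-decreasing in both, which the tests verify
over a grid.

Three extensions share this machinery:

* **Morbidity** multiplies the affected portion of a sojourn by a QALY
  factor $q \in [0,1]$ (`apply_morbidity`); temporary side effects
  reweight only the period in which they occur.
* **Treatment mortality** replaces the early-treated service law by a
  mixture: with probability $p$ a short premature-death time (default a
  point mass at one month — a placeholder whose exact shape matters far
  less than $p$ itself), with probability $1-p$ the original law
  (`apply_mortality`).
* **Specificity** (`net_benefit_with_specificity`) charges the program
  for false positives: healthy screenees test positive at the
  false-positive rate, a fraction $1-s_c$ survives the confirmatory
  test (specificity $s_c$), and each such person loses a configurable
  fraction of their conditional life expectancy. The net score can go
  negative when overtreatment outweighs early detection.

Benefits are reported per cancer patient by default, per positive case
detected on request (divide by the routing probability $r_{12}d$), and
per screen via the standing-pool yield: the expected number of
undetected early cases at any screening instant is $\rho_1 = \eta_1 /
\mu_1$, so one screen of a random member of a population of size $M$
finds $\rho_1 / M$ detectable cases in expectation. The per-screen and
per-patient rankings can disagree — high-incidence groups with modest
per-patient gains can win per screen — and the test suite constructs
such an instance.

## Parameter estimation

Because no parametric family is assumed, estimation is deliberately
plain: empirical means for durations and empirical proportions for
routing. From a registry table (one row per case: subgroup covariates,
diagnosis year, treated flag, time to treatment, survival months, vital
status), `estimate_subgroup_params` computes

* $\eta_1$: the mean yearly diagnosis count over the study window
  (default 2000–2016);
* $f$: the unweighted mean of per-year treated fractions;
* mean treated survival: mean of (imputed survival − time to
  treatment) among the treated;
* mean late-stage survival:
  $1/\mu_3 = f\,(w + \text{treated}) + (1-f)\,\text{untreated}$, with
  $w$ the tunable diagnosis-to-treatment mean (registries rarely record
  it reliably; default 1 month);
* $L$: a life-table lookup at the age-band midpoint.

Right-censored survivals are imputed with the conditional empirical
rule: a censored time $t$ becomes $t + \operatorname{mean}(s - t \mid
s > t)$ over observed deaths $s$. We apply the rule within treatment
strata, because treated and untreated survival laws differ sharply and
pooling would bias the residuals. The rule is undefined for a censored
time beyond every observed death; such records are left unchanged
(zero residual — the empirical law has no mass beyond its maximum) and
flagged. The conditional *mean* is used rather than a draw from the
conditional distribution; the mean is what the downstream model
consumes, so no variance is lost where it matters. Imputation never
decreases a time, and estimation is deterministic and order-invariant.

Subgroups under 100 records are excluded (small-sample estimates are
unstable), mirroring exclusions of sparse strata in registry practice.
Subgroups are keyed by age at disease development, not current age, so
there is no flux between age-band models. Two acknowledged
approximations: incidence is slightly underestimated by deaths before
diagnosis (a warning is attached to 75+ bands, where it is largest),
and the coarse life-table bands (≤64, 65–74, 75+) produce a small
artificial upward bump in modeled survival at age 65.

Three quantities are not estimable from diagnosis-anchored registries
and are configuration parameters with stated defaults: the early-stage
sojourn $1/\mu_1$ (default 180 months, reflecting a roughly 15-year
window of pre-symptomatic progression in the pancreatic-type disease
that motivates the defaults) and the routing fractions $r_{10}, r_{12},
r_{13}$ (defaults 0.1 / 0.3 / 0.6).

## The synthetic registry

`generate_registry` is first-class, tested code, not a throwaway
fixture: it emulates Poisson yearly diagnosis arrivals per subgroup,
Bernoulli treatment routing, arbitrary survival laws, and
administrative right-censoring at a cutoff. Defaults describe a
poor-prognosis cancer: treated survival lognormal with mean 13.5
months — the pooled mean survival printed for pancreatic cancer in the
bundled registry overview — and coefficient of variation 0.95 (the
printed SD of 23.6 months pools treated and untreated patients, so the
treated-only dispersion is set once at a realistic cv ≈ 1); untreated
survival exponential with mean 3 months; time to treatment uniform on
(0, 2) months. What the generator does *not* emulate: secular trends
in incidence or survival, competing-cause mortality, stage structure,
or correlated covariates. Passing recovery tests therefore demonstrate
estimator correctness under the stated sampling model, not robustness
to those real-data features.

## The simulator and its role

`simulate_network` is the independent oracle for the analytic results,
not a second implementation of them. It draws each agent's full path —
arrival from the Poisson stream, service durations from the actual
distributions (not just their means), routing by the kernel — and
superposes paths; this is exact for infinite-server networks because
agents never interact. Queue lengths are then sampled at spaced epochs
(`empirical_stationary`; burn-in defaults to 5× and spacing to 1× the
largest mean service time).

Reproducibility uses a single seeded stream with draws in a fixed,
documented order (arrival counts, arrival times, then per-hop batches),
so identical seed and configuration give bit-identical event logs
without per-agent substream bookkeeping.

## Goodness of fit

Two Kolmogorov–Smirnov families mirror the validation logic: are
yearly arrival counts Poisson (a necessary condition for Markovian
arrivals), and does an observed queue-length distribution match the
predicted Poisson($\rho_j$)? Both references are discrete, where the
classical KS null distribution is conservative, and the arrival test
additionally plugs in an estimated rate; p-values therefore come from
a simulated null (default 2,000 replicates) that re-estimates the rate
per replicate, restoring calibration while keeping the familiar
statistic. An `simulate_null = FALSE` flag exposes the asymptotic
version. Multiple tests across subgroups are Bonferroni-adjusted
(`bonferroni`, decisions at the adjusted 5% level).

## Numerical choices and problem sizes

* Traffic equations: direct solve of $\lambda = \eta(I-R)^{-1}$ with a
  fixed-point fallback; residual tolerance $10^{-9}$ relative.
  Networks here are tiny ($J \le 6$ in every example), so robustness
  beats speed.
* "Every customer eventually exits" is checked via invertibility of
  $I - R$ with a non-negative inverse (residual tolerance $10^{-10}$)
  — necessary and sufficient for a unique non-negative traffic
  solution.
* Poisson pmfs and tails are computed in log space; the tail uses the
  exact partial-sum formula; diagnostics cap enumeration at
  $10\rho + 50$ terms. Queues with $\rho_j = 0$ get a degenerate
  mass at zero rather than an error (the no-screening network has an
  empty early-treatment queue by construction).
* Zero-probability ties in allocation are broken deterministically
  (score desc, size desc, key lexicographic); scores strictly greater
  than the threshold qualify; fractional screens are not allocated.
* Validation-study sizes were fixed by a priori power analysis, not by
  the clock. The total-variation statistic between an empirical pmf on
  $n$ samples and a Poisson law with mean $\rho \approx 50$–$60$ has a
  noise floor of about $2.4/\sqrt{n}$ even under a perfect model, so
  resolving a 0.02 band needs $n \approx 4\times 10^4$ decorrelated
  epochs; the product-form check samples exactly that, at 2× the
  largest mean service spacing, and thins by a further factor of two
  before the KS test so its iid simulated null is calibrated. The
  Little's-law check uses deterministic services — the identity is
  family-insensitive, so this isolates routing randomness — making the
  1% band roughly three Monte-Carlo standard deviations at the stated
  $10^5$ agents.

## Limitations

Finite-server contention (shared oncologists, scanners), repeated
screening with correlated test outcomes, time-varying arrival rates,
and non-Poisson exogenous arrivals are out of scope; the product form
does not survive them, and simulation would be the only general tool.
Estimates inherit the biases of observational registries (treatment
selection, secular trends, lead-time effects beyond the
conditional-life-expectancy correction), and cross-country transfer
requires re-estimation. Aggregating a 17-year window masks trends in
incidence and survival over time.
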