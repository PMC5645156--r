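---
title: "Context-sensitive valuation by sequential Bayesian belief updating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-sensitive valuation by sequential Bayesian belief updating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcv)
```

## The model

A choice set offers $N$ options, each characterized by reward amounts
$R_{i,n}$ on $I$ attributes (for a car: a price reward and a quality
reward). The agent treats each attribute's rewards as draws from an
attribute-specific population with unknown average $C_i$,

$$C_i \sim \mathcal{N}(\mu_{C_i}, \sigma^2_{C_i}), \qquad
  R_{i,n} \sim \mathcal{N}(C_i, \sigma^2_{R_i}),$$

and infers $C_i$ by considering the rewards one at a time, in a random
order that may differ between attributes. Each observation triggers a
conjugate-Gaussian update of the running belief
$(\hat\mu_{C_i}, \hat\sigma^2_{C_i})$, and the **incentive value** of the
reward considered at that step is the precision-weighted prediction error
that drives the update:

$$V_i(R_{i,n}) =
  \frac{\hat\sigma^2_{C_i}}{\hat\sigma^2_{C_i} + \sigma^2_{R_i}}
  \left(R_{i,n} - \hat\mu_{C_i}\right),$$

after which $\hat\mu_{C_i} \leftarrow \hat\mu_{C_i} + V_i(R_{i,n})$ and
$\hat\sigma^2_{C_i} \leftarrow \hat\sigma^2_{C_i} -
g\,\hat\sigma^2_{C_i}$ with $g$ the same gain. The option's value is the
sum of its attribute values, $V(u_n) = \sum_i V_i(R_{i,n})$, and a choice
follows the softmax rule
$P(u_n) \propto \exp\{\beta V(u_n)\}$.

Two normalizations are built in: a *subtractive* one (value is measured
against the current reward expectation, so the same reward is worth less
where more is expected) and a *divisive* one (the gain $g \in (0,1)$
scales prediction errors by the relative precision of the belief, so
small reward variance magnifies them). Because updating is sequential and
order is random, the options present in the set shape each other's values
— the source of all within-choice context effects produced by the model.

The reward-update form is printed above for a single step and applied
recursively at every step (equivalently: precisions add). After $t$
observations the belief variance is exactly
$1/(1/\sigma^2_C + t/\sigma^2_R)$, a property the tests assert at
$10^{-10}$ against the recursive path.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| $\mu_C$ | prior mean of the attribute average (reward units) | 0 | the neutral default; scanned over $\{-2, 0, 2\}$ and finer grids by the drivers |
| $\sigma^2_C$ | prior variance | 1 | fixed at 1 in all canonical runs; only the ratio $\sigma^2_R/\sigma^2_C$ matters for the gain |
| $\sigma^2_R$ | reward variance | 1 | scanned over $\{0.1, 1, 10\}$; context effects need it small |
| $\beta$ | softmax inverse temperature | 1 | $\beta = 0$ gives uniform choice |

Zero variances are rejected rather than treated as limits: the gain and
the variance update degenerate there, and no canonical condition uses
them.

## Choice probability engines

Choice probabilities are averages over presentation orders. Two engines
compute them:

* `exact_choice_probs()` enumerates all $(N!)^I$ per-attribute order
  combinations with equal weight. Every in-scope design needs at most
  $(3!)^2 = 36$ combinations, so enumeration is the default everywhere
  and makes every reported surface deterministic and exactly
  reproducible.
* `mc_choice_probs()` samples order sets from a seeded generator, with
  `n_trials = 100000` by default. Two estimator modes are provided —
  averaging the per-trial softmax probabilities (default; lower
  variance) or tallying sampled discrete choices — because a "simulated
  trial" is ambiguous between the two readings. They share the same
  expectation, and the tests require agreement with enumeration within
  three standard errors at the canonical trial count.

Each simulated choice starts from the fresh prior
$(\mu_C, \sigma^2_C)$; there is no belief carry-over between trials of
an experiment, which treats trials as exchangeable repetitions.

## Experiment drivers and what they show

All drivers return long-format tables (one row per grid cell and metric)
and record method, trial count and seed. Grid defaults span all canonical
payoffs: prior means $[-6, 14]$ in steps of $0.5$ for the two-option
scan, third-option rewards $[0, 10]$, decoy grids $[1, 10]^2$, proximity
$d \in \{0, 0.5, \dots, 4\}$.

**Two-option scan** (`run_binary_scan()`): options with rewards 10 and 6.
The choice ratio $P[H]/P[L]$ is a bell-shaped function of $\mu_C$. By the
model's mirror symmetry (reflecting rewards and prior about the reward
midpoint swaps the options), the peak sits at $(R_H + R_L)/2 = 8$, which
enumeration confirms. Smaller $\sigma^2_R$ gives a taller peak *and* a
faster relative decay away from it — i.e. more precise reward beliefs
produce narrower, not wider, preference curves. The tests assert the
measured direction of this ordering rather than a verbal description,
since "width" without normalization is ambiguous.

**Third-option scan** (`run_trinary_scan()`): adding a third option with
reward $R_3$ modulates the ratio between the two targets as a U-shaped
function of $R_3$ with an interior minimum (near 8 under the defaults);
with $\sigma^2_R = 10$ the curve is nearly flat.

**Decoy grid** (`run_decoy_grid()`, `decoy_probe_effects()`): targets
$A = (1, 10)$ and $B = (10, 1)$ on price/quality, with a decoy $K$
ranging over the grid. The surface $P[A] - P[B]$ is exactly antisymmetric
under attribute swap (zero on the diagonal $R_{p,K} = R_{q,K}$). Under
enumeration at $\mu_C = 0$, $\sigma^2_R = 0.1$ the model places:

* *similarity-type* regions at decoys adjacent to a target in attribute
  space — a decoy near $A$, e.g. $K = (2, 9)$, **favours $A$**
  ($P[A]-P[B] \approx +0.038$), and symmetrically for $B$;
* *attraction-type* regions at decoys dominated by a target — a decoy
  dominated by $B$, e.g. $K = (5, 1)$, **favours $A$**
  ($\approx +0.027$), and symmetrically.

The prior mean arbitrates between the two effect types: at $\mu_C = -2$
the dominated-decoy (attraction-type) effect is several times the
adjacent-decoy effect, at $\mu_C = +2$ the ranking reverses; both
magnitudes shrink monotonically as $\sigma^2_R$ moves through
$\{0.1, 1, 10\}$, the attraction-type effect vanishing first. The probe
points $(2,9)/(9,2)$ and $(5,1)/(1,5)$ were fixed from the surface's
geometry (one probe per signed region, mirror pairs exact by symmetry)
and effect presence is read off as the sign, exactly for enumeration and
against $3\,\mathrm{SE}$ for Monte Carlo.

**Compromise design** (`run_compromise()`): extremes
$A = (5-d, 5+d)$, $B = (5+d, 5-d)$ and the intermediate $K = (5, 5)$.
In the binary control (K versus one extreme) the order-averaged value
differences come in exactly cancelling pairs, so
$P[K|A,K] - P[A|A,K]$ is *identically zero* — at machine precision under
enumeration, for every $d$, $\mu_C$ and $\sigma^2_R$. With both extremes
present, the preference for the intermediate option
$P[K|A,B,K] - P[A|A,B,K]$ is zero at $d = 0$ (three identical options)
and grows with $d$ to about $0.018$ at $d = 4$ under the canonical
parameters. Enumeration resolves a detail invisible at Monte-Carlo
resolution: the curve dips very slightly negative (magnitude below
$5 \times 10^{-4}$) around $d \approx 1$ before rising; the tests assert
strict growth from $d \ge 1$ and bound the dip rather than claiming
global monotonicity.

## Between-choice context: observations before the reward

When context is signalled before a reward arrives, the same machinery
applies with the contextual cue as the first observation. With a zero
prior mean, one contextual observation $O$ (noise $\sigma^2_O$) gives

$$V(R) = \frac{\hat\sigma^2_{C|O}}{\hat\sigma^2_{C|O} + \sigma^2_R}
         \left(R - \hat\mu_{C|O}\right),
  \qquad \hat\mu_{C|O} = \frac{\sigma^2_C}{\sigma^2_C + \sigma^2_O} O.$$

With two hierarchical context levels (e.g. restaurant within
neighbourhood), sequentially propagating the high- and low-level
observations $HO$ and $LO$ collapses to the closed form

$$V(R) = K\,(R - \tau_{LO} LO - \tau_{HO} HO),$$

with two subtractive weights and a divisive gain, all strictly in
$(0,1)$; at unit variances $\tau_{LO} = 0.6$, $\tau_{HO} = 0.2$,
$K = 0.375$. `hierarchical_value()` implements both the closed form and
the explicit step-by-step inference; they are algebraically identical and
the tests require agreement at $10^{-12}$. Two limits anchor intuition:
as $\sigma^2_{LO} \to 0$ the low-level context screens the reward off
from the high level ($\tau_{LO} \to 1$, $\tau_{HO} \to 0$ — a Markov
blanket), and as $\sigma^2_{HO} \to \infty$ the model collapses to the
single-level form (asserted numerically at $\sigma^2_{HO} = 10^8$ within
$10^{-6}$).

```{r hier}
hierarchical_factors(hierarchical_context_model())
hierarchical_value(HO = 2, LO = 4, R = 6, hierarchical_context_model())
```

## Scenario mapping

`scenario_predictions()` turns a block design — named contexts, each a
list of the rewards it can deliver — into incentive values. The design
itself does not dictate how a reward list becomes a contextual
observation, so the package adopts one explicit convention: the
observation ($O$, or $LO$ and $HO$ per level) is the arithmetic mean of
the context's rewards; the reward variance is the population variance of
the list, floored at 0.01 so single-valued contexts stay valid; and the
observation variances default to 1. Only *ordinal* comparisons of the
output are meaningful under this convention, and those are what the
canonical scenarios test:

* `scenario_mean_shift()` — contexts $\{x, x{+}1, x{+}2\}$ versus
  $\{x{+}1, x{+}2, x{+}3\}$: shared rewards are worth more in the
  lower-average context (subtractive normalization).
* `scenario_variance()` — $\{x, \dots, x{+}3\}$ versus
  $\{x{+}1, x{+}2\}$ with equal means: the low-variance context
  stretches the shared rewards' values apart (divisive normalization:
  smaller reward variance, larger gain).
* `scenario_two_level()` — low/medium-average sub-contexts inside a
  low-average super-context versus medium/high inside high: values fall
  as either level's average rises, extremes at low/low and high/high.

The base reward defaults to $x = -1.5$, centring the canonical lists on
the model's zero prior mean so that contexts straddle the prior
expectation. The mean-shift and two-level patterns are invariant to $x$;
the variance pattern requires the shared rewards to bracket the inferred
context mean (guaranteed when the lists straddle the prior), which is
why a symmetric base is the sensible default rather than a free dial.

```{r scenario}
scenario_predictions(scenario_variance())
```

## Numerical choices

* Softmax uses max-subtraction; probabilities sum to one within
  $10^{-12}$ even for extreme values.
* Deterministic assertions use absolute tolerance $10^{-10}$ or tighter;
  machine-precision claims (the compromise binary control, mirror
  antisymmetry) use $10^{-12}$; Monte-Carlo assertions use
  $3\,\mathrm{SE}$.
* The Monte-Carlo engine is vectorized over trials (the variance path is
  order-independent, so per-step gains are scalars); it is tested
  against the scalar single-trial evaluator.
* Seeding is scoped: `mc_choice_probs()` restores the caller's RNG
  state. Grid drivers derive distinct per-cell seeds by offsetting the
  configured seed so that cells are independent yet reproducible.
* Enumeration refuses problems above `enumeration_limit` (default
  10000 combinations) with an explicit pointer to the Monte-Carlo
  engine.

The test suite runs entirely on enumeration except where Monte-Carlo
behaviour is itself under test; those checks use 2000-20000 trials,
plus one check at the canonical 100000 trials. These sizes were chosen
to keep the full suite near-instant while leaving every Monte-Carlo
assertion at least three standard errors wide.

## What the simulations do and do not show

The drivers regenerate model predictions under idealized conditions:
exchangeable trials, fresh priors per choice, known parameters, exact
Gaussian assumptions. Passing tests therefore demonstrate internal
correctness of the implementation and the qualitative signatures the
model implies — not that human choice data exhibit them, nor anything
about parameter values that would fit such data. Known limitations of
the model itself: parameters are given, not learned; inference runs to
completion before a choice, so there is no account of reaction times or
premature commitment; and the scenario mapping from reward blocks to
contextual observations is a convention, so only ordinal scenario
predictions should be interpreted.
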