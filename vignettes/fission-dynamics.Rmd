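---
title: "Modelling irreversible group fission with dynamic grooming networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling irreversible group fission with dynamic grooming networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fissim)
```

## The question

Social groups split. In primates and other bonded species an irreversible
group fission — two daughter groups that never merge again — is typically
preceded by a period of fission–fusion dynamics in which the group forages
in temporary subgroups by day and reunites by night. `fissim` implements a
minimal individual-based model of that process: daily foraging decisions
are shaped by the grooming network, each temporary fission reshapes the
grooming network in turn, and the positive feedback between the two can
drive the group past a point of no return. The model asks how three
quantities — group size, the balance of nutritional versus social
motivation, and the strength of the daily network rewiring — govern the
number of days until the split becomes irreversible.

## State, parameters, and one simulated day

The state is a directed weighted network over `n` individuals: `w[i, k]`
is the percentage of `i`'s grooming-time budget spent on `k`. Rows sum to
100 at all times — grooming time is a budget, not an unbounded quantity —
and every simulation starts from the egalitarian network
`w[i, k] = 100/(n - 1)`, so structure can only *emerge*.

One day runs in three steps:

1. **Movement.** Everyone starts in a resting area; two foraging areas s1
   and s2 are available. While individual `i` rests, one movement draw
   sends it to area `s` with probability
   `p_s = lambda_s + C * sum(w[i, k])` over the individuals `k` already in
   `s`, and keeps it resting with the complementary probability. Draws are
   organised in rounds: each round visits the remaining resters in a fresh
   uniformly random order, and probabilities are recomputed after every
   single movement, so early movers pull later ones. The day's partition is
   fixed once the resting area is empty.
2. **Rewiring.** If both areas ended occupied (a *temporary fission*),
   every individual moves a fraction `T/100` of each grooming link that
   crosses the split onto its same-area companions, in equal shares. An
   individual alone in its area keeps its outgoing links unchanged (links
   toward it still decay); a day spent all together changes nothing.
3. **Criterion.** The fission is irreversible when both subgroups of the
   day's partition have at least `min_subgroup = 4` members (the departure
   of up to 3 animals is a dispersion, not a fission) and every individual
   now keeps at least `threshold = 95`% of its grooming time within its own
   subgroup. The criterion is evaluated after the day's rewiring, on the
   day's own partition: an irreversible fission is a property of a realised
   subgrouping *and* of the network it leaves behind. All individuals
   return to the resting area each night; a run that reaches `max_days =
   900` without an event is censored.

### Parameters

| parameter | meaning | units | default / range |
|-----------|---------|-------|-----------------|
| `n` | group size | individuals | 10 or 20 in the calibration grid |
| `lambda1`, `lambda2` | intrinsic (nutritional) movement probability toward s1, s2 | per draw | calibration pairs 0.05–0.45 |
| `C` | mimetic coefficient: probability gained per unit of link weight already in an area | per % of social time | 0.001–0.009 |
| `T` (`transfer`) | share of each cross-split link reallocated after a temporary fission | % | 10–100 |
| `threshold` | within-subgroup social-time concentration defining irreversibility | % | 95 (inclusive) |
| `min_subgroup` | smallest daughter group that counts as a fission | individuals | 4 |
| `max_days` | censoring horizon | days | 900 |

Since each row of the network sums to 100, the mimetic term is at most
`C * 100` and feasibility of the probabilities requires
`lambda1 + lambda2 <= 1 - C * 100`; the `condition()` constructor enforces
this. The single control `R = (lambda1 + lambda2)/(C * 100)` — the
Nutrition/Sociality ratio — summarises whether movement is need-driven
(`R` large) or cohesion-driven (`R` small). The calibration grid
(`standard_conditions()`) uses the nine symmetric pairs sitting exactly on
the feasibility boundary, spanning `R` from 0.11 to 9.

## Design choices

Several points are under-determined by the verbal description of such
models; the package fixes them as follows.

* **Order within a day**: move, then rewire, then test the criterion. The
  alternative (testing against the pre-rewiring network) makes full
  transfer (`T = 100`) require two consecutive identical partitions; we
  compared both and kept the former, under which a single day can complete
  a split that the network already supports.
* **Threshold comparisons** are inclusive (`>= 95`, `>= 4`), with a 1e-9
  floating-point allowance on the grooming sums.
* **Within a round**, resters are visited in a uniformly random
  permutation, re-sampled every round; a fixed order would bias the
  mimetic pull toward whoever happens to be early. Probabilities are
  recomputed after every single movement, making the process
  occupancy-sensitive within the round.
* **The mimetic sum uses the outgoing links** of the moving individual
  (what *i* invests in the occupants), not the incoming ones; with the
  egalitarian seed the two only diverge after rewiring.
* **`lambda` values are fixed per condition**, identical across
  individuals and days; heterogeneous daily needs are deliberately out of
  scope.
* **Dispersion-sized splits still rewire the network.** Only the fission
  *definition* excludes them; social time is redistributed on any
  temporary fission.
* **Seeding**: one seed per simulation drives every draw; batch replicate
  `r` of condition `c` uses a seed derived arithmetically from the batch
  base seed (`derive_seed()`), so any single run can be reproduced in
  isolation and batch results are independent of execution order. The
  compiled engine and the plain-R engine consume the random stream
  identically and are asserted equal in the test suite.

## Numerical behaviour

The transfer update is exactly conservative in exact arithmetic; in
floating point the row sums stay within ~1e-13 of 100 over hundreds of
days, well inside the 1e-9 invariant the package asserts (an optional
renormalisation was considered and rejected as unnecessary). Weights
cannot become negative for any `T` in [0, 100]. Repeated rewiring with a
*fixed* partition contracts each cross-split link geometrically by
`(1 - T/100)` per day, so within-subgroup sums converge monotonically to
100 — the `pre_clustered` test fixture exploits the closed form. Results
are written to CSV with 12 significant digits, enough to round-trip the
budget invariant. If `lambda1 + lambda2 = 0` and both areas are empty no
one can ever leave the resting area; a 10 000-round guard turns that
degenerate configuration into an informative error.

## What the simulations show — and what they do not

The sweeps shipped with the package (100 replicates per condition; the
full 9-ratio × 10-transfer grid at `n = 10` and the five lowest ratios at
`n = 20`; about a minute of CPU in total) exhibit:

* **No fission at weak transfer.** At `T` of 40% and below, no replicate
  of any calibration condition splits within 900 days; below ratio 1.5 the
  smallest fissioning transfer is 40–50% for groups of 10 and 60% for
  groups of 20.
* **Transfer brings fission forward.** Mean days-to-fission (censored runs
  capped at 900) falls with `T` at roughly −11 days per percentage point;
  the decline is, however, a fairly sharp threshold rather than a clean
  line (r² ≈ 0.79 for the 10-point regression), because the onset of any
  fission sits between `T = 50` and `T = 80` for most ratios.
* **A partial U in the ratio.** Among fissioning conditions, mid ratios
  (0.43–2.33) split fastest and high ratios (4, 9) take severalfold
  longer: independent movers produce nearly random daily partitions, so
  consistent subgroups — and hence 95% within-subgroup concentration —
  take a long time to accumulate.
* **Strong mimetism accelerates, not prevents, fission here.** At the
  lowest ratios (0.11, 0.25) daily partitions are cascade-driven and
  highly repeatable, so once a chance split occurs it reinforces itself
  and fission arrives at *lower* transfer percentages than for mid
  ratios. Likewise, larger groups take *longer* to fission at matched
  conditions (all 20 individuals must concentrate 95% of their budget),
  so the Poisson-regression coefficient of group size on days is positive
  in this implementation. Accounts of highly cohesive wild groups that
  never split, and of larger groups splitting sooner, are *not* reproduced
  by these dynamics: winner-take-all unanimity at high mimetism would
  require the per-draw defection probability toward an empty area to be
  orders of magnitude below `lambda`, which the movement rule as specified
  does not deliver. Readers should treat the low-ratio regime of this
  model as a distinct dynamical hypothesis, not as a calibrated
  description of cohesive groups.

The model is synthetic throughout: an egalitarian seed network (real
grooming networks are heterogeneous, Erdős–Rényi- or scale-free-like),
exactly two foraging patches with no quality or competition terms, a
single group-wide transfer percentage, and one potential temporary fission
per day. Passing tests therefore establish internal correctness and the
parameter dependencies above — not field realism. Obvious extensions
(empirical seed networks via `read_network()`, per-dyad transfer rates,
more than two patches) are left out of scope; the import interface is the
designed entry point for the first of these.

## Statistical toolkit

`summarize_batch()` reduces a batch to per-condition mean/min/max days and
fission fraction under an explicit censoring policy (`exclude` or
`cap_at_max`). `transfer_linearity()` is the OLS of mean days on `T`
(F on 1 and levels−2 df). `ratio_groups()` runs Kruskal–Wallis across
ratio levels, then Dunn's pairwise z-tests with the usual tie correction —
unadjusted by default, with Bonferroni/Holm options — and partitions the
levels into homogeneity groups by transitive non-significance at
`alpha = 0.05`; the 10%-transfer cells, where nothing ever fissions, are
excluded by default. `poisson_covariate_model()` fits the log-link Poisson
GLM of days on group size, transfer and ratio (ratio numeric by default,
categorical on request since the response is not monotone in it).
`survival_curves()` returns per-condition Kaplan–Meier estimates with
censoring at the 900-day cap. Runs with an event between 90 and 900 days
carry a `viable` flag — the window in which wild fissions are typically
observed — as a classification, never as a stopping rule.
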