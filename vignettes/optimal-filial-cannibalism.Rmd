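---
title: "A cohort model of optimal filial cannibalism in a territorial predator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cohort model of optimal filial cannibalism in a territorial predator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannfor)
```

## The question

Females of the damsel bug *Nabis pseudoferus* are strictly territorial
predators that readily eat their own nymphs. Because territoriality removes
the competitive motive for cannibalism (the only conspecifics a female
meets are her own offspring), filial cannibalism in this species is a pure
feeding decision, and one can ask whether it is an *optimal foraging
strategy*. The answer depends on what "optimal" maximizes:

* **Life reproductive success `X`** — the total number of adult daughters a
  female sends out of her territory over her own reproductive life.
* **Reproductive-season growth rate `Z`** — the number of descendants her
  lineage accumulates by the end of one reproductive season, counting
  granddaughters, great-granddaughters and so on.

Eating a nymph converts offspring biomass back into eggs quickly, which can
raise `X`. But it also (a) delays the lineage, because the eggs bought with
the nymph's biomass start reproducing later than the nymph would have, and
(b) deletes every descendant the nymph would have produced for the rest of
the season. `cannfor` implements the cohort model that quantifies this
trade-off and optimises both fitness functionals over the female's prey
preference.

## The model

### Time, cohorts and the territory recursion

Time advances in units of `unit_days` (5 days). A female forages
`activity_minutes` (4800 min = 16 h/day) per unit. Offspring pass through
six cohorts: two egg units, three cannibalizable nymph cohorts (first/second
instars, third/fourth instars, fifth instars; one unit each), and one
migration unit for the matured daughter. Only the three nymph cohorts can
be cannibalized — an egg cannot be attacked before it hatches 10 days after
laying, and matured daughters leave.

The focal female reproduces for `reproductive_units` = 7 units (35 days,
matching the measured oviposition span of conspecific-fed females) and then
dies. Each step while she is alive:

1. she forages on the nymph cohorts present plus the constant
   heterospecific availability (functional response below);
2. consumed nymphs are removed from their cohorts;
3. the consumption is converted into this step's newly hatched nymph
   production `e(t)` (numerical response);
4. all cohorts advance one stage; cohorts reaching full development leave
   as adult daughters `a(tau)`.

After her death the remaining cohorts develop and leave unharmed. The model
is deterministic: cohort counts are expected values, not integers.

### Functional response

The phenotype is the prey-preference pair `(p_a, p_b)`: the probability of
attacking an encountered conspecific nymph / heterospecific prey. Foraging
is a renewal process of encounter cycles. One search costs `tau_s` minutes
and finds one prey item, drawn by relative abundance from the `x + y` items
in the territory (`x` = nymphs present, `y` = heterospecific availability,
held constant — the prey standing crop is assumed to be replenished).
An attacked conspecific costs handling time `tau_a` whether or not the
attack succeeds (success probability `k3`, `k4`, `k5` falls with nymph
size); an attacked heterospecific costs `tau_b` and always succeeds. The
expected cycle length is therefore

```
C(x) = tau_s + [x p_a tau_a + y p_b tau_b] / (x + y)
```

and instantaneous consumption rates are `p_a k_i c_i / ((x+y) C)` for nymph
cohort `i` and `p_b y / ((x+y) C)` for heterospecific prey. Because a
female can eat a sizable fraction of a cohort within one 4800-minute step,
the rates are not evaluated once per step: the cohorts are depleted
continuously, by integrating this system over the activity window
(classical fixed-step RK4; see *Numerical choices*). Two design points here
were genuinely open, and we fixed them as the package's own
reconstruction, cross-checked against the printed optima of both published
parameter sets (see *Accuracy*): handling is paid per attack rather than
per successful capture, and within-step depletion is continuous rather
than absent or discretised per day. The alternative conventions shift the
optimal cannibalism rate by several grid points and are not compatible
with both parameter sets at once.

The numerical response converts consumption into newly hatched nymphs with
the measured coefficients: `a3`, `a4`, `a5` hatched nymphs per consumed
cohort-3/4/5 nymph and `b` per heterospecific prey. All hatched nymphs are
treated as daughters (males are assumed never limiting), and the only
mortality in the model is maternal cannibalism.

### Fitness definitions

`X` is the row sum of departures: `X = sum(a(tau))` — equivalently
everything hatched minus everything eaten. The alternative convention
(counting hatched nymphs `sum(e(tau))`) is incompatible with the printed
maxima of both canonical parameter sets, so departures it is.

`Z` is computed by a renewal recursion over the descendants tree. Every
female of the lineage has the same phenotype and an identical territory
environment, so each founder repeats the same production schedule
time-shifted. A daughter laid at maternal age `tau` leaves 5 units after
laying and founds her own territory one migration unit later, giving the
founder recursion

```
f(t) = sum_tau a(tau) * f(t - tau - 5),   f(1) = 1 (Eve).
```

`Z` counts the nodes of the descendants tree: every descendant female that
has established her own territory by the end of the `season_units` = 50
unit (250 day) season, Eve herself excluded. Among the counting conventions
we examined (all individuals alive in any stage at season end; individuals
ever born; established females), the established-females convention is the
one consistent with the printed season totals, and it is also the natural
reading of the descendants *tree*: each node of the tree is a female with
her own territory. The renewal shortcut is enforced against a brute-force
generation-by-generation expansion of the tree in the test suite (relative
tolerance 1e-9).

### Optimisation

`fitness_surface()` sweeps either functional on a uniform
`grid_n x grid_n` grid over `[0,1]^2`, default `grid_n = 100`, i.e. grid
points `i/99`. The published optima are rational numbers on exactly this
grid (`0.1717 = 17/99`, `0.6667 = 66/99`, `0.3232 = 32/99`,
`0.9798 = 97/99`), which is why exhaustive grid search, not a gradient
method, is the default: the surfaces need not be concave, the grid cost is
trivial (about one minute per surface on one CPU), and the optimum is
reported on the conventional grid. Ties are broken towards the smallest
`p_a`, then the smallest `p_b`.

## Parameters

| symbol | meaning | unit | laboratory value |
|---|---|---|---|
| `y` | heterospecific prey availability per territory | count | 16.8 |
| `b` | hatched nymphs per consumed heterospecific prey | – | 0.44 |
| `tau_a` | conspecific handling time | min | 23.3 |
| `tau_b` | heterospecific handling time | min | 16.6 |
| `tau_s` | search time per encounter | min | 5.3 |
| `k3,k4,k5` | attack success on nymph cohorts | prob. | 1.00, 0.80, 0.55 |
| `a3,a4,a5` | hatched nymphs per consumed nymph | – | 0.91, 3.00, 6.14 |

The same symbols appear in the literature both as `Y`/`y` and as
`kappa_i`/`k_i`; the package treats each pair as one quantity. The
illustrative set (`illustrative_parameters()`) makes conspecifics the more
valuable food (`a = (2, 6, 11)`, `b = 0.04`, cheap `tau_a = 5`), the regime
where partial cannibalism is optimal under *both* fitness definitions.

## Synthetic scenarios and the stochastic oracle

`random_parameters(seed)` draws structurally valid parameter sets —
positive densities and times, `k3 >= k4 >= k5` (larger nymphs escape more)
and `a3 <= a4 <= a5` (larger nymphs carry more biomass) — for
property-based testing. The defaults emulate the magnitude of the
laboratory values (`y` in 1–50, times in 1–120 min); they are sampling
bounds for tests, not biological estimates.

`stochastic_oracle()` is an individual-based re-implementation of the same
biology with none of the deterministic machinery: integer nymph counts,
stochastic renewal foraging (exponential cycle durations, Bernoulli-thinned
attacks and successes, simulated exactly via the consumption-event
skeleton) and integer offspring whose expectation equals the conversion
arithmetic. The deterministic recursion is the expected-value skeleton of
this jump process: in regimes where the process is linear in the state (no
cannibalism, so consumption does not feed back on prey counts) ensemble
means agree exactly; with cannibalism the agreement holds to the usual
fluid-limit accuracy of order one over the cohort size. Test scenarios are
therefore run at reduced activity time, where both effects are within the
Monte-Carlo resolution of 1e4 replicates. Passing these tests shows the
recursion correctly averages the assumed individual-level process; it says
nothing about how well that process describes real territories
(temperature-dependent development, prey depletion, winter survival and
non-cannibalism mortality are all outside the model).

## Numerical choices

* **Within-step integration** — fixed-step RK4 with `steps = 16` substeps
  over the activity window; the per-step production is converged to about
  1e-7 relative (doubling to 200 substeps changes nothing in the sixth
  decimal). Fixed-step keeps grid sweeps bit-reproducible.
* **Degenerate inputs** — zero preferences, zero availability or zero time
  short-circuit to zero consumption; cohort counts are clamped at zero and
  consumption can never exceed availability (the ODE depletes smoothly, so
  the clamp only guards round-off).
* **Tie-breaks** — the grid scan visits `p_a` ascending, `p_b` ascending,
  and replaces the incumbent only on a strict improvement, so the reported
  argmax of a flat surface is the smallest coordinate pair.
* **Problem sizes** — the default analyses are desk-scale: a 100 x 100
  sweep evaluates 1e4 schedules of 12 steps each; property tests use 20
  random scenarios, seasons of 8–20 units for the brute-force tree, and
  1e4 oracle replicates.

## Accuracy of the reconstruction

The exact algebra of the published functional response was not available
to us, so the open conventions above were fixed by requiring the model to
reproduce the printed optima of both canonical parameter sets. With those
choices the four published maximizing grid points are reproduced exactly
(`p_a` = 17/99 and 0 for the laboratory set, 66/99 and 32/99 for the
illustrative set), and the published surface maxima are matched to within
about 1% for `X` and about 2.5% for `Z` (the season total compounds the
per-step residual over ~44 steps). The heterospecific coordinate of the
illustrative `Z` optimum lands at 1.0 versus the published 97/99 — the
surface is nearly flat in `p_b` there. The residuals are frozen as
tolerances in the acceptance tests; we deliberately did not tune further.

## Limitations

* No temperature-dependent development, activity or lifespan.
* The heterospecific standing crop is constant: no prey depletion across
  steps and no feedback between neighbouring territories.
* No mortality other than cannibalism (migration survival is 1), no males,
  no winter stage, no egg cannibalism.
* The stochastic oracle is a test instrument at desk scale, not a
  research-grade individual-based model.
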