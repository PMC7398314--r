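---
title: "Methods: a Markov cohort model for post-mastectomy radiotherapy cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for post-mastectomy radiotherapy cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmrtcea)
```

## The decision problem

After mastectomy for locally advanced breast cancer, chest-wall and nodal
irradiation (post-mastectomy radiotherapy, PMRT) improves survival but
exposes the heart, the lungs and the contralateral breast to radiation.
Advanced delivery techniques (IMRT, several VMAT variants, tomotherapy, a
mixed electron/photon technique, and intensity-modulated proton therapy)
reduce those incidental doses at a higher treatment price. `pmrtcea`
implements a Markov cohort model that weighs the up-front cost of each
technique against the downstream costs and quality-of-life losses of late
radiogenic side effects, from a payer perspective.

A hypothetical cohort of 55-year-old women enters the model in the
no-evidence-of-disease (NED) state immediately after treatment and is
propagated through annual cycles over a 15-year horizon. The states are

* `ned` — well after treatment;
* `local_recurrence`, `metastasis` — tumour-control failures, identical
  across techniques (all techniques are assumed to control the tumour
  equally well; they differ only in late toxicity);
* `cardiac`, `cl_breast`, `lung` — late radiogenic side-effect states
  (cardiac toxicity, contralateral breast cancer, radiogenic lung cancer);
* `death_cancer`, `death_other`, `death_toxicity` — absorbing death
  states, split by attributed cause so that the survival validation can be
  decomposed.

Each strategy is summarised by its radiotherapy course cost and the total
probabilities of the three late effects over their event windows: cardiac
and lung events occur in cycles 11–15, contralateral breast events in
cycles 6–15. Everything else — disease transitions, background mortality,
toxicity-specific mortality, utilities and event costs — is shared.

## Annualisation of published band probabilities

Published transition probabilities are totals over multi-year windows
("6.5% over years 0–5"). The model converts each band to a per-cycle
probability by dividing the total by the number of years in the band
(`period_cumulative` convention). Two row families deserve comment:

* **Metastasis to death** (25.9% in the first band, 15.6% thereafter) is
  treated as an **annual** probability. These figures derive from annual
  breast-cancer mortality rates, and reading them as window totals drives
  15-year breast-cancer mortality far below every published estimate for
  this cohort; the annual reading reproduces the ~19% mortality benchmark.
  The convention is stored per band in the parameter file, so either
  reading can be run (`--met-death-convention` in the CLI).
* **Year labels.** "Years 0–5" maps to cycles 1–5, "6–10" to 6–10,
  "11–15" to 11–15: a 15-cycle horizon admits no year-0 event, and the
  bands then tile the horizon exactly. Normal-death age bands
  (56–60/61–65/66–70 for the age-55 cohort) map onto the same cycles.

Annualisation is homogeneous (scaling a band value scales the per-cycle
probability) and invariant under band splitting; both are property-tested.

## Transition structure and competing risks

The NED row carries all incidence exits plus background mortality, with the
complement remaining in NED. Competing risks within a cycle are additive:
per-cycle probabilities are subtracted from the stay probability directly,
with no rate-to-probability conversion. Published per-cycle probabilities
are small (at most ~26%/cycle), the source estimates are themselves
probabilities rather than rates, and feasibility is checked every cycle —
a row whose exits exceed 1 raises an error naming the row and cycle.

Two topology choices were genuinely open:

* **Local recurrence.** The model's default keeps local-recurrence
  occupants subject to background mortality only
  (`recurrence_progression = FALSE`). The alternative — progression to
  metastasis at the NED→metastasis schedule — is available as a toggle.
  Calibration decided the default: with progression on, the model predicts
  68.3% 15-year overall survival and 20.1% breast-cancer mortality; with it
  off, 69.1% and 19.3%, matching the published validation benchmarks
  (69.7% and 19.2%) to well within one percentage point.
* **Toxicity states are reachable only from NED.** Recurrent or metastatic
  patients do not additionally acquire toxicity states; the states remain a
  mutually exclusive partition, and toxicity incidence among the small
  recurrent fraction is second order.

Deaths are attributed by the transition taken: through metastasis to
`death_cancer`, through a toxicity-death row to `death_toxicity`, through
background mortality to `death_other`.

No half-cycle correction is applied by default — state membership is
valued at cycle end — because the published model gives no indication of
one; a `half_cycle` toggle averages start- and end-of-cycle occupancy for
readers who prefer it. The toxicity-specific death rows (0.49%, 2.6%,
21.7% over cycles 11–15) default to the period-cumulative reading like
every other incidence row; occupancy of the toxicity states is small, so
this choice has little leverage.

## Rewards

QALYs accumulate as
$\sum_{t=1}^{15} (1+r)^{-t} \sum_s \pi_t(s)\, u(s)$
with $r = 3\%$ per year, $u(\mathrm{NED}) = 1$, published utilities for the
other alive states, and 0 for the dead states. The NED utility is not
published; 1.0 is the standard convention for a well state and anchors the
QALY scale. In the no-event limit the QALY equals the discounted annuity
$\sum_{t=1}^{15} 1.03^{-t} = 11.9379$, a closed form the tests pin down.

Costs book the radiotherapy course at cycle 0 undiscounted (treatment
precedes the first cycle) and charge each clinical event **once, at the
discounted cycle of state entry**. Annual charging is not defensible here:
the published cost margin between the reference strategy's total cost and
its course cost is a few thousand dollars, an order of magnitude below what
annual charging of recurrence and metastasis treatment would produce.

## Frontier analysis

Strategies are sorted by ascending cost; a strategy is dominated when
another costs no more and yields no fewer QALYs (one inequality strict).
ICERs are reported between consecutive non-dominated strategies. The
pairwise scan is quadratic and is verified in the test suite against an
independently coded brute-force oracle over a thousand random strategy
sets. An extended-dominance pass (removing strategies whose ICER exceeds
that of the next, more effective frontier member) is implemented but off by
default — strict dominance suffices for the bundled data. Display rounding
is dollars to the nearest dollar and QALYs to three decimals; JSON exports
keep full precision.

## Sensitivity analyses

**One-way (tornado).** For each technique, the nine quantities with
published ranges — the technique's three late-effect probabilities and the
shared utilities and event costs of the three late effects — are set to
their low and high bounds one at a time, the full model is rerun for the
technique and for SOC, and the ICER versus SOC is recorded. Bars are
sorted by width. The comparator is always SOC.

**Probabilistic (PSA).** Probabilities and utilities are drawn from beta
distributions and costs from gamma distributions, parameterised by the
method of moments with mean equal to the base value and standard deviation
`(high − low) / 4` — the published ranges are read as approximate 95%
intervals, the most common convention in health-economic modelling; the
rule is isolated in `build_distributions()` for easy substitution.
Parameters without published ranges are held fixed: that includes the
disease transitions (the source analysis states recurrence and metastasis
uncertainties were excluded), the reference strategy's toxicity
probabilities, and the course costs. Shared quantities are drawn once per
iteration and applied to every strategy; technique-specific probabilities
are drawn independently per technique. Acceptability curves report, per
willingness-to-pay threshold $\lambda$, the fraction of iterations in which
$\lambda \cdot \mathrm{QALY} - \mathrm{cost}$ exceeds the reference
strategy's.

Draws are generated as a $K \times n$ uniform matrix filled column-major
and pushed through quantile functions, so each iteration consumes a fixed
RNG substream: results are bit-reproducible under a fixed seed, and
enlarging the iteration count leaves earlier iterations' draws unchanged.
Draws that would make a transition row infeasible are rejected and redrawn
(the count is reported; with the bundled ranges it is zero). The PSA runs
through a vectorised re-implementation of the cohort engine that propagates
all draws simultaneously; the tests pin it to the scalar engine to
$10^{-10}$ on perturbed parameter sets. A full 100,000-iteration PSA over
eight strategies takes a few seconds on one CPU.

## The synthetic generator

`random_parameter_set()` emulates the structure of the bundled set — three
5-year disease and mortality bands, late-effect windows 11–15 and 6–15,
ranged utilities, costs and technique probabilities — with magnitudes drawn
small enough that every transition row is feasible by construction, so
fuzz tests never stall on rejection. It reproduces structural validity,
not realistic epidemiology: random sets exercise conservation, frontier
and I/O code paths, and say nothing about clinical plausibility.
`degenerate_scenarios()` provides named fixtures with closed-form outcomes
(annuity QALYs, product-form survival, a hand-computable two-strategy ICER,
a forced transition).

## Calibration results and known limitations

With the conventions above, the bundled parameter set reproduces the
published validation outputs: 69.1% 15-year overall survival and 19.3%
breast-cancer mortality against the published 69.7% and 19.2%.

The published per-technique cost and QALY levels, however, are **not
reproducible from the published inputs**, and users comparing this model's
absolute base-case table against the original report should expect
systematic differences:

* The published QALY gaps between techniques (for example 0.19 between the
  reference strategy and IMRT, or 0.04 between two VMAT variants whose
  late-effect probabilities differ by less than 0.1 percentage points) are
  one to two orders of magnitude larger than the maximum effect the
  published toxicity probabilities can exert through utility decrements
  and toxicity-specific mortality. Bounding the effect is elementary: a
  technique's late effects shift at most ~10% of the cohort (reference
  strategy) or ~1.5% (advanced techniques) into states whose utilities are
  0.72–0.85, for at most 10 discounted years.
* The published cost column implies the proton-therapy strategy accrues
  *more* event cost than the reference strategy despite strictly lower
  late-effect probabilities and an identical disease backbone, which no
  assignment of event costs to state entries can produce.
* Reproducing a QALY gap of 0.19 via stronger toxicity conventions (annual
  rather than period-cumulative late-effect incidence and mortality) drives
  15-year overall survival to ~65%, contradicting the published validation
  benchmark. The published QALY gaps and the published survival cannot
  both be generated by this state structure under any band convention we
  explored.

Consequences: full-precision ICERs of the advanced techniques versus the
reference strategy computed by this model are far larger than the published
ones (the QALY denominators are smaller), and the probabilistic
acceptability of the advanced techniques at conventional thresholds is near
zero rather than substantial, because the deterministic incremental net
benefit is negative and the published ranges give it little spread.
Within the model, relative orderings remain informative: the
proton-therapy strategy has the lowest late-effect burden of all
strategies, and among the technique-specific probabilities the cardiac one
carries the widest tornado bars for the photon techniques.

Other limitations are structural: no individual-level simulation (cohort
fractions only), no societal-perspective costing, no inflation indexing
beyond the 3% discount, tumour control assumed identical across
techniques, and a single age cohort.

## Problem sizes used by the test suite

The suite runs the full eight-strategy base case, tornado sweeps for all
seven advanced techniques, a 100,000-iteration PSA for the acceptability
summary, a 1,000-set frontier fuzz against the brute-force oracle, and
60 random parameter sets through the whole pipeline; the complete run takes
on the order of a minute on one CPU.
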