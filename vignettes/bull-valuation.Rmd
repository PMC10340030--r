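---
title: "Valuing dairy AI bulls: the herd model, the NPV engine, and its conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing dairy AI bulls: the herd model, the NPV engine, and its conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bullval)
```

## The decision problem

An artificial-insemination (AI) company keeps a stud of a few hundred
bulls, collects semen several times a week, packs it into straws and
sells it worldwide. Deciding *when to replace a bull* is genuinely hard:
a bull's revenue depends jointly on its age (production rises to a
mid-life plateau and declines), its semen output relative to herd mates,
its genetic merit (lifetime net merit, NM\$, which drives what buyers
will pay), and on which markets its straws are sold into. `bullval`
makes that decision objective: it computes the discounted net present
value (NPV) of keeping each bull, subtracts the NPV of a reference young
replacement sire, and flags bulls whose relative value —
`bullval = NPV(bull) − NPV(replacement)` — is negative.

## The herd as an age-binned Markov chain

Ages from 10 to 85 months are divided into 19 bins of 4 months — one bin
per round of replacement decisions, three per year. The only transition
out of a bin is involuntary culling (death, injury, illness) with a
per-bin probability `cull_b`; survivors advance one bin per iteration,
and any bull reaching the end of bin 19 is culled by assumption. Under
constant-herd regeneration every exit is replaced by a young bull
entering bin 1 in the same iteration:

    state[b+1] <- state[b] * (1 - cull[b])
    state[1]   <- sum(state * cull)

so total mass is conserved exactly. The steady state of this chain has a
closed form: occupancy is proportional to the cumulative survival
weights `w_b = prod_{a<b}(1 - cull_a)`, normalized
(`steady_state_closed_form()`). The iterative solver
(`steady_state_iterative()`) exists both as the conventional simulation
route and as a cross-check; the two agree to at least 1e-9 on every
schedule we generate, and the fixed point is independent of the starting
distribution. Convergence is declared when the max-norm change between
successive iterations falls below `tol` (default 1e-12) — we expose the
tolerance and report the iteration count rather than fixing a canonical
number of iterations, because the "right" number depends entirely on the
criterion chosen.

With the packaged culling schedule and a 396-bull stud this gives 23
bulls in the youngest bin and 16 in the oldest:

```{r}
s <- default_schedule()
scale_to_herd(steady_state_closed_form(s), 396)$counts
```

Counts are rounded half-away-from-zero because studs report whole bulls.

## The economic engine

Per iteration `i` and bin `b`, four cash flows are weighted by the
occupancy `state[b]` and the discount factor:

* **Semen income** `Si = (1 + pdev) * sum_mkt PU * MS * U`, with `U` the
  straw units produced (bin mean TSp / packing rate), `PU` the price per
  straw for the bin's age class and the bull's NM decile in each market,
  and `MS` the market's share of units at that age. `pdev` is the bull's
  fractional deviation from mean TSp, so income is exactly linear in
  `(1 + pdev)` and in every price cell.
* **Maintenance** `Mc` per occupied bin (feeding, housing, veterinary).
* **Culling cost**: on involuntary exit the stud buys a replacement
  (`CR`) and realizes the remaining linear depreciation of the insured
  value (full value at arrival age, zero at the end of the term, clamped
  outside). Age classes for pricing partition the bins as young (1–4),
  in-waiting (5–12) and proven (13–19); bin 12 is assigned to in-waiting
  so the classes tile the bins. Depreciation within a bin is evaluated
  at the bin's starting month.
* **Culling income**: salvage value times the culled proportion.

`npv()` propagates the chain from the bull's starting bin and
accumulates each component; the reported `npv` equals
`semen_income − maintenance − culling_cost + culling_income` by
construction, and the whole aggregation is verified against an
independent brute-force oracle that enumerates every cull/survive path
on small schedules.

## Numerical conventions, and how the defaults were chosen

Three aspects of the aggregation admit more than one defensible reading,
so all are explicit configuration:

1. **Discount basis** — the stated interest rate (6%/year in the base
   economics) can be applied directly as the per-iteration rate, or
   converted to the equivalent 4-month rate `(1+r)^(1/3) − 1`.
2. **Discount exponent offset** — the factor for iteration `i` is
   `1/(1+rate)^(i+offset)` with `offset ∈ {−1, 0, 1}`; offset −1 leaves
   the first iteration undiscounted.
3. **Culling-cost grouping** — `cull × (CR + Depr)` charges the
   replacement purchase only on actual exits; the alternative
   `CR + cull × Depr` charges it every occupied iteration. We consider
   the first economically sensible (an unconditional 10,000 USD charge
   per 4-month bin would dwarf every other cost), but both are
   implemented.
4. **Regeneration inside the NPV** — follow only the bull's own
   trajectory, or keep the constant-herd chain running so each exit is
   succeeded by an identical young profile.
5. **Maintenance basis** — 900 USD/month × 4 = 3600 USD per bin, or
   30 USD/day × 365/3 ≈ 3650.

Rather than guessing, `calibrate_npv_convention()` evaluates the
cost-side decomposition of the reference replacement bull under all 48
combinations and selects the one matching a reference decomposition with
the smallest worst-case relative error. Against the case-study
decomposition published for the commercial stud (maintenance 63,600 USD,
culling cost 7,264 USD, culling income 532 USD over 330 iterations) the
winner — and hence the packaged default — is: per-iteration discounting
at the stated rate, exponent offset −1, regeneration on, grouping
`cull × (CR + Depr)`, maintenance 3600 USD/bin. Its residuals are 0.00%
on maintenance (the match is exact:
`3600 × Σ_{k=0}^{329} 1.06^{−k} = 63,600`), +1.5% on culling cost and
−0.07% on culling income. No other combination comes close (the
runner-up misses by >5%). Notably, a convention with the exponent
`(i+1)` — the form one would write down first — underestimates
maintenance by 11%, which is why the offset is configurable at all.

```{r}
cal <- calibrate_npv_convention(
  c(maintenance = 63600, culling_cost = 7264, culling_income = 532),
  default_schedule())
cal$components
cal$max_rel_error
```

The full NPV and the semen-income component of the published case study
are *not* reproducible from packaged data: they require the proprietary
market-share distributions, which are only available as box plots in the
original appendix. `npv()` therefore accepts `prices = NULL` /
`shares = NULL` for cost-side analyses, and the calibration uses only
the three price-free components.

## Empirical Bayes price smoothing

Export sales are recorded per *order*, and an order often blends straws
of several bulls at one blended price, diluting bull-level price
differences. Prices are therefore estimated per
(market × age class × NM decile) group and shrunk toward the market mean
with weight `beta_i = tau² / (tau² + se_i²)`: well-measured groups keep
their mean; sparse groups (elite bulls sold in few, heavily blended
orders) are pulled to the market average. Choices a user can change:

* `tau²` defaults to the sample variance of the group means within the
  market (method of moments); the variance of all prices is available as
  an alternative.
* Singleton groups would get `se² = 0` and spuriously keep their single
  observed price; they instead take the market-wide price variance
  (maximal uncertainty) and are flagged `low_information`.
* Outlier orders beyond 3 IQRs from the market median are dropped before
  estimation (configurable).
* Grid cells with no sales at all take the market mean.

Market shares are estimated as unit fractions per age bin; records
lacking a bin attribution spread their units uniformly over their age
class's bins, and empty bins inherit the nearest populated bin's shares.

## The valuation pipeline

`value_herd()` reads a herd table, derives what is missing (age bin from
age in months; NM decile from the herd's own NM\$ distribution,
lower-inclusive deciles with the top bin open above; `pdev` from the
last ≤3 collection months via `compute_pdev()`), values every bull
against the replacement, ranks descending (ties broken by bull id for
determinism) and flags `bullval < 0` for culling. Per-bull failures are
collected and reported without aborting the herd. Bulls without any
production record take `pdev = 0` with a warning — young genomic bulls
routinely have no collection history yet, and average production is the
neutral assumption. Collection histories are monthly, so the expected
monthly output is the 4-month bin mean divided by 4; deviations are
relative, so this constant affects nothing downstream.
`summarize_by_nm_bin()` reproduces the standard per-decile reporting
(counts, mean/SD of deviation in %, mean/SD of value), and
`summarize_total()` recovers herd-level averages from a bin-level
summary alone — the arithmetic that ties published per-decile tables to
their totals.

## Synthetic data: what it does and does not emulate

Proprietary company data cannot ship, so `generate_herd()` and
`generate_sales()` produce seeded data with known ground truth:

* ages drawn from the steady-state distribution (defaults) with NM\$
  declining in age (younger bulls carry higher merit), NM residual SD
  100 USD;
* true TSp deviations `N(0, 0.30)` — matching the ~30% deviation SD
  observed in the case-study herd — with multiplicative lognormal
  monthly noise (sdlog 0.10; keeps production positive). The lognormal
  mean `exp(σ²/2) ≈ 1.005` leaves a ≈ +0.005 bias in recovered
  deviations, well inside the ±0.01 band we test;
* sales orders blending several (age class × NM bin) groups at a
  unit-weighted blended price plus truncated Gaussian noise, so the
  estimator faces exactly the dilution problem described above.

What the generators do *not* emulate: real studs' non-stationary
demographics (the case-study herd was far from steady state at entry),
price seasonality and contract pricing, correlated health events, and
NM re-ranking as genomic predictions mature. Passing recovery tests
therefore demonstrates estimator correctness under the stated model, not
performance on any particular company's books.

Problem sizes used in the shipped tests were chosen to make the
statistical checks sharp while staying quick: coverage of the shrinkage
estimator is assessed over ~720 well-populated groups of ~200 unblended
records (a 2-standard-error interval has nominal coverage just above
95%, so the observed proportion is tested with a one-sided exact
binomial test at the 95% level instead of a raw point comparison that
would fail on sampling noise alone), and deviation-estimator bias over
1,000 bulls.

## Degenerate inputs and tie-breaks

* A herd state with no mass is rejected; full-turnover schedules
  (cull = 1 everywhere) are valid and keep all mass in bin 1.
* `beta` is defined as 1 when `tau²` and `se²` are both zero (an exact
  group in a homogeneous market keeps its mean).
* An all-equal NM\$ reference makes every decile boundary coincide; all
  bulls land in one bin and a warning is emitted.
* Depreciation with `arrival_age ≥ term` is a configuration error;
  evaluation before arrival clamps to the full value, after the term to
  zero.
* Ranking ties are broken by bull id; report files are byte-identical
  for identical inputs.

## Known limitations

* Culling probabilities are treated as exact transition parameters;
  no uncertainty in the schedule is propagated into the valuation.
* Semen income assumes the full production of every bin is sold at the
  smoothed prices; inventory carry-over and unsold stock are not
  modeled.
* The replacement comparison uses one fixed reference profile; changing
  it shifts every `bullval` by a constant and leaves the ranking intact,
  but the cull threshold (zero) moves with it.
* With regeneration inside the NPV, successors inherit the bull's own
  NM bin and deviation; a more refined model would let successors revert
  to herd-average profiles.
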