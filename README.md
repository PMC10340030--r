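# bullval

Decision support for bull replacement at dairy artificial-insemination
(AI) studs.

AI companies must regularly decide which semen-producing bulls to keep
and which to replace with young, genetically superior candidates. The
decision couples demography (how long a bull is likely to stay in the
herd), production (total sperm output relative to herd mates of the same
age), genetics (lifetime net merit, NM$, which drives straw prices) and
markets (where the straws are sold, at what price). `bullval` makes the
decision objective:

* the stud is an **age-binned Markov chain**: 19 four-month bins
  spanning 10–85 months, per-bin involuntary-culling probabilities
  `cull_b` as the only exits, survivors advancing one bin per iteration,
  and constant-herd regeneration routing every exit into bin 1. The
  steady state has the closed form
  `pi_b ∝ w_b = prod_{a<b}(1 − cull_a)`;
* a **discounted NPV engine** aggregates, over 330 four-month
  iterations, the occupancy-weighted cash flows
  `Si − Mc − Cc + Ci` — semen income
  `Si = (1+Pdev) · Σ_mkt PU·MS·U`, maintenance `Mc`, culling cost
  `Cc = cull·(CR + Depr)` with linear depreciation of the insured value,
  and culling income `Ci = SV·cull` — each discounted by
  `1/(1+rate)^(i+offset)`;
* blended order-level sales prices are smoothed per
  (market × age class × NM decile) by **empirical Bayes shrinkage**
  `shrunk_i = beta_i·x̄_i + (1−beta_i)·mu` with
  `beta_i = tau²/(tau² + se_i²)`;
* every bull is valued against a reference young replacement
  (`bullval = NPV(bull) − NPV(replacement)`); a negative value is a
  cull recommendation.

Seeded synthetic-data generators (herds, monthly collection histories,
blended sales orders) with known ground truth make the whole pipeline
testable without proprietary company data.

## Worked example

```r
library(bullval)
s <- default_schedule()                      # packaged case-study schedule

# steady-state demography of a 396-bull stud
scale_to_herd(steady_state_closed_form(s), 396)$counts
#>  [1] 23 23 22 22 22 22 22 22 22 21 21 21 20 20 20 19 19 18 16

# cost-side NPV decomposition of the reference replacement sire
npv(replacement_profile(), s, prices = NULL, shares = NULL,
    config = default_econ_config())
#> NPV breakdown (USD):
#>   semen income             0.00
#>   maintenance          63600.00
#>   culling cost          7376.03
#>   culling income         531.64
#>   NPV                 -70444.39

# a synthetic herd valued end to end
g      <- generate_herd(synthetic_spec(seed = 3, n_bulls = 60))
sales  <- generate_sales(synthetic_spec(seed = 3))
prices <- smooth_prices(sales$sales)
shares <- estimate_market_shares(sales$sales)
val <- value_herd(g$herd, s, prices, shares, default_econ_config(),
                  histories = g$histories)
head(val$report[, c("bull_id", "start_age_bin", "nm_bin", "pdev",
                    "bullval", "rank", "cull_flag")], 5)
#>   bull_id start_age_bin nm_bin      pdev bullval rank cull_flag
#> 1   B0046             5      9 0.6878362 8069712    1     FALSE
#> 2   B0015            17      2 0.8179617 7045457    2     FALSE
#> 3   B0038             4      6 0.5870244 6440541    3     FALSE
#> 4   B0042            15      4 0.6284797 6380471    4     FALSE
#> 5   B0009            11      1 0.5880127 6059807    5     FALSE
sum(val$report$cull_flag)
#> [1] 31
```

The steady-state counts range from 23 bulls in the youngest bin down to
16 in the oldest: attrition thins older cohorts, and regeneration keeps
the herd at 396. The replacement's cost-side NPV is negative because
with `prices = NULL` no income stream is modeled — the decomposition
isolates maintenance, culling cost and salvage. In the synthetic herd,
31 of 60 bulls fall below the replacement and are flagged; the top-ranked
bulls combine high production deviations (`pdev`) with well-priced NM
deciles. `val$summary` adds the per-decile reporting table (counts,
mean/SD deviation in %, mean/SD value, plus a Total row).

Every default is explicit and overridable: the age-bin schedule
(`inst/extdata/age_bin_schedule.csv`), the base economics
(`inst/extdata/econ_base.yaml`), and the replacement profile
(`inst/extdata/replacement_profile.yaml`). The NPV engine's numerical
conventions (discount basis, exponent offset, regeneration,
culling-cost grouping) are configuration; the packaged defaults are the
combination selected by `calibrate_npv_convention()` against the
case-study replacement decomposition. See the vignette
(`vignettes/bull-valuation.Rmd`) for the model account.

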