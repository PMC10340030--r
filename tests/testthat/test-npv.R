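test_that("a null economy yields an NPV of exactly zero", {
  cfg <- econ_config(maintenance_cost_per_bin_usd = 0,
                     replacement_cost_usd = 0, salvage_value_usd = 0,
                     depreciation_value_usd = 0)
  b <- npv(replacement_profile(), default_schedule(), NULL, NULL, cfg)
  expect_identical(b$npv, 0)
  expect_identical(b$semen_income, 0)
})

test_that("the breakdown identity npv = Si - Mc - Cc + Ci always holds", {
  set.seed(11)
  s <- default_schedule()
  prices <- flat_prices(20)
  shares <- single_market_shares()
  for (rep in 1:20) {
    cfg <- econ_config(
      maintenance_cost_per_bin_usd = runif(1, 0, 5000),
      replacement_cost_usd = runif(1, 0, 20000),
      salvage_value_usd = runif(1, 0, 2000),
      depreciation_value_usd = runif(1, 0, 80000),
      interest_rate_annual = runif(1, 0, 0.2),
      n_iterations = sample(5:60, 1),
      regeneration_in_npv = sample(c(TRUE, FALSE), 1),
      culling_cost_grouping = sample(c("cull_times_both",
                                       "cr_plus_cull_times_depr"), 1))
    prof <- bull_profile("x", sample(1:19, 1), sample(1:15, 1),
                         sample(1:10, 1), runif(1, -0.5, 0.5))
    b <- npv(prof, s, prices, shares, cfg)
    expect_equal(b$npv,
                 b$semen_income - b$maintenance - b$culling_cost +
                   b$culling_income,
                 tolerance = 1e-6)
  }
})

test_that("semen income is exactly linear in (1 + pdev) and in prices", {
  s <- default_schedule()
  cfg <- econ_config(n_iterations = 40L)
  shares <- single_market_shares()
  base <- npv(bull_profile("b", 3, 6, 5, 0), s, flat_prices(10), shares,
              cfg)
  up <- npv(bull_profile("b", 3, 6, 5, 0.25), s, flat_prices(10), shares,
            cfg)
  expect_equal(up$semen_income, 1.25 * base$semen_income,
               tolerance = 1e-12)
  dead <- npv(bull_profile("b", 3, 6, 5, -1), s, flat_prices(10), shares,
              cfg)
  expect_identical(dead$semen_income, 0)
  doubled <- npv(bull_profile("b", 3, 6, 5, 0), s, flat_prices(20), shares,
                 cfg)
  expect_equal(doubled$semen_income, 2 * base$semen_income,
               tolerance = 1e-12)
  # cost side untouched by prices
  expect_equal(doubled$maintenance, base$maintenance)
  expect_equal(doubled$culling_cost, base$culling_cost)
})

test_that("income_straws sums price x share x units across markets", {
  s <- default_schedule()
  cfg <- econ_config()
  prof <- bull_profile("b", 5, 6, 7, 0)
  # degenerate one-market economy: Si = price x units
  expect_equal(income_straws(prof, 5, s, flat_prices(3),
                             single_market_shares(), cfg),
               3 * 24420)
  # two markets splitting units 60/40 at different prices
  two_p <- price_table(rbind(flat_prices(3, "A"), flat_prices(5, "B")))
  two_s <- market_shares(data.frame(market = rep(c("A", "B"), each = 19),
                                    age_bin = rep(1:19, 2),
                                    share = rep(c(0.6, 0.4), each = 19)))
  expect_equal(income_straws(prof, 5, s, two_p, two_s, cfg),
               (0.6 * 3 + 0.4 * 5) * 24420)
  # lookup failures name the missing key
  expect_error(income_straws(prof, 5, s, flat_prices(3),
                             single_market_shares(market = "B"), cfg),
               "no market share")
  sparse <- price_table(flat_prices(3)[-5L, ], complete = FALSE)
  expect_error(income_straws(bull_profile("b", 5, 6,
                                          flat_prices(3)$nm_bin[5L], 0),
                             5, s, sparse, single_market_shares(), cfg),
               "no price")
})

test_that("npv is monotone in prices and salvage, antitone in costs", {
  s <- default_schedule()
  shares <- single_market_shares()
  cfg <- econ_config(n_iterations = 60L)
  prof <- bull_profile("b", 2, 6, 5, 0.1)
  v <- function(cfg, p = 10) npv(prof, s, flat_prices(p), shares, cfg)$npv
  expect_lt(v(cfg, 10), v(cfg, 11))
  expect_lt(v(econ_config(n_iterations = 60L, salvage_value_usd = 0)),
            v(econ_config(n_iterations = 60L, salvage_value_usd = 2000)))
  expect_gt(v(econ_config(n_iterations = 60L,
                          maintenance_cost_per_bin_usd = 0)),
            v(econ_config(n_iterations = 60L,
                          maintenance_cost_per_bin_usd = 5000)))
  expect_gt(v(econ_config(n_iterations = 60L, replacement_cost_usd = 0)),
            v(econ_config(n_iterations = 60L,
                          replacement_cost_usd = 30000)))
})

test_that("npv matches the brute-force path-enumeration oracle on toys", {
  set.seed(22)
  for (rep in 1:30) {
    n_bins <- sample(2:3, 1)
    s <- toy_schedule(c(runif(n_bins - 1, 0, 0.6), 1),
                      tsp = runif(n_bins, 100, 500))
    cfg <- econ_config(
      maintenance_cost_per_bin_usd = runif(1, 0, 4000),
      replacement_cost_usd = runif(1, 0, 15000),
      salvage_value_usd = runif(1, 0, 1500),
      depreciation_value_usd = runif(1, 0, 60000),
      interest_rate_annual = runif(1, 0, 0.1),
      n_iterations = sample(1:5, 1),
      discount_exponent_offset = sample(-1:1, 1),
      regeneration_in_npv = sample(c(TRUE, FALSE), 1),
      culling_cost_grouping = sample(c("cull_times_both",
                                       "cr_plus_cull_times_depr"), 1))
    prof <- bull_profile("t", sample(seq_len(n_bins), 1), 6, 4,
                         runif(1, -0.3, 0.3))
    got <- npv(prof, s, NULL, NULL, cfg)
    want <- oracle_npv(prof, s, cfg)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9,
                   label = paste0(f, " (rep ", rep, ")"))
    }
  }
})

test_that("zero interest and a long horizon reproduce undiscounted sums", {
  s <- default_schedule()
  cfg <- econ_config(interest_rate_annual = 0, n_iterations = 2000L,
                     regeneration_in_npv = FALSE)
  b <- npv(bull_profile("b", 1, 6, 9, 0), s, NULL, NULL, cfg)
  surv <- cumprod(c(1, 1 - s$cull_proportion[-19]))
  expect_equal(b$maintenance, 3600 * sum(surv), tolerance = 1e-9)
  # every bull eventually exits exactly once
  expect_equal(b$culling_income, 850, tolerance = 1e-9)
})

test_that("bullval is zero for self-comparison and increases with pdev", {
  s <- default_schedule()
  cfg <- econ_config(n_iterations = 60L)
  prof <- bull_profile("b", 7, 8, 3, -0.2)
  expect_identical(bullval(prof, prof, s, config = cfg), 0)
  lo <- bull_profile("b", 7, 8, 3, 0)
  hi <- bull_profile("b", 7, 8, 3, 0.10)
  shares <- single_market_shares()
  expect_gt(bullval(hi, lo, s, flat_prices(15), shares, cfg), 0)
  # zero-price economy: value differences come from the cost side only
  # (depreciation and culling timing); checked against the path oracle
  young <- bull_profile("y", 1, 6, 9, 0)
  old <- bull_profile("o", 19, 6, 9, 0)
  short <- econ_config(n_iterations = 6L)
  d_oracle <- oracle_npv(old, s, short)$npv -
    oracle_npv(young, s, short)$npv
  expect_equal(bullval(old, young, s, config = short), d_oracle,
               tolerance = 1e-6)
  expect_lt(bullval(old, young, s, config = short), 0)
})

test_that("bull profiles validate their ranges", {
  expect_error(bull_profile("b", 0, 6, 5), "start_age_bin")
  expect_error(bull_profile("b", 1, 16, 5), "arrival_age")
  expect_error(bull_profile("b", 1, 6, 11), "nm_bin")
  expect_error(bull_profile("b", 1, 6, 5, -1.5), "pdev")
  rp <- replacement_profile()
  expect_equal(rp$start_age_bin, 1L)
  expect_equal(rp$arrival_age, 6)
  expect_equal(rp$nm_bin, 9L)
  expect_equal(rp$pdev, 0)
})
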