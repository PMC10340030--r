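# Shared fixtures: toy schedules built in code and an independent
# brute-force oracle for the NPV aggregation.

toy_schedule <- function(culls, tsp = NULL) {
  n <- length(culls)
  if (is.null(tsp)) tsp <- rep(400, n)
  age_bin_schedule(
    data.frame(bin = seq_len(n),
               start_month = 10L + 4L * (seq_len(n) - 1L),
               end_month = 13L + 4L * (seq_len(n) - 1L),
               mean_tsp_billion = tsp,
               cull_proportion = culls),
    strict = FALSE)
}

random_schedule <- function(n = 19L) {
  toy_schedule(c(runif(n - 1L, 0, 0.25), 1), runif(n, 50, 500))
}

random_state <- function(n = 19L) {
  x <- runif(n)
  x / sum(x)
}

# Brute-force NPV oracle: recursively enumerates every cull/survive branch
# of the bull's life (and, with regeneration, of each successor), weighting
# cash flows by path probability. Exponential in the horizon, so only for
# tiny schedules/horizons; structurally independent of the vectorized
# state-propagation in npv().
oracle_npv <- function(profile, schedule, config, si_bin = NULL) {
  n <- nrow(schedule)
  cull <- schedule$cull_proportion
  depr <- depreciation(schedule$start_month, profile$arrival_age, config)
  if (is.null(si_bin)) si_bin <- rep(0, n)
  mc <- config$maintenance_cost_per_bin_usd
  cr <- config$replacement_cost_usd
  sv <- config$salvage_value_usd
  grouping <- config$culling_cost_grouping
  zero <- c(semen = 0, maint = 0, cc = 0, ci = 0)
  rec <- function(bin, i) {
    if (i > config$n_iterations) return(zero)
    d <- discount_factor(i, config)
    here <- c(semen = d * si_bin[bin], maint = d * mc,
              cc = if (grouping == "cr_plus_cull_times_depr") d * cr else 0,
              ci = 0)
    culled <- c(semen = 0, maint = 0,
                cc = d * (if (grouping == "cull_times_both")
                            cr + depr[bin] else depr[bin]),
                ci = d * sv)
    if (config$regeneration_in_npv) culled <- culled + rec(1L, i + 1L)
    survived <- if (bin < n) rec(bin + 1L, i + 1L) else zero
    here + cull[bin] * culled + (1 - cull[bin]) * survived
  }
  v <- rec(profile$start_age_bin, 1L)
  list(semen_income = v[["semen"]], maintenance = v[["maint"]],
       culling_cost = v[["cc"]], culling_income = v[["ci"]],
       npv = v[["semen"]] - v[["maint"]] - v[["cc"]] + v[["ci"]])
}

# One-market economy with a flat price so semen income is price x units.
flat_prices <- function(price, market = "A") {
  price_table(expand.grid(market = market,
                          age_class = c("young", "in_waiting", "proven"),
                          nm_bin = 1:10,
                          stringsAsFactors = FALSE) |>
                transform(price_usd_per_straw = price))
}

single_market_shares <- function(n_bins = 19L, market = "A") {
  market_shares(data.frame(market = market, age_bin = seq_len(n_bins),
                           share = 1))
}
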