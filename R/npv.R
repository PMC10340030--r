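#' Bull profile
#'
#' The per-bull state variables entering the valuation: the age bin at the
#' start of the Markov chain, the arrival age at the stud (months, drives
#' depreciation), the net-merit decile bin (drives pricing) and the bull's
#' expected TSp deviation from the bin mean (`pdev`, signed fraction:
#' +0.10 means 10% above average production).
#'
#' @param bull_id Identifier.
#' @param start_age_bin Age bin 1..19 at the first iteration.
#' @param arrival_age Arrival age at the stud, 1..15 months.
#' @param nm_bin Net-merit decile bin 1..10.
#' @param pdev Signed fractional TSp deviation, >= -1.
#' @return A list with class `"bull_profile"`.
#' @export
bull_profile <- function(bull_id, start_age_bin, arrival_age, nm_bin,
                         pdev = 0) {
  if (!(start_age_bin %in% 1:19)) stop("start_age_bin must be in 1..19")
  if (arrival_age < 1 || arrival_age > 15) {
    stop("arrival_age must be 1..15 months")
  }
  if (!(nm_bin %in% 1:10)) stop("nm_bin must be in 1..10")
  if (!is.numeric(pdev) || pdev < -1) stop("pdev must be numeric and >= -1")
  structure(list(bull_id = as.character(bull_id),
                 start_age_bin = as.integer(start_age_bin),
                 arrival_age = as.numeric(arrival_age),
                 nm_bin = as.integer(nm_bin),
                 pdev = as.numeric(pdev)),
            class = "bull_profile")
}

#' The reference young replacement sire
#'
#' A young bull at the start of its productive life: age bin 1, arrived at
#' 6 months, net merit in decile 9 (just below the elite bulls reserved
#' for breeding the next generation), average production (`pdev = 0`).
#' Every bull in the herd is valued against this profile.
#'
#' @return A `bull_profile`.
#' @export
replacement_profile <- function() {
  p <- yaml::read_yaml(system.file("extdata", "replacement_profile.yaml",
                                   package = "bullval", mustWork = TRUE))
  bull_profile(p$bull_id, p$start_age_bin, p$arrival_age, p$nm_bin, p$pdev)
}

#' Semen income of a bull in one age bin
#'
#' `Si = (1 + pdev) * sum over markets of PU * MS * U`: price per straw for
#' the bin's age class and the bull's NM bin in each market, times the
#' market's share of units at that age, times the straw units produced.
#'
#' @param profile A [bull_profile()].
#' @param bin_index Age bin.
#' @param schedule,prices,shares,config See [npv()].
#' @return USD for one 4-month bin at full occupancy.
#' @export
income_straws <- function(profile, bin_index, schedule, prices, shares,
                          config) {
  if (is.null(prices) || is.null(shares)) return(0)
  u <- units_produced(bin_index, schedule, config)
  ac <- age_class_of(bin_index)
  mkts <- unique(prices$market)
  inc <- vapply(mkts, function(m) {
    price_lookup(prices, ac, profile$nm_bin, m) *
      share_lookup(shares, m, bin_index)
  }, numeric(1))
  (1 + profile$pdev) * sum(inc) * u
}

# Per-bin cash-flow vectors for one profile under one configuration.
bin_cashflows <- function(profile, schedule, prices, shares, config) {
  n <- nrow(schedule)
  cull <- schedule$cull_proportion
  depr <- depreciation(schedule$start_month, profile$arrival_age, config)
  cr <- config$replacement_cost_usd
  si <- vapply(seq_len(n), function(b) {
    income_straws(profile, b, schedule, prices, shares, config)
  }, numeric(1))
  cc <- switch(config$culling_cost_grouping,
               cull_times_both = cull * (cr + depr),
               cr_plus_cull_times_depr = cr + cull * depr)
  list(si = si, mc = rep(config$maintenance_cost_per_bin_usd, n),
       cc = cc, ci = config$salvage_value_usd * cull)
}

#' Discounted net present value of a bull
#'
#' Propagates the Markov chain from the bull's starting age bin over
#' `config$n_iterations` 4-month iterations, accumulating at each
#' iteration the discounted, occupancy-weighted semen income, maintenance
#' cost, culling cost (replacement purchase plus unrealized depreciation
#' on involuntary exit) and culling income (salvage). Depreciation is
#' evaluated at each bin's starting month with the profile's arrival age.
#' With `config$regeneration_in_npv` the chain regenerates (every exit is
#' succeeded by a young bull of the same profile in bin 1); otherwise only
#' the bull's own trajectory is followed and mass drains out of the
#' system.
#'
#' With `prices`/`shares` equal to `NULL` the semen-income stream is zero
#' (a cost-side-only valuation).
#'
#' @param profile A [bull_profile()].
#' @param schedule An [age_bin_schedule()].
#' @param prices A [price_table()] or `NULL`.
#' @param shares A [market_shares()] table or `NULL`.
#' @param config An [econ_config()].
#' @return An `"npv_breakdown"` list: `semen_income`, `maintenance`,
#'   `culling_cost`, `culling_income`, and their signed sum `npv`.
#' @examples
#' npv(replacement_profile(), default_schedule(), NULL, NULL,
#'     default_econ_config())
#' @export
npv <- function(profile, schedule, prices = NULL, shares = NULL,
                config = default_econ_config()) {
  flows <- bin_cashflows(profile, schedule, prices, shares, config)
  n <- nrow(schedule)
  state <- numeric(n)
  state[profile$start_age_bin] <- 1
  semen <- maint <- cc <- ci <- 0
  for (i in seq_len(config$n_iterations)) {
    d <- discount_factor(i, config)
    semen <- semen + d * sum(state * flows$si)
    maint <- maint + d * sum(state * flows$mc)
    cc <- cc + d * sum(state * flows$cc)
    ci <- ci + d * sum(state * flows$ci)
    state <- step_herd(state, schedule,
                       regenerate = config$regeneration_in_npv)
    if (sum(state) == 0) break
  }
  structure(list(semen_income = semen, maintenance = maint,
                 culling_cost = cc, culling_income = ci,
                 npv = semen - maint - cc + ci),
            class = "npv_breakdown")
}

#' @export
print.npv_breakdown <- function(x, ...) {
  cat("NPV breakdown (USD):\n")
  cat(sprintf("  semen income   %14.2f\n", x$semen_income))
  cat(sprintf("  maintenance    %14.2f\n", x$maintenance))
  cat(sprintf("  culling cost   %14.2f\n", x$culling_cost))
  cat(sprintf("  culling income %14.2f\n", x$culling_income))
  cat(sprintf("  NPV            %14.2f\n", x$npv))
  invisible(x)
}

#' Relative value of a bull against a replacement
#'
#' `bullval = NPV(bull) - NPV(replacement)`. A negative value means the
#' bull is worth less than a fresh young sire of average production, i.e.
#' a cull recommendation.
#'
#' @param bull,replacement [bull_profile()]s; the replacement defaults to
#'   [replacement_profile()].
#' @inheritParams npv
#' @return USD (a single number).
#' @export
bullval <- function(bull, replacement = replacement_profile(), schedule,
                    prices = NULL, shares = NULL,
                    config = default_econ_config()) {
  npv(bull, schedule, prices, shares, config)$npv -
    npv(replacement, schedule, prices, shares, config)$npv
}
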