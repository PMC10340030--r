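#' Herd-wide economic configuration
#'
#' Bundles the economic constants of the stud and the numerical
#' conventions of the discounted net-present-value aggregation. The
#' defaults are the case-study base values: maintenance of 900
#' USD/bull/month (3600 per 4-month bin), a 10,000 USD replacement
#' purchase, 850 USD salvage on culling, bulls insured for 54,000 USD
#' written off linearly over a 36-month term from arrival, a 6%/year
#' interest rate, 15 million sperm cells packed per straw, and a 330
#' iteration (4-month) horizon.
#'
#' Three conventions are deliberately configurable because the aggregation
#' admits more than one defensible reading; the packaged defaults are the
#' combination selected by [calibrate_npv_convention()] against the
#' case-study replacement decomposition (see the vignette):
#'
#' * `discount_convention`: `"per_iteration_rate"` applies
#'   `interest_rate_annual` directly as the per-bin rate;
#'   `"annual_rate_compounded_per_bin"` converts it to the equivalent
#'   4-month rate `(1 + r)^(1/3) - 1`.
#' * `discount_exponent_offset`: the factor for iteration `i` is
#'   `1 / (1 + rate)^(i + offset)`; offset `-1` leaves the first iteration
#'   undiscounted.
#' * `culling_cost_grouping`: `"cull_times_both"` charges
#'   `cull * (CR + Depr)` (replacement cost only on actual exits);
#'   `"cr_plus_cull_times_depr"` charges `CR + cull * Depr` every occupied
#'   iteration.
#'
#' @param maintenance_cost_per_bin_usd Housing/feed/veterinary cost per
#'   bull per 4-month bin.
#' @param replacement_cost_usd Purchase price of a new bull (CR).
#' @param salvage_value_usd Income per culled bull (SV), age-constant.
#' @param depreciation_value_usd Insured value written off over the term.
#' @param depreciation_term_months Length of the linear write-off, from
#'   arrival age.
#' @param interest_rate_annual Yearly interest rate as a fraction.
#' @param packing_rate_cells_per_straw Sperm cells per straw unit.
#' @param n_iterations Number of 4-month iterations aggregated.
#' @param discount_convention,discount_exponent_offset,culling_cost_grouping
#'   Numerical conventions, see Details.
#' @param regeneration_in_npv Keep the constant-herd regeneration active
#'   inside the NPV aggregation (a perpetual chain of successors) rather
#'   than following only the bull's own trajectory.
#' @return A list with class `"econ_config"`.
#' @export
econ_config <- function(maintenance_cost_per_bin_usd = 3600,
                        replacement_cost_usd = 10000,
                        salvage_value_usd = 850,
                        depreciation_value_usd = 54000,
                        depreciation_term_months = 36,
                        interest_rate_annual = 0.06,
                        packing_rate_cells_per_straw = 15e6,
                        n_iterations = 330L,
                        discount_convention = c("per_iteration_rate",
                                                "annual_rate_compounded_per_bin"),
                        discount_exponent_offset = -1L,
                        regeneration_in_npv = TRUE,
                        culling_cost_grouping = c("cull_times_both",
                                                  "cr_plus_cull_times_depr")) {
  cfg <- list(
    maintenance_cost_per_bin_usd = maintenance_cost_per_bin_usd,
    replacement_cost_usd = replacement_cost_usd,
    salvage_value_usd = salvage_value_usd,
    depreciation_value_usd = depreciation_value_usd,
    depreciation_term_months = depreciation_term_months,
    interest_rate_annual = interest_rate_annual,
    packing_rate_cells_per_straw = packing_rate_cells_per_straw,
    n_iterations = as.integer(n_iterations),
    discount_convention = match.arg(discount_convention),
    discount_exponent_offset = as.integer(discount_exponent_offset),
    regeneration_in_npv = isTRUE(regeneration_in_npv),
    culling_cost_grouping = match.arg(culling_cost_grouping)
  )
  money <- c("maintenance_cost_per_bin_usd", "replacement_cost_usd",
             "salvage_value_usd", "depreciation_value_usd")
  for (f in money) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0) {
      stop(f, " must be a single non-negative number")
    }
  }
  if (cfg$interest_rate_annual < 0 || cfg$interest_rate_annual >= 1) {
    stop("interest_rate_annual must lie in [0, 1)")
  }
  if (cfg$packing_rate_cells_per_straw <= 0) {
    stop("packing_rate_cells_per_straw must be > 0")
  }
  if (cfg$depreciation_term_months <= 0) {
    stop("depreciation_term_months must be > 0")
  }
  if (cfg$n_iterations < 1L) stop("n_iterations must be >= 1")
  class(cfg) <- "econ_config"
  cfg
}

#' Read an economic configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [econ_config()]
#' defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return An `econ_config`.
#' @export
read_econ_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(vals), names(formals(econ_config)))
  if (length(unknown)) {
    stop("unknown economics keys: ", paste(unknown, collapse = ", "))
  }
  do.call(econ_config, vals)
}

#' The packaged case-study economics
#' @return An `econ_config` with the case-study base values.
#' @export
default_econ_config <- function() {
  read_econ_config(system.file("extdata", "econ_base.yaml",
                               package = "bullval", mustWork = TRUE))
}

per_bin_rate <- function(config) {
  switch(config$discount_convention,
         per_iteration_rate = config$interest_rate_annual,
         annual_rate_compounded_per_bin =
           (1 + config$interest_rate_annual)^(1 / 3) - 1)
}

#' Discount factor for one iteration
#'
#' `1 / (1 + rate)^(i + offset)` with the per-bin rate and exponent offset
#' implied by the configuration; strictly decreasing in `i` for a positive
#' rate.
#'
#' @param i Iteration index (>= 1), vectorized.
#' @param config An [econ_config()].
#' @return Discount factors in (0, 1].
#' @export
discount_factor <- function(i, config) {
  if (any(i < 1)) stop("iteration index must be >= 1")
  (1 + per_bin_rate(config))^(-(i + config$discount_exponent_offset))
}

#' Age class of an age bin
#'
#' Bins are grouped into the three commercial classes used for pricing:
#' young genomic bulls (bins 1-4), in-waiting (5-12) and proven sires with
#' daughter data (13-19). Bin 12 belongs to in-waiting so the classes
#' partition the bins.
#'
#' @param bin_index Integer vector of bins in 1..19.
#' @return Character vector: `"young"`, `"in_waiting"` or `"proven"`.
#' @export
age_class_of <- function(bin_index) {
  if (any(bin_index < 1 | bin_index > 19)) stop("age bin must be in 1..19")
  ifelse(bin_index <= 4, "young",
         ifelse(bin_index <= 12, "in_waiting", "proven"))
}

#' Straw units produced in an age bin
#'
#' Mean bin TSp divided by the packing rate.
#'
#' @param bin_index Bin(s) in the schedule.
#' @param schedule An [age_bin_schedule()].
#' @param config An [econ_config()] supplying the packing rate.
#' @return Straw units per 4-month bin.
#' @examples
#' units_produced(5, default_schedule(), econ_config())  # 24420 straws
#' @export
units_produced <- function(bin_index, schedule, config) {
  if (any(bin_index < 1 | bin_index > nrow(schedule))) {
    stop("age bin out of schedule range")
  }
  schedule$mean_tsp_billion[bin_index] * 1e9 /
    config$packing_rate_cells_per_straw
}

#' Remaining depreciation at a given age
#'
#' Linear write-off of the insured value from arrival age to the end of
#' the depreciation term; the remainder is the unrealized cost charged if
#' the bull exits early. Clamped to the full value before arrival and to
#' zero beyond the term.
#'
#' @param age_months Age(s) at evaluation, months.
#' @param arrival_age Arrival age at the stud, months (must precede the
#'   end of the term).
#' @param config An [econ_config()].
#' @return Remaining depreciation in USD.
#' @examples
#' depreciation(21, 6, econ_config())  # 27000
#' @export
depreciation <- function(age_months, arrival_age, config) {
  v <- config$depreciation_value_usd
  term <- config$depreciation_term_months
  if (arrival_age >= term) {
    stop("arrival_age (", arrival_age, ") must be below the ",
         term, "-month depreciation term")
  }
  raw <- v - (v / (term - arrival_age)) * (age_months - arrival_age)
  pmin(v, pmax(0, raw))
}

#' Culling cost charged in an age bin
#'
#' Replacement purchase plus unrealized depreciation on involuntary exit.
#' Under the default grouping both are contingent on the exit:
#' `cull * (CR + Depr)`; the alternative charges `CR` unconditionally each
#' occupied iteration: `CR + cull * Depr`.
#'
#' @param bin_index Bin in the schedule.
#' @param age_months Age at the bin (for depreciation).
#' @param arrival_age Arrival age, months.
#' @param schedule,config See [npv()].
#' @return USD per unit of occupancy for that bin.
#' @export
culling_cost <- function(bin_index, age_months, arrival_age, schedule,
                         config) {
  cull <- schedule$cull_proportion[bin_index]
  depr <- depreciation(age_months, arrival_age, config)
  cr <- config$replacement_cost_usd
  switch(config$culling_cost_grouping,
         cull_times_both = cull * (cr + depr),
         cr_plus_cull_times_depr = cr + cull * depr)
}

#' Culling income in an age bin
#'
#' Salvage value times the culled proportion.
#'
#' @inheritParams culling_cost
#' @return USD per unit of occupancy for that bin.
#' @export
culling_income <- function(bin_index, schedule, config) {
  config$salvage_value_usd * schedule$cull_proportion[bin_index]
}
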