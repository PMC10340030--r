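#' Specification for synthetic stud data
#'
#' Parameters of the seeded generators that emulate the statistical
#' structure of a commercial stud: herd demographics (ages distributed as
#' the schedule's steady state, NM$ declining with age), per-bull
#' multiplicative TSp deviations around the bin means with lognormal
#' month-to-month noise, and blended sales orders whose order-level
#' price is the unit-weighted mean of the true group prices plus noise.
#' Defaults echo the case-study scale: 396 bulls, a TSp deviation SD of
#' 0.30, six markets.
#'
#' @param seed Integer seed; fixed seed, identical output.
#' @param n_bulls Herd size.
#' @param age_distribution Probability over the schedule's bins for start
#'   ages; default = the steady-state distribution.
#' @param arrival_age_mean,arrival_age_sd Arrival age (months, clamped to
#'   1..15 and below the bull's current age).
#' @param nm_intercept,nm_age_slope,nm_sd NM$ model: intercept at bin 1,
#'   change per age bin (negative: younger bulls carry higher merit),
#'   residual SD.
#' @param pdev_sd SD of the true per-bull TSp deviation fraction.
#' @param history_months Collection months generated per bull.
#' @param tsp_noise_sdlog Lognormal sdlog of monthly TSp noise.
#' @param markets Market labels.
#' @param price_base Named base price per straw by age class (USD).
#' @param price_nm_slope Price increase per NM bin (USD/straw).
#' @param price_market_sd SD of per-market price offsets.
#' @param tau_star SD of true group prices around their systematic part.
#' @param price_noise_sd SD of order-level blended-price noise (USD).
#' @param n_orders_per_market Sales orders per market.
#' @param bulls_per_order Bull groups blended into one order.
#' @param units_mean Mean straw units per record (geometric-ish spread).
#' @return A list with class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed,
                           n_bulls = 396L,
                           age_distribution = NULL,
                           arrival_age_mean = 6, arrival_age_sd = 2,
                           nm_intercept = 800, nm_age_slope = -25,
                           nm_sd = 100,
                           pdev_sd = 0.30,
                           history_months = 3L,
                           tsp_noise_sdlog = 0.10,
                           markets = LETTERS[1:6],
                           price_base = c(young = 14, in_waiting = 16,
                                          proven = 20),
                           price_nm_slope = 0.8,
                           price_market_sd = 2,
                           tau_star = 2,
                           price_noise_sd = 2,
                           n_orders_per_market = 300L,
                           bulls_per_order = 3L,
                           units_mean = 200) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_bulls >= 1, pdev_sd >= 0, nm_sd >= 0, tsp_noise_sdlog >= 0,
            price_noise_sd >= 0, tau_star >= 0,
            history_months >= 1, bulls_per_order >= 1,
            n_orders_per_market >= 1, units_mean > 0,
            all(c("young", "in_waiting", "proven") %in% names(price_base)))
  if (!is.null(age_distribution)) {
    if (any(age_distribution < 0) || sum(age_distribution) <= 0) {
      stop("age_distribution must be non-negative with positive mass")
    }
    age_distribution <- age_distribution / sum(age_distribution)
  }
  spec <- as.list(environment())
  spec$seed <- as.integer(seed)
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic herd with collection histories
#'
#' Draws start ages from the age distribution, arrival ages, NM$ with the
#' declining age trend, true TSp deviations, and a short monthly
#' collection history per bull: monthly TSp = (bin mean / 4) x
#' (1 + pdev_true) x lognormal noise. The true deviations are returned as
#' ground truth so estimator properties can be checked.
#'
#' @param spec A [synthetic_spec()].
#' @param schedule An [age_bin_schedule()].
#' @return A list: `herd` (data.frame ready for [value_herd()], without a
#'   `pdev` column), `histories` (named list of per-bull data.frames) and
#'   `truth` (data.frame with `bull_id`, `pdev_true`).
#' @export
generate_herd <- function(spec, schedule = default_schedule()) {
  set.seed(spec$seed)
  n <- spec$n_bulls
  p_age <- spec$age_distribution
  if (is.null(p_age)) p_age <- steady_state_closed_form(schedule)
  bins <- sample.int(nrow(schedule), n, replace = TRUE, prob = p_age)
  age_months <- schedule$start_month[bins] +
    sample.int(4L, n, replace = TRUE) - 1L
  arrival <- round(stats::rnorm(n, spec$arrival_age_mean,
                                spec$arrival_age_sd))
  arrival <- pmin(pmax(arrival, 1L), 15L, age_months)
  nm <- stats::rnorm(n, spec$nm_intercept + spec$nm_age_slope * (bins - 1),
                     spec$nm_sd)
  pdev_true <- stats::rnorm(n, 0, spec$pdev_sd)
  pdev_true <- pmax(pdev_true, -0.95)
  ids <- sprintf("B%04d", seq_len(n))
  histories <- vector("list", n)
  names(histories) <- ids
  for (k in seq_len(n)) {
    m_ages <- seq(age_months[k] - spec$history_months + 1L, age_months[k])
    m_ages <- m_ages[m_ages >= 10L]
    mb <- months_to_bin(m_ages)
    noise <- exp(stats::rnorm(length(m_ages), 0, spec$tsp_noise_sdlog))
    histories[[k]] <- data.frame(
      month = seq_along(m_ages),
      age_months = m_ages,
      total_sperm_billion = schedule$mean_tsp_billion[mb] / 4 *
        (1 + pdev_true[k]) * noise)
  }
  list(herd = data.frame(bull_id = ids, age_months = age_months,
                         arrival_age_months = arrival, nm_dollars = nm,
                         stringsAsFactors = FALSE),
       histories = histories,
       truth = data.frame(bull_id = ids, start_age_bin = bins,
                          pdev_true = pdev_true,
                          stringsAsFactors = FALSE))
}

#' Generate blended sales orders with known true prices
#'
#' Builds a true price table per (market, age class, NM bin) — a base
#' price by age class plus an NM-bin trend, a market offset and a group
#' effect with SD `tau_star` — then simulates orders: each order blends
#' `bulls_per_order` bull groups in one market; every record of the order
#' carries the same blended price, the unit-weighted mean of the groups'
#' true prices plus truncated Gaussian noise. Heavy blending compresses
#' raw group means toward order means, which is exactly what the
#' shrinkage estimator has to cope with.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `sales` (a [sales_records()] data.frame with `age_bin`
#'   attribution) and `true_prices` (a [price_table()]).
#' @export
generate_sales <- function(spec) {
  set.seed(spec$seed + 1L)
  classes <- c("young", "in_waiting", "proven")
  class_bins <- list(young = 1:4, in_waiting = 5:12, proven = 13:19)
  grid <- expand.grid(market = spec$markets, age_class = classes,
                      nm_bin = 1:10, stringsAsFactors = FALSE)
  mkt_off <- stats::setNames(
    stats::rnorm(length(spec$markets), 0, spec$price_market_sd),
    spec$markets)
  grid$price_usd_per_straw <- pmax(
    0.5,
    spec$price_base[grid$age_class] + spec$price_nm_slope * grid$nm_bin +
      mkt_off[grid$market] + stats::rnorm(nrow(grid), 0, spec$tau_star))
  truth <- price_table(grid)
  key <- function(m, a, g) paste(m, a, g)
  price_of <- stats::setNames(truth$price_usd_per_straw,
                              key(truth$market, truth$age_class,
                                  truth$nm_bin))
  k <- spec$bulls_per_order
  n_orders <- length(spec$markets) * spec$n_orders_per_market
  n_rec <- n_orders * k
  order_of <- rep(seq_len(n_orders), each = k)
  mkt <- rep(rep(spec$markets, each = spec$n_orders_per_market), each = k)
  ac <- sample(classes, n_rec, replace = TRUE)
  gb <- sample.int(10L, n_rec, replace = TRUE)
  units <- pmax(1, round(stats::rexp(n_rec, 1 / spec$units_mean)))
  bin_lo <- c(young = 1L, in_waiting = 5L, proven = 13L)
  bin_n <- c(young = 4L, in_waiting = 8L, proven = 7L)
  age_bin <- bin_lo[ac] +
    as.integer(floor(stats::runif(n_rec) * bin_n[ac]))
  true_p <- price_of[key(mkt, ac, gb)]
  blended_order <- as.vector(
    rowsum(true_p * units, order_of) / rowsum(units + 0, order_of)) +
    stats::rnorm(n_orders, 0, spec$price_noise_sd)
  blended_order <- pmax(0, blended_order)
  sales <- data.frame(
    order_id = sprintf("O%05d", order_of), market = mkt,
    bull_id = sprintf("S%05d-%d", order_of, rep(seq_len(k), n_orders)),
    age_class = ac, nm_bin = gb, age_bin = unname(age_bin),
    units = units, blended_price_usd = blended_order[order_of],
    stringsAsFactors = FALSE)
  list(sales = sales_records(sales), true_prices = truth)
}

#' Write a complete synthetic data set to disk
#'
#' Emits `herd.csv`, `histories/<bull_id>.csv`, `sales.csv`,
#' `true_prices.csv` and `truth.json` (ground-truth deviations and the
#' generator parameters) into a directory.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @param schedule An [age_bin_schedule()].
#' @return `out_dir`, invisibly.
#' @export
simulate_to_dir <- function(spec, out_dir,
                            schedule = default_schedule()) {
  dir.create(file.path(out_dir, "histories"), recursive = TRUE,
             showWarnings = FALSE)
  hd <- generate_herd(spec, schedule)
  sl <- generate_sales(spec)
  utils::write.csv(hd$herd, file.path(out_dir, "herd.csv"),
                   row.names = FALSE)
  for (id in names(hd$histories)) {
    utils::write.csv(hd$histories[[id]],
                     file.path(out_dir, "histories", paste0(id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(sl$sales, file.path(out_dir, "sales.csv"),
                   row.names = FALSE)
  utils::write.csv(sl$true_prices, file.path(out_dir, "true_prices.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = spec$seed, pdev_true = hd$truth,
         spec = spec[!vapply(spec, is.null, logical(1))]),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
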