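#' Validate blended sales records
#'
#' One row per (order, bull-group) sale: the order's market, the bull's
#' commercial age class and NM decile at the time of sale, straw units
#' sold and the order-level blended price per straw (the same price is
#' recorded for every bull in a multi-bull order, which dilutes bull-level
#' price differences and motivates the shrinkage estimator).
#'
#' @param x A data.frame with columns `order_id`, `market`, `bull_id`,
#'   `age_class`, `nm_bin`, `units`, `blended_price_usd`; an optional
#'   `age_bin` column attributes units to a 4-month age bin for market
#'   share estimation.
#' @return The validated data.frame with class `"sales_records"`.
#' @export
sales_records <- function(x) {
  need <- c("order_id", "market", "bull_id", "age_class", "nm_bin",
            "units", "blended_price_usd")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("sales records need columns ", paste(need, collapse = ", "))
  }
  x <- as.data.frame(x)
  if (any(x$units <= 0)) stop("units must be > 0")
  if (any(x$blended_price_usd < 0)) stop("blended_price_usd must be >= 0")
  if (!all(x$age_class %in% c("young", "in_waiting", "proven"))) {
    stop("age_class must be young, in_waiting or proven")
  }
  if (!all(x$nm_bin %in% 1:10)) stop("nm_bin must be in 1..10")
  g <- match(x$order_id, unique(x$order_id))
  mean_g <- as.vector(rowsum(x$blended_price_usd, g, reorder = FALSE)) /
    tabulate(g)
  if (any(abs(x$blended_price_usd - mean_g[g]) > 1e-9)) {
    stop("records of one order must share the same blended price")
  }
  rownames(x) <- NULL
  class(x) <- c("sales_records", "data.frame")
  x
}

#' Drop price outliers within a market
#'
#' Removes records whose blended price lies more than `k` interquartile
#' ranges from the market median; with a degenerate IQR of zero nothing is
#' dropped.
#'
#' @param records A [sales_records()] data.frame (one market or several;
#'   the filter is applied per market).
#' @param k IQR multiplier.
#' @return The filtered records.
#' @export
filter_price_outliers <- function(records, k = 3) {
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$market),
                        function(idx) {
    p <- records$blended_price_usd[idx]
    med <- stats::median(p)
    iqr <- stats::IQR(p)
    if (iqr == 0) return(idx)
    idx[abs(p - med) <= k * iqr]
  }))
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group price statistics within a market
#'
#' Groups one market's records by (age class, NM bin) and computes the
#' ingredients of the empirical Bayes estimator: group size `n`, mean
#' price, sample variance (0 for singletons), and the squared standard
#' error `se_sq = var / n`. Because a singleton gives a spuriously exact
#' `se_sq = 0`, singleton groups take the market-wide price variance as
#' `se_sq` (maximal uncertainty) and are flagged `low_information`.
#'
#' Also returns the market's population mean `mu` and the between-group
#' variance `tau_sq` used as the prior spread: by default the sample
#' variance of the group means (`tau_method = "group_means"`), or the
#' variance of all prices in the market (`"all_prices"`).
#'
#' @param records A [sales_records()] data.frame.
#' @param market Market label to analyze.
#' @param tau_method Between-group variance estimator, see Details.
#' @return A list: `stats` (data.frame per group), `mu`, `tau_sq`.
#' @export
group_stats <- function(records, market,
                        tau_method = c("group_means", "all_prices")) {
  tau_method <- match.arg(tau_method)
  rec <- records[records$market == market, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no sales records for market '", market, "'")
  key <- interaction(rec$age_class, rec$nm_bin, drop = TRUE)
  grp <- split(rec$blended_price_usd, key)
  st <- do.call(rbind, lapply(names(grp), function(k) {
    p <- grp[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(age_class = parts[1],
               nm_bin = as.integer(parts[2]),
               n = length(p),
               mean_price = mean(p),
               var_price = if (length(p) > 1L) stats::var(p) else 0,
               stringsAsFactors = FALSE)
  }))
  market_var <- if (nrow(rec) > 1L) stats::var(rec$blended_price_usd) else 0
  st$low_information <- st$n == 1L
  st$se_sq <- ifelse(st$low_information, market_var, st$var_price / st$n)
  mu <- mean(rec$blended_price_usd)
  tau_sq <- switch(tau_method,
                   group_means = if (nrow(st) > 1L) stats::var(st$mean_price)
                                 else 0,
                   all_prices = market_var)
  st <- st[order(st$age_class, st$nm_bin), , drop = FALSE]
  rownames(st) <- NULL
  list(stats = st, mu = mu, tau_sq = tau_sq)
}

#' Empirical Bayes shrinkage of group prices
#'
#' Shrinks each group mean toward the market population mean with weight
#' `beta = tau_sq / (tau_sq + se_sq)`: well-measured groups keep their own
#' mean, sparse or noisy groups are pulled to `mu`. When `tau_sq` and
#' `se_sq` are both 0 the group mean is kept (`beta = 1`).
#'
#' @param stats The per-group data.frame from [group_stats()].
#' @param mu Market population mean price.
#' @param tau_sq Between-group variance.
#' @return `stats` with columns `beta` and `shrunk_price` appended.
#' @export
shrink_prices <- function(stats, mu, tau_sq) {
  if (tau_sq < 0 || any(stats$se_sq < 0)) {
    stop("tau_sq and se_sq must be >= 0")
  }
  denom <- tau_sq + stats$se_sq
  stats$beta <- ifelse(denom == 0, 1, tau_sq / denom)
  stats$shrunk_price <- stats$beta * stats$mean_price +
    (1 - stats$beta) * mu
  stats
}

#' Estimate the full price table from blended sales records
#'
#' Per market: optional outlier filtering, per-group statistics, empirical
#' Bayes shrinkage, and completion of the (age class x NM bin) grid —
#' cells with no sales take the market mean `mu`.
#'
#' @param records A [sales_records()] data.frame.
#' @param tau_method Passed to [group_stats()].
#' @param outlier_k IQR multiplier for [filter_price_outliers()]; `NULL`
#'   disables filtering.
#' @return A [price_table()] covering every market in `records`.
#' @export
smooth_prices <- function(records, tau_method = "group_means",
                          outlier_k = 3) {
  records <- sales_records(records)
  if (!is.null(outlier_k)) {
    records <- filter_price_outliers(records, k = outlier_k)
  }
  grid <- expand.grid(age_class = c("young", "in_waiting", "proven"),
                      nm_bin = 1:10, stringsAsFactors = FALSE)
  out <- lapply(unique(records$market), function(m) {
    gs <- group_stats(records, m, tau_method = tau_method)
    sh <- shrink_prices(gs$stats, gs$mu, gs$tau_sq)
    idx <- match(paste(grid$age_class, grid$nm_bin),
                 paste(sh$age_class, sh$nm_bin))
    data.frame(market = m, age_class = grid$age_class,
               nm_bin = grid$nm_bin,
               price_usd_per_straw = ifelse(is.na(idx), gs$mu,
                                            sh$shrunk_price[idx]),
               stringsAsFactors = FALSE)
  })
  price_table(do.call(rbind, out))
}

#' Estimate market shares from unit flows
#'
#' `MS[market, age_bin]` is the fraction of all straw units sold from
#' bulls of that age bin that went to the market. Records carrying an
#' `age_bin` are attributed directly; records with only an age class
#' spread their units uniformly over the class's bins. Age bins with no
#' sales at all inherit the shares of the nearest populated bin.
#'
#' @param records A [sales_records()] data.frame.
#' @param n_bins Number of age bins in the schedule.
#' @return A [market_shares()] table covering bins `1..n_bins`.
#' @export
estimate_market_shares <- function(records, n_bins = 19L) {
  records <- sales_records(records)
  class_bins <- list(young = 1:4, in_waiting = 5:12, proven = 13:19)
  mkts <- sort(unique(records$market))
  units <- matrix(0, length(mkts), n_bins,
                  dimnames = list(mkts, NULL))
  for (r in seq_len(nrow(records))) {
    m <- records$market[r]
    if ("age_bin" %in% names(records) && !is.na(records$age_bin[r])) {
      units[m, records$age_bin[r]] <- units[m, records$age_bin[r]] +
        records$units[r]
    } else {
      bins <- class_bins[[records$age_class[r]]]
      units[m, bins] <- units[m, bins] + records$units[r] / length(bins)
    }
  }
  tot <- colSums(units)
  populated <- which(tot > 0)
  if (length(populated) == 0L) stop("no units in any age bin")
  share <- units
  for (b in seq_len(n_bins)) {
    src <- if (tot[b] > 0) b else populated[which.min(abs(populated - b))]
    share[, b] <- units[, src] / tot[src]
  }
  market_shares(data.frame(
    market = rep(mkts, times = n_bins),
    age_bin = rep(seq_len(n_bins), each = length(mkts)),
    share = as.vector(share),
    stringsAsFactors = FALSE))
}
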