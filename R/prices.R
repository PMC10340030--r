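#' Price table per (market, age class, NM bin)
#'
#' Smoothed price per straw unit, indexed by the market label, the bull's
#' commercial age class and its net-merit decile bin.
#'
#' @param x A data.frame with columns `market`, `age_class`, `nm_bin`,
#'   `price_usd_per_straw`.
#' @param complete Require every (age_class x nm_bin) cell for every
#'   market present.
#' @return The validated table with class `"price_table"`.
#' @export
price_table <- function(x, complete = TRUE) {
  need <- c("market", "age_class", "nm_bin", "price_usd_per_straw")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("price table needs columns ", paste(need, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  if (!all(x$age_class %in% c("young", "in_waiting", "proven"))) {
    stop("age_class must be young, in_waiting or proven")
  }
  if (!all(x$nm_bin %in% 1:10)) stop("nm_bin must be in 1..10")
  if (any(x$price_usd_per_straw < 0)) stop("prices must be >= 0")
  key <- paste(x$market, x$age_class, x$nm_bin)
  if (anyDuplicated(key)) stop("duplicate (market, age_class, nm_bin) cells")
  if (complete) {
    for (m in unique(x$market)) {
      if (sum(x$market == m) != 30L) {
        stop("market '", m, "' does not cover the full 3 x 10 ",
             "(age_class x nm_bin) grid")
      }
    }
  }
  rownames(x) <- NULL
  class(x) <- c("price_table", "data.frame")
  x
}

#' @rdname price_table
#' @param path CSV file with the `price_table` columns.
#' @export
read_price_table <- function(path, complete = TRUE) {
  price_table(utils::read.csv(path), complete = complete)
}

price_lookup <- function(prices, age_class, nm_bin, market) {
  hit <- prices$market == market & prices$age_class == age_class &
    prices$nm_bin == nm_bin
  if (sum(hit) != 1L) {
    stop("no price for (market=", market, ", age_class=", age_class,
         ", nm_bin=", nm_bin, ")")
  }
  prices$price_usd_per_straw[hit]
}

#' Market shares per (market, age bin)
#'
#' Fraction of straw units from bulls of each age bin directed to each
#' market; shares must sum to 1 within every age bin.
#'
#' @param x A data.frame with columns `market`, `age_bin`, `share`.
#' @return The validated table with class `"market_shares"`.
#' @export
market_shares <- function(x) {
  need <- c("market", "age_bin", "share")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("market shares need columns ", paste(need, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  if (any(x$share < 0)) stop("shares must be >= 0")
  tot <- tapply(x$share, x$age_bin, sum)
  if (any(abs(tot - 1) > 1e-9)) {
    bad <- names(tot)[abs(tot - 1) > 1e-9]
    stop("shares do not sum to 1 in age bin(s) ", paste(bad, collapse = ", "))
  }
  rownames(x) <- NULL
  class(x) <- c("market_shares", "data.frame")
  x
}

#' @rdname market_shares
#' @param path CSV file with the `market_shares` columns.
#' @export
read_market_shares <- function(path) market_shares(utils::read.csv(path))

share_lookup <- function(shares, market, age_bin) {
  hit <- shares$market == market & shares$age_bin == age_bin
  if (sum(hit) != 1L) {
    stop("no market share for (market=", market, ", age_bin=", age_bin, ")")
  }
  shares$share[hit]
}
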