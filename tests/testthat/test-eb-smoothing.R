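make_records <- function(market, age_class, nm_bin, price, units = 100) {
  n <- length(price)
  stem <- paste(market, age_class, nm_bin[1], sep = "-")
  data.frame(order_id = sprintf("%s-O%03d", stem, seq_len(n)),
             market = market,
             bull_id = sprintf("%s-B%03d", stem, seq_len(n)),
             age_class = age_class, nm_bin = nm_bin, units = units,
             blended_price_usd = price, stringsAsFactors = FALSE)
}

test_that("group statistics match hand arithmetic", {
  rec <- sales_records(make_records("A", "young", 1, c(10, 10)))
  gs <- group_stats(rec, "A")
  expect_equal(gs$stats$mean_price, 10)
  expect_equal(gs$stats$var_price, 0)
  expect_equal(gs$stats$se_sq, 0)
  expect_equal(gs$mu, 10)

  rec2 <- sales_records(rbind(make_records("A", "young", 1, c(0, 0)),
                              make_records("A", "proven", 2, c(10, 10))))
  gs2 <- group_stats(rec2, "A")
  expect_equal(gs2$mu, 5)
  expect_equal(gs2$tau_sq, 50)  # sample variance of group means {0, 10}
  expect_equal(group_stats(rec2, "A", tau_method = "all_prices")$tau_sq,
               var(c(0, 0, 10, 10)))
  expect_error(group_stats(rec2, "B"), "no sales records")
})

test_that("singleton groups take market-wide variance and are flagged", {
  rec <- sales_records(rbind(make_records("A", "young", 1, c(8, 10, 12)),
                             make_records("A", "proven", 9, 30)))
  gs <- group_stats(rec, "A")
  single <- gs$stats[gs$stats$n == 1L, ]
  expect_true(single$low_information)
  expect_equal(single$var_price, 0)
  expect_equal(single$se_sq, var(c(8, 10, 12, 30)))
  expect_false(any(gs$stats$low_information[gs$stats$n > 1L]))
})

test_that("shrinkage interpolates between group mean and population mean", {
  st <- data.frame(age_class = "young", nm_bin = 1, n = 4,
                   mean_price = 8, var_price = 16, se_sq = 4)
  expect_equal(shrink_prices(st, mu = 4, tau_sq = 4)$beta, 0.5)
  expect_equal(shrink_prices(st, mu = 4, tau_sq = 4)$shrunk_price, 6)
  # exact group: beta = 1, keeps its mean
  st$se_sq <- 0
  expect_equal(shrink_prices(st, mu = 4, tau_sq = 4)$beta, 1)
  expect_equal(shrink_prices(st, mu = 4, tau_sq = 4)$shrunk_price, 8)
  # no between-group variance: everything collapses to mu
  st$se_sq <- 4
  expect_equal(shrink_prices(st, mu = 4, tau_sq = 0)$beta, 0)
  expect_equal(shrink_prices(st, mu = 4, tau_sq = 0)$shrunk_price, 4)
  # both zero: convention beta = 1
  st$se_sq <- 0
  expect_equal(shrink_prices(st, mu = 4, tau_sq = 0)$beta, 1)
  expect_error(shrink_prices(st, mu = 4, tau_sq = -1), ">= 0")
})

test_that("shrunk prices are convex combinations and preserve order", {
  set.seed(33)
  for (rep in 1:50) {
    st <- data.frame(age_class = "young", nm_bin = 1:5,
                     n = sample(1:50, 5, replace = TRUE),
                     mean_price = runif(5, 0, 40))
    st$var_price <- runif(5, 0, 25)
    st$se_sq <- st$var_price / st$n
    mu <- runif(1, 0, 40)
    tau_sq <- runif(1, 0, 30)
    sh <- shrink_prices(st, mu, tau_sq)
    expect_true(all(sh$beta >= 0 & sh$beta <= 1))
    lo <- pmin(sh$mean_price, mu) - 1e-12
    hi <- pmax(sh$mean_price, mu) + 1e-12
    expect_true(all(sh$shrunk_price >= lo & sh$shrunk_price <= hi))
  }
  # equal uncertainty: ordering of group means survives shrinkage
  st <- data.frame(age_class = "young", nm_bin = 1:2, n = 10,
                   mean_price = c(5, 15), var_price = 10, se_sq = 1)
  sh <- shrink_prices(st, mu = 10, tau_sq = 3)
  expect_lte(sh$shrunk_price[1], sh$shrunk_price[2])
})

test_that("smooth_prices fills missing cells with the market mean", {
  rec <- sales_records(rbind(
    make_records("A", "young", 1, c(10, 12, 14)),
    make_records("A", "proven", 9, c(30, 32, 34))))
  pt <- smooth_prices(rec, outlier_k = NULL)
  expect_s3_class(pt, "price_table")
  expect_equal(nrow(pt), 30)
  filled <- pt[pt$age_class == "in_waiting" & pt$nm_bin == 5, ]
  expect_equal(filled$price_usd_per_straw, mean(c(10, 12, 14, 30, 32, 34)))
})

test_that("outlier filtering drops records far from the market median", {
  prices <- c(rep(c(9, 10, 11, 12), 5), 500)
  rec <- sales_records(make_records("A", "young", 1, prices))
  kept <- filter_price_outliers(rec, k = 3)
  expect_equal(nrow(kept), 20)
  expect_false(any(kept$blended_price_usd == 500))
  # a degenerate IQR keeps everything
  same <- sales_records(make_records("A", "young", 1, rep(10, 5)))
  expect_equal(nrow(filter_price_outliers(same)), 5)
})

test_that("sales validation enforces one blended price per order", {
  rec <- make_records("A", "young", 1, c(10, 20))
  rec$order_id <- "same"
  expect_error(sales_records(rec), "same blended price")
  rec <- make_records("A", "young", 1, 10)
  rec$units <- 0
  expect_error(sales_records(rec), "units")
})

test_that("market shares are unit fractions per age bin", {
  rec <- make_records("A", "young", 1, rep(10, 4))
  rec$age_bin <- c(1, 1, 2, 2)
  rec$units <- c(100, 200, 50, 50)
  ms <- estimate_market_shares(sales_records(rec))
  expect_true(all(ms$share[ms$market == "A"] == 1))

  two <- rbind(rec, transform(make_records("B", "young", 1, rep(8, 2)),
                              age_bin = c(1, 1), units = c(50, 50)))
  ms2 <- estimate_market_shares(sales_records(two))
  expect_equal(ms2$share[ms2$market == "A" & ms2$age_bin == 1], 0.75)
  expect_equal(ms2$share[ms2$market == "B" & ms2$age_bin == 1], 0.25)
  # empty bins inherit the nearest populated bin's shares
  expect_equal(ms2$share[ms2$market == "A" & ms2$age_bin == 19],
               ms2$share[ms2$market == "A" & ms2$age_bin == 2])
  tot <- tapply(ms2$share, ms2$age_bin, sum)
  expect_true(all(abs(tot - 1) < 1e-9))
})

test_that("records without an age bin spread units over their age class", {
  rec <- sales_records(make_records("A", "proven", 5, 10, units = 700))
  ms <- estimate_market_shares(rec)
  expect_true(all(ms$share == 1))  # single market still owns every bin
})
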