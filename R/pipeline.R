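#' Expected TSp deviation from recent collections
#'
#' Averages a bull's relative deviation from the age-bin mean over its
#' most recent (at most) 3 collection months. Schedule means are totals
#' per 4-month bin, so the monthly expectation is the bin mean divided
#' by 4.
#'
#' @param history A data.frame with one row per collection month:
#'   `month` (anything orderable: an index or a date), `age_months` (age
#'   at collection, 10..85) and `total_sperm_billion` (that month's
#'   production).
#' @param schedule An [age_bin_schedule()].
#' @param window Number of most recent months to average (default 3).
#' @return The mean signed fractional deviation (`pdev`).
#' @examples
#' s <- default_schedule()
#' h <- data.frame(month = 1:3, age_months = c(26, 27, 28),
#'                 total_sperm_billion = 366.3 / 4 * c(1.1, 1.2, 1.3))
#' compute_pdev(h, s)  # 0.2
#' @export
compute_pdev <- function(history, schedule, window = 3L) {
  need <- c("month", "age_months", "total_sperm_billion")
  if (!is.data.frame(history) || !all(need %in% names(history))) {
    stop("history needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(history) == 0L) stop("empty collection history")
  if (anyDuplicated(history$month)) stop("collection months must be distinct")
  if (any(history$total_sperm_billion < 0)) stop("TSp must be >= 0")
  history <- history[order(history$month), , drop = FALSE]
  recent <- utils::tail(history, window)
  bins <- months_to_bin(recent$age_months)
  monthly_mean <- schedule$mean_tsp_billion[bins] / 4
  if (any(monthly_mean == 0)) {
    stop("bin mean TSp is 0 at age ",
         paste(recent$age_months[monthly_mean == 0], collapse = ", "),
         " months; deviation undefined")
  }
  mean((recent$total_sperm_billion - monthly_mean) / monthly_mean)
}

#' Assign net-merit decile bins
#'
#' Discretizes NM$ values into decile bins 1..10 relative to a reference
#' population (the herd's own NM$ distribution in the case study) or
#' against explicit bin lower bounds. Bins are lower-inclusive; the top
#' bin is open above. Values below the reference minimum (or first bound)
#' are clamped to bin 1 with a warning, since empirical decile ranges need
#' not cover new bulls.
#'
#' @param nm_values Numeric NM$ values to bin.
#' @param reference Reference NM$ population whose deciles define the
#'   bins; ignored when `boundaries` is given.
#' @param boundaries Explicit lower bounds of bins 2..10 (9 increasing
#'   values).
#' @return Integer bins 1..10.
#' @export
assign_nm_bins <- function(nm_values, reference = NULL, boundaries = NULL) {
  if (is.null(boundaries)) {
    if (is.null(reference) || length(reference) == 0L) {
      stop("either a reference NM$ population or explicit boundaries ",
           "are required")
    }
    boundaries <- stats::quantile(reference, probs = seq(0.1, 0.9, by = 0.1),
                                  names = FALSE, type = 7)
    if (any(nm_values < min(reference))) {
      warning("NM$ value(s) below the reference range; clamped to bin 1")
    }
  } else {
    if (length(boundaries) != 9L) {
      stop("boundaries must give the 9 lower bounds of bins 2..10")
    }
  }
  if (any(diff(boundaries) < 0)) stop("boundaries must be non-decreasing")
  if (any(diff(boundaries) == 0)) {
    warning("degenerate decile boundaries: ties collapse bins")
  }
  as.integer(findInterval(nm_values, boundaries) + 1L)
}

#' Value every bull in a herd against the replacement
#'
#' Runs the full valuation: per-bull NPV, the (single) replacement NPV,
#' their difference `bullval`, a descending rank (ties broken by bull id)
#' and a cull flag for negative values. Bulls whose inputs fail
#' validation are reported in `errors` and excluded from the report;
#' valuation continues for the rest.
#'
#' @param herd A data.frame with columns `bull_id`, `arrival_age_months`,
#'   either `start_age_bin` or `age_months`, either `nm_bin` or
#'   `nm_dollars` (binned against the herd's own NM$ deciles), and
#'   optionally `pdev`.
#' @param schedule An [age_bin_schedule()].
#' @param prices,shares,config See [npv()].
#' @param replacement The reference [bull_profile()].
#' @param histories Optional named list (by `bull_id`) of collection
#'   histories for [compute_pdev()]; used for bulls without a `pdev`
#'   column entry. Bulls with neither take `pdev = 0` with a warning.
#' @return A list of class `"herd_valuation"`: `report` (one row per
#'   bull: profile fields, `npv_bull`, `npv_replacement`, `bullval`,
#'   `rank`, `cull_flag`), `summary` (see [summarize_by_nm_bin()]) and
#'   `errors` (named character vector, possibly empty).
#' @export
value_herd <- function(herd, schedule, prices = NULL, shares = NULL,
                       config = default_econ_config(),
                       replacement = replacement_profile(),
                       histories = NULL) {
  if (!is.data.frame(herd) || !"bull_id" %in% names(herd)) {
    stop("herd must be a data.frame with a bull_id column")
  }
  if (anyDuplicated(herd$bull_id)) stop("bull_id values must be unique")
  n <- nrow(herd)
  if (!"start_age_bin" %in% names(herd)) {
    if (!"age_months" %in% names(herd)) {
      stop("herd needs start_age_bin or age_months")
    }
    herd$start_age_bin <- months_to_bin(herd$age_months)
  }
  if (!"nm_bin" %in% names(herd)) {
    if (!"nm_dollars" %in% names(herd)) {
      stop("herd needs nm_bin or nm_dollars")
    }
    herd$nm_bin <- assign_nm_bins(herd$nm_dollars,
                                  reference = herd$nm_dollars)
  }
  if (!"pdev" %in% names(herd)) herd$pdev <- NA_real_
  missing_pdev <- is.na(herd$pdev)
  if (any(missing_pdev) && !is.null(histories)) {
    for (r in which(missing_pdev)) {
      h <- histories[[as.character(herd$bull_id[r])]]
      if (!is.null(h)) herd$pdev[r] <- compute_pdev(h, schedule)
    }
    missing_pdev <- is.na(herd$pdev)
  }
  if (any(missing_pdev)) {
    warning(sum(missing_pdev), " bull(s) without collection history or ",
            "pdev; assuming average production (pdev = 0)")
    herd$pdev[missing_pdev] <- 0
  }
  npv_rep <- npv(replacement, schedule, prices, shares, config)$npv
  rows <- vector("list", n)
  errors <- character(0)
  for (r in seq_len(n)) {
    id <- as.character(herd$bull_id[r])
    res <- tryCatch({
      prof <- bull_profile(id, herd$start_age_bin[r],
                           herd$arrival_age_months[r], herd$nm_bin[r],
                           herd$pdev[r])
      b <- npv(prof, schedule, prices, shares, config)
      data.frame(bull_id = id, start_age_bin = prof$start_age_bin,
                 arrival_age_months = prof$arrival_age,
                 nm_bin = prof$nm_bin, pdev = prof$pdev,
                 npv_bull = b$npv, npv_replacement = npv_rep,
                 bullval = b$npv - npv_rep,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errors[id] <- res else rows[[r]] <- res
  }
  report <- do.call(rbind, rows)
  if (is.null(report)) stop("no bull could be valued; first error: ",
                            errors[1])
  ord <- order(-report$bullval, report$bull_id)
  report$rank <- NA_integer_
  report$rank[ord] <- seq_len(nrow(report))
  report$cull_flag <- report$bullval < 0
  report <- report[order(report$rank), , drop = FALSE]
  rownames(report) <- NULL
  structure(list(report = report,
                 summary = summarize_by_nm_bin(report),
                 errors = errors),
            class = "herd_valuation")
}

#' @export
print.herd_valuation <- function(x, ...) {
  cat("Herd valuation:", nrow(x$report), "bulls,",
      sum(x$report$cull_flag), "flagged for culling\n")
  if (length(x$errors)) {
    cat(length(x$errors), "bull(s) skipped with errors\n")
  }
  print(utils::head(x$report, 5), ...)
  cat("Summary by NM bin:\n")
  print(x$summary, ...)
  invisible(x)
}

#' Summarize a valuation report by NM decile bin
#'
#' Per NM bin: bull count, mean and SD of the TSp deviation (in %), mean
#' and SD of `bullval`, plus a `Total` row computed over all bulls (its
#' means equal the count-weighted means of the bin means). SDs are 0 for
#' single-bull bins.
#'
#' @param report The per-bull data.frame from [value_herd()].
#' @return A data.frame with one row per NM bin plus a `Total` row.
#' @export
summarize_by_nm_bin <- function(report) {
  one <- function(d, label) {
    data.frame(nm_bin = label, n_bulls = nrow(d),
               mean_pdev_pct = 100 * mean(d$pdev),
               sd_pdev_pct = if (nrow(d) > 1L) 100 * stats::sd(d$pdev) else 0,
               mean_bullval = mean(d$bullval),
               sd_bullval = if (nrow(d) > 1L) stats::sd(d$bullval) else 0,
               stringsAsFactors = FALSE)
  }
  parts <- lapply(split(report, report$nm_bin),
                  function(d) one(d, as.character(d$nm_bin[1])))
  out <- rbind(do.call(rbind, parts), one(report, "Total"))
  rownames(out) <- NULL
  out
}

#' Count-weighted herd averages from a bin-level summary
#'
#' Reconstructs the herd-level averages from per-NM-bin counts and means
#' alone (no per-bull data): the mean NM bin, mean TSp deviation (%), and
#' mean bull value are the count-weighted means of the bin means. This is
#' the arithmetic that ties a published bin-level summary to its `Total`
#' row.
#'
#' @param bin_summary A data.frame with numeric `nm_bin`, a count column
#'   (`n_bulls`) and mean columns `mean_pdev_pct` and `mean_bullval`.
#' @return A list: `n_bulls`, `mean_nm_bin`, `mean_pdev_pct`,
#'   `mean_bullval`.
#' @examples
#' s <- utils::read.csv(system.file("extdata", "herd_nm_summary.csv",
#'                                  package = "bullval"))
#' summarize_total(s)
#' @export
summarize_total <- function(bin_summary) {
  need <- c("nm_bin", "n_bulls", "mean_pdev_pct", "mean_bullval")
  if (!all(need %in% names(bin_summary))) {
    stop("bin summary needs columns ", paste(need, collapse = ", "))
  }
  w <- bin_summary$n_bulls
  if (any(w < 0) || sum(w) == 0) stop("invalid bin counts")
  list(n_bulls = sum(w),
       mean_nm_bin = sum(w * as.numeric(bin_summary$nm_bin)) / sum(w),
       mean_pdev_pct = sum(w * bin_summary$mean_pdev_pct) / sum(w),
       mean_bullval = sum(w * bin_summary$mean_bullval) / sum(w))
}

#' Read a herd table from CSV
#'
#' @param path CSV with columns `bull_id`, `arrival_age_months`, either
#'   `age_months` or `start_age_bin`, either `nm_dollars` or `nm_bin`,
#'   optionally `pdev`.
#' @return A data.frame.
#' @export
read_herd <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a valuation report to CSV
#'
#' One row per bull, followed by a commented `# summary` block with the
#' per-NM-bin summary. Byte-identical output for identical inputs.
#'
#' @param valuation A `"herd_valuation"` from [value_herd()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(valuation, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.csv(valuation$report, con, row.names = FALSE)
  writeLines("# summary", con)
  utils::write.csv(valuation$summary, con, row.names = FALSE)
  invisible(path)
}
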