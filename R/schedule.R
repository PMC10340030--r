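#' Age-bin schedule of a bull stud
#'
#' Builds and validates the age-bin schedule that drives both the Markov
#' chain and the income model: one row per age bin with the bin's month
#' span, the mean total sperm production (TSp, billion cells per bin) of
#' bulls of that age, and the involuntary culling proportion (the Markov
#' exit probability for that bin).
#'
#' The standard stud layout has 19 bins of 4 months covering ages 10 to 85
#' months; bulls surviving to the last bin are culled there, so its culling
#' proportion must be 1. With `strict = FALSE` a schedule with any number
#' of contiguous bins is accepted (the last bin must still cull everything),
#' which is useful for small worked examples.
#'
#' @param x A data.frame with columns `bin`, `start_month`, `end_month`,
#'   `mean_tsp_billion`, `cull_proportion`.
#' @param strict Enforce the standard 19-bin, 10-85 month layout.
#' @return The validated schedule with class `"age_bin_schedule"`.
#' @examples
#' sched <- default_schedule()
#' sched[sched$bin == 5, ]
#' @export
age_bin_schedule <- function(x, strict = TRUE) {
  need <- c("bin", "start_month", "end_month", "mean_tsp_billion",
            "cull_proportion")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("schedule must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  x <- x[order(x$bin), , drop = FALSE]
  rownames(x) <- NULL
  n <- nrow(x)
  if (n < 1L) stop("schedule has no bins")
  if (!identical(as.integer(x$bin), seq_len(n))) {
    stop("bin indices must be 1..", n, " without gaps")
  }
  if (any(x$mean_tsp_billion < 0)) stop("mean_tsp_billion must be >= 0")
  if (any(x$cull_proportion < 0 | x$cull_proportion > 1)) {
    stop("cull_proportion must lie in [0, 1]")
  }
  if (abs(x$cull_proportion[n] - 1) > 1e-12) {
    stop("last bin must have cull_proportion = 1 (all remaining bulls culled)")
  }
  if (any(x$end_month - x$start_month != 3L)) {
    stop("each bin must span 4 months (end_month = start_month + 3)")
  }
  if (any(diff(x$start_month) != 4L)) stop("bins must be contiguous")
  if (strict) {
    if (n != 19L) stop("standard schedule must have exactly 19 bins")
    if (x$start_month[1] != 10L || x$end_month[n] != 85L) {
      stop("standard schedule must span months 10 to 85")
    }
  }
  class(x) <- c("age_bin_schedule", "data.frame")
  x
}

#' Read an age-bin schedule from CSV
#'
#' @param path CSV file with columns
#'   `bin,start_month,end_month,mean_tsp_billion,cull_proportion`.
#' @param strict See [age_bin_schedule()].
#' @return An `age_bin_schedule`.
#' @export
read_age_bin_schedule <- function(path, strict = TRUE) {
  age_bin_schedule(utils::read.csv(path), strict = strict)
}

#' The packaged case-study schedule
#'
#' TSp bin means and involuntary culling proportions estimated from the
#' 2018-2020 production and health records of a commercial AI stud; this is
#' the parameterization used throughout the package examples.
#'
#' @return An `age_bin_schedule` with 19 bins.
#' @export
default_schedule <- function() {
  read_age_bin_schedule(system.file("extdata", "age_bin_schedule.csv",
                                    package = "bullval", mustWork = TRUE))
}

#' Map an age in months to its age bin
#'
#' Bulls enter production at 10 months and any survivor is culled at 85
#' months, so valid ages span 10-85 months, binned in 4-month steps.
#'
#' @param age_months Integer vector of ages in months.
#' @return Integer bin indices in 1..19.
#' @examples
#' months_to_bin(c(10, 26, 85))
#' @export
months_to_bin <- function(age_months) {
  if (!is.numeric(age_months) || anyNA(age_months)) {
    stop("age_months must be numeric and non-missing")
  }
  if (any(age_months < 10 | age_months > 85)) {
    stop("age_months outside the valid span [10, 85] months")
  }
  as.integer((age_months - 10) %/% 4 + 1)
}
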