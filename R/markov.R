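#' Herd state vector
#'
#' A herd state is the vector of proportions of a bull (or of the herd)
#' occupying each age bin at one iteration of the Markov chain.
#'
#' @param proportions Non-negative numeric vector, one entry per bin.
#' @param schedule The `age_bin_schedule` the state refers to.
#' @return The validated proportions vector.
#' @keywords internal
validate_herd_state <- function(proportions, schedule) {
  if (!is.numeric(proportions) || anyNA(proportions)) {
    stop("herd state must be numeric and non-missing")
  }
  if (length(proportions) != nrow(schedule)) {
    stop("herd state length (", length(proportions),
         ") does not match the schedule (", nrow(schedule), " bins)")
  }
  if (any(proportions < 0)) stop("herd state entries must be >= 0")
  as.numeric(proportions)
}

#' Advance the herd one 4-month iteration
#'
#' Survivors of bin `b` move to bin `b + 1`; the mass leaving each bin is
#' its occupancy times the involuntary culling proportion (the last bin
#' culls everything). With `regenerate = TRUE` every exit is replaced by a
#' young bull entering bin 1 in the same iteration, so total herd mass is
#' conserved; with `regenerate = FALSE` culled mass leaves the system.
#'
#' @param state Numeric occupancy vector, one entry per bin.
#' @param schedule An [age_bin_schedule()].
#' @param regenerate Route all exits back into bin 1 (constant herd size).
#' @return The next state vector.
#' @examples
#' s <- default_schedule()
#' step_herd(c(1, rep(0, 18)), s)
#' @export
step_herd <- function(state, schedule, regenerate = TRUE) {
  state <- validate_herd_state(state, schedule)
  cull <- schedule$cull_proportion
  n <- length(state)
  nxt <- numeric(n)
  if (n > 1L) nxt[2:n] <- state[1:(n - 1L)] * (1 - cull[1:(n - 1L)])
  if (regenerate) nxt[1L] <- nxt[1L] + sum(state * cull)
  nxt
}

#' Steady-state age distribution by iteration
#'
#' Iterates the regenerating chain until the maximum absolute change
#' between successive states falls below `tol`. The fixed point is unique
#' and independent of the initial distribution.
#'
#' @param schedule An [age_bin_schedule()].
#' @param init Initial distribution; defaults to all mass in bin 1.
#' @param tol Convergence tolerance on the max-norm change.
#' @param max_iter Iteration cap.
#' @return A list with `proportions` (the steady state) and `n_iterations`.
#' @seealso [steady_state_closed_form()] for the analytic solution.
#' @export
steady_state_iterative <- function(schedule, init = NULL, tol = 1e-12,
                                   max_iter = 100000L) {
  stopifnot(tol > 0, max_iter >= 1)
  n <- nrow(schedule)
  if (is.null(init)) init <- c(1, rep(0, n - 1L))
  state <- validate_herd_state(init, schedule)
  tot <- sum(state)
  if (tot <= 0) stop("initial state has no mass")
  state <- state / tot
  for (i in seq_len(max_iter)) {
    nxt <- step_herd(state, schedule, regenerate = TRUE)
    resid <- max(abs(nxt - state))
    state <- nxt
    if (resid < tol) {
      return(list(proportions = state, n_iterations = i))
    }
  }
  stop("steady state not reached in ", max_iter,
       " iterations; last max-norm change = ", format(resid))
}

#' Closed-form steady-state age distribution
#'
#' The fixed point of the regenerating chain is proportional to the
#' cumulative survival weights w_b = prod_{a<b} (1 - cull_a): bin
#' occupancy is the chance a recruit survives to that bin, normalized so
#' the herd sums to 1.
#'
#' @param schedule An [age_bin_schedule()].
#' @return Steady-state proportions, one per bin.
#' @export
steady_state_closed_form <- function(schedule) {
  surv <- cumprod(c(1, 1 - schedule$cull_proportion[-nrow(schedule)]))
  surv / sum(surv)
}

#' Scale an age distribution to herd counts
#'
#' @param state Proportions vector.
#' @param herd_size Number of bulls in the stud.
#' @return A list with `counts` (rounded half-away-from-zero, as whole
#'   bulls) and `exact` (the unrounded products).
#' @examples
#' scale_to_herd(steady_state_closed_form(default_schedule()), 396)
#' @export
scale_to_herd <- function(state, herd_size) {
  if (!is.numeric(herd_size) || length(herd_size) != 1L || herd_size < 0) {
    stop("herd_size must be a single non-negative number")
  }
  exact <- as.numeric(state) * herd_size
  counts <- as.integer(trunc(abs(exact) + 0.5) * sign(exact))
  list(counts = counts, exact = exact)
}
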