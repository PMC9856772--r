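#' Per-cycle discount factor
#'
#' Continuous monthly compounding of a yearly rate:
#' \eqn{(1+r)^{-t/12}} for cycle index `t`. Equals 1 at cycle 0.
#'
#' @param annual_rate Yearly discount rate, a non-negative fraction.
#' @param cycle_index Cycle index (months), non-negative.
#' @return Discount factor(s).
#' @export
#' @examples
#' discount_factor(0.03, 12)  # one year out: 1/1.03
discount_factor <- function(annual_rate, cycle_index) {
  if (any(annual_rate < 0)) abort_model("negative discount rate")
  if (any(cycle_index < 0)) abort_model("negative cycle index")
  (1 + annual_rate)^(-cycle_index / 12)
}

#' Run the deterministic Markov cohort simulation
#'
#' Propagates a state-occupancy vector through the transition matrix for
#' `horizon_cycles` monthly cycles, recording the occupancy at every cycle and
#' the full matrix of transition flows (the fraction of the cohort moving from
#' each state to each other state during each cycle). Flows are what event
#' costs and event counts are accounted against.
#'
#' @param P Transition matrix (validated before simulation).
#' @param initial_state Name of the state holding the cohort at cycle 0.
#' @param horizon_cycles Number of cycles, at least 1.
#' @return An object of class `dfu_trace`: list with `occupancy`
#'   (`(horizon+1) x n` matrix, row `t+1` = occupancy after cycle `t`) and
#'   `flows` (`n x n x horizon` array, `flows[i, j, t]` = cohort fraction
#'   moving i to j during cycle `t`).
#' @export
run_cohort <- function(P, initial_state, horizon_cycles) {
  validate_transition_matrix(P)
  st <- rownames(P)
  if (!initial_state %in% st) abort_model("unknown initial state '%s'", initial_state)
  horizon_cycles <- as.integer(horizon_cycles)
  if (horizon_cycles < 1L) abort_model("horizon must be at least one cycle")
  n <- length(st)
  occ <- matrix(0, horizon_cycles + 1L, n,
                dimnames = list(paste0("cycle", 0:horizon_cycles), st))
  occ[1L, initial_state] <- 1
  flows <- array(0, c(n, n, horizon_cycles), dimnames = list(st, st, NULL))
  v <- occ[1L, ]
  for (t in seq_len(horizon_cycles)) {
    flows[, , t] <- P * v          # row i scaled by occupancy of i
    v <- as.vector(v %*% P)
    occ[t + 1L, ] <- v
  }
  structure(list(occupancy = occ, flows = flows,
                 initial_state = initial_state, horizon = horizon_cycles),
            class = "dfu_trace")
}

#' @export
print.dfu_trace <- function(x, ...) {
  cat(sprintf("<dfu_trace> %d cycles from '%s'; final occupancy:\n",
              x$horizon, x$initial_state))
  print(round(x$occupancy[nrow(x$occupancy), ], 4))
  invisible(x)
}

#' Export a cohort trace as a tidy data frame
#'
#' @param trace A `dfu_trace`.
#' @return `data.frame` with columns `cycle`, `state`, `occupancy`.
#' @export
trace_to_df <- function(trace) {
  occ <- trace$occupancy
  data.frame(cycle = rep(0:trace$horizon, times = ncol(occ)),
             state = rep(colnames(occ), each = nrow(occ)),
             occupancy = as.vector(occ))
}

#' Accumulate discounted costs, life-years and QALYs along a cohort trace
#'
#' Per cycle `t` (discount factor \eqn{d_t}), the accumulators add
#' \eqn{d_t [\sum_s w_s c_s + \sum_{i \ne j} f_{ij} e_{ij} + c_{drug}
#' \sum_{s \in D} w_s]} to cost, \eqn{d_t \sum_s w_s u_s / 12} to QALYs, and
#' \eqn{d_t (1 - w_{death}) / 12} to life-years, where `w` is the end-of-cycle
#' occupancy or, with `settings$half_cycle = TRUE`, the mean of the start- and
#' end-of-cycle occupancies (trapezoid half-cycle correction). Event costs are
#' charged against transition flows, the one-time initial cost at cycle 0
#' undiscounted. Drug cost accrues while the cohort occupies the strategy's
#' drug states, up to the strategy's cycle cap. Mean months per state are
#' undiscounted end-of-cycle occupancy sums.
#'
#' @param trace A [run_cohort()] trace.
#' @param params The `dfu_params` the matrix was built from.
#' @param strategy The [strategy_config()] of this arm.
#' @return Object of class `dfu_arm_outcome`: `total_cost`, `life_years`,
#'   `qalys` (all discounted), `mean_months_in_state`, `cumulative_probability`
#'   (occupancy at horizon), and a `cost_components` breakdown (`initial`,
#'   `state`, `event`, `drug`).
#' @export
accumulate_outcomes <- function(trace, params, strategy) {
  st <- params$states
  if (!identical(colnames(trace$occupancy), st)) {
    abort_model("trace and parameter set use different state sets")
  }
  h <- trace$horizon
  dth <- params$death_state
  live <- setdiff(st, dth)
  util <- vapply(st, function(s) if (s == dth) 0 else params$utilities[[s]]$base,
                 numeric(1))
  sc <- vapply(st, function(s) if (s == dth) 0 else params$state_costs[[s]]$base,
               numeric(1))
  EC <- event_cost_matrix(params)
  drug_cost <- params$drug$monthly_cost$base
  drug_states <- strategy$drug_cost_states
  cap <- strategy$drug_cap_cycles %||% Inf

  half <- isTRUE(params$settings$half_cycle)
  d <- discount_factor(params$discount_rate_annual, seq_len(h))
  occ <- trace$occupancy
  w <- occ[-1L, , drop = FALSE]                       # end-of-cycle occupancy
  if (half) w <- (w + occ[-nrow(occ), , drop = FALSE]) / 2

  state_cost <- sum(d * (w %*% sc))
  qalys <- sum(d * (w %*% util)) / 12
  life_years <- sum(d * (1 - w[, dth])) / 12
  event_cost <- sum(d * vapply(seq_len(h),
                               function(t) sum(trace$flows[, , t] * EC),
                               numeric(1)))
  drug <- 0
  if (length(drug_states) > 0L && drug_cost > 0) {
    in_drug <- rowSums(w[, drug_states, drop = FALSE])
    tmax <- min(h, cap)
    if (tmax >= 1L) drug <- drug_cost * sum(d[seq_len(tmax)] * in_drug[seq_len(tmax)])
  }
  total <- params$initial_cost$base + state_cost + event_cost + drug

  mm <- colSums(occ[-1L, , drop = FALSE])
  structure(list(
    strategy = strategy$label,
    total_cost = total, life_years = life_years, qalys = qalys,
    mean_months_in_state = mm,
    cumulative_probability = occ[nrow(occ), ],
    cost_components = c(initial = params$initial_cost$base, state = state_cost,
                        event = event_cost, drug = drug)),
    class = "dfu_arm_outcome")
}

# one-time event costs as a from x to matrix (base-case values);
# events are state changes, so self-transitions never carry an event cost
event_cost_matrix <- function(params) {
  st <- params$states
  EC <- matrix(0, length(st), length(st), dimnames = list(st, st))
  for (ec in params$event_costs) {
    EC[ec$from, ec$to] <- EC[ec$from, ec$to] + ec$cost$base
  }
  diag(EC) <- 0
  EC
}

#' @export
print.dfu_arm_outcome <- function(x, ...) {
  cat(sprintf("<dfu_arm_outcome> %s: cost %.0f, LY %.4f, QALY %.4f\n",
              x$strategy, x$total_cost, x$life_years, x$qalys))
  invisible(x)
}

#' Compare two strategy outcomes
#'
#' Computes incremental cost and QALYs, the incremental cost-effectiveness
#' ratio, the dominance quadrant, and per-strategy net monetary benefit at
#' each willingness-to-pay threshold (\eqn{NMB(\lambda) = \lambda Q - C}).
#' When the intervention is cheaper and more effective the result carries the
#' `"dominant"` flag instead of presenting a negative ratio; the mirror case
#' is `"dominated"`; a zero QALY difference leaves the ICER undefined.
#'
#' @param intervention,comparator `dfu_arm_outcome` objects.
#' @param wtp_list Willingness-to-pay thresholds (currency/QALY).
#' @return Object of class `dfu_ce_result` with `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` unless the ratio is meaningful), `status` (one of
#'   `"icer"`, `"dominant"`, `"dominated"`, `"undefined"`), and `nmb`
#'   (strategies x thresholds matrix).
#' @export
compute_icer <- function(intervention, comparator, wtp_list = c(32787, 98361)) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$qalys - comparator$qalys
  if (dq == 0) {
    status <- "undefined"; icer <- NA_real_
  } else if (dc <= 0 && dq > 0) {
    status <- "dominant"; icer <- dc / dq
  } else if (dc >= 0 && dq < 0) {
    status <- "dominated"; icer <- dc / dq
  } else {
    status <- "icer"; icer <- dc / dq
  }
  nmb <- rbind(comparator   = wtp_list * comparator$qalys - comparator$total_cost,
               intervention = wtp_list * intervention$qalys - intervention$total_cost)
  colnames(nmb) <- format(wtp_list, trim = TRUE)
  rownames(nmb) <- c(comparator$strategy, intervention$strategy)
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 status = status, nmb = nmb,
                 intervention = intervention, comparator = comparator),
            class = "dfu_ce_result")
}

#' @export
print.dfu_ce_result <- function(x, ...) {
  cat(sprintf("<dfu_ce_result> dCost %.0f, dQALY %.4f: %s\n",
              x$delta_cost, x$delta_qaly,
              switch(x$status,
                     icer = sprintf("ICER %.0f/QALY", x$icer),
                     dominant = "intervention dominant (cost-saving, more effective)",
                     dominated = "intervention dominated",
                     undefined = "ICER undefined (no QALY difference)")))
  invisible(x)
}

#' Run one strategy arm of a model
#'
#' Builds the strategy matrix, runs the cohort and accumulates outcomes.
#'
#' @param params A `dfu_params`.
#' @param strategy A [strategy_config()].
#' @param horizon_cycles Optional horizon override.
#' @return A `dfu_arm_outcome`. The trace is attached as attribute `"trace"`.
#' @export
run_strategy <- function(params, strategy, horizon_cycles = NULL) {
  P <- build_transition_matrix(params, strategy)
  trace <- run_cohort(P, params$initial_state,
                      horizon_cycles %||% params$horizon_cycles)
  out <- accumulate_outcomes(trace, params, strategy)
  attr(out, "trace") <- trace
  out
}

#' Run the full two-arm base-case comparison
#'
#' Runs the comparator (first strategy) and intervention (second strategy)
#' over the model horizon and compares them.
#'
#' @param params A `dfu_params` with two strategies.
#' @return Object of class `dfu_basecase`: list with `arms` (named list of
#'   `dfu_arm_outcome`) and `ce` (the [compute_icer()] result).
#' @export
#' @examples
#' bc <- run_base_case(load_paper_parameters())
#' bc
run_base_case <- function(params) {
  if (length(params$strategies) < 2L) {
    abort_model("base case needs a comparator and an intervention strategy")
  }
  comp <- run_strategy(params, params$strategies[[1L]])
  intv <- run_strategy(params, params$strategies[[2L]])
  ce <- compute_icer(intv, comp, params$wtp_thresholds)
  structure(list(arms = stats::setNames(list(comp, intv),
                                        c(comp$strategy, intv$strategy)),
                 ce = ce, params_name = params$name),
            class = "dfu_basecase")
}

#' @export
print.dfu_basecase <- function(x, ...) {
  cat(sprintf("<dfu_basecase> %s\n", x$params_name))
  for (a in x$arms) {
    cat(sprintf("  %-12s cost %8.0f  LY %.4f  QALY %.4f\n",
                a$strategy, a$total_cost, a$life_years, a$qalys))
  }
  print(x$ce)
  invisible(x)
}
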