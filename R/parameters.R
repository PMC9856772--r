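#' Describe the sampling distribution of a model parameter
#'
#' Every uncertain parameter carries a base-case value, a plausible range and
#' a distribution family used by the probabilistic sensitivity analysis. The
#' range doubles as the variation interval of the deterministic sensitivity
#' analysis.
#'
#' @param base Base-case value.
#' @param low,high Range bounds, `low <= base <= high`.
#' @param family One of `"beta"`, `"uniform"`, `"triangular"`, `"lognormal"`.
#' @return An object of class `param_dist`.
#' @export
param_dist <- function(base, low = base, high = base,
                       family = c("beta", "uniform", "triangular", "lognormal")) {
  family <- match.arg(family)
  if (!is.numeric(base) || !is.numeric(low) || !is.numeric(high)) {
    abort_model("param_dist(): base/low/high must be numeric")
  }
  if (low > base || base > high) {
    abort_model("param_dist(): need low <= base <= high, got (%g, %g, %g)",
                low, base, high)
  }
  structure(list(base = base, low = low, high = high, family = family),
            class = "param_dist")
}

#' @export
print.param_dist <- function(x, ...) {
  cat(sprintf("%g (%g-%g), %s\n", x$base, x$low, x$high, x$family))
  invisible(x)
}

#' Assemble a complete model parameterization
#'
#' A `parameter_set` is one numeric instantiation of the state-transition
#' model: the printed per-cycle transition rows (with ranges and distribution
#' families), an interpretation configuration resolving structurally ambiguous
#' rows (see [expand_transitions()]), yearly health utilities, monthly state
#' costs, one-time event costs with their triggering transitions, the monthly
#' drug cost and its accrual rule, the treatment effect size, discounting and
#' horizon settings, and the strategy definitions compared by
#' [run_base_case()].
#'
#' @param states Character vector of state names.
#' @param transitions `data.frame` with columns `from`, `to`, and a
#'   `param_dist` in the list-column `value` (or numeric `base`, `low`,
#'   `high`, `family` columns).
#' @param utilities Named list of `param_dist`, one per live state, utility
#'   per year in `[0, 1]`. The death state is fixed at 0.
#' @param state_costs Named list of `param_dist`, cost per monthly cycle.
#' @param event_costs List of event-cost rules; each rule is a list with
#'   `name`, `from` (character vector of source states), `to` (single target
#'   state), and `cost` (a `param_dist`). The cost is charged once per
#'   transition from any listed source into the target.
#' @param initial_cost `param_dist`: one-time cost charged at cycle 0.
#' @param drug List with `monthly_cost` (`param_dist`), `states` (states in
#'   which the drug cost accrues), `cap_cycles` (`Inf` for no cap).
#' @param effect List with `or` (`param_dist`), `target` (list with `from`,
#'   `to`: the single transition the effect modifies), and `scale`
#'   (`"odds"` or `"rate"`).
#' @param interpretation List of interpretation tags for the ambiguous printed
#'   rows; see [expand_transitions()]. Defaults to the literal reading.
#' @param discount_rate_annual Yearly discount rate (fraction), applied as
#'   \eqn{(1+r)^{-t/12}} per monthly cycle.
#' @param horizon_cycles Number of monthly cycles simulated.
#' @param wtp_thresholds Willingness-to-pay thresholds, currency per QALY.
#' @param initial_state State holding the whole cohort at cycle 0.
#' @param death_state Name of the absorbing death state.
#' @param strategies Named list of [strategy_config()] objects; the first is
#'   taken as the comparator, the second as the intervention.
#' @param settings List of engine settings. `half_cycle = TRUE` applies a
#'   trapezoid (half-cycle) correction to state-occupancy rewards.
#' @param name Optional model label.
#' @return An object of class `dfu_params`.
#' @export
parameter_set <- function(states,
                          transitions,
                          utilities,
                          state_costs,
                          event_costs = list(),
                          initial_cost = param_dist(0),
                          drug = list(monthly_cost = param_dist(0),
                                      states = character(), cap_cycles = Inf),
                          effect = list(or = param_dist(1),
                                        target = NULL, scale = "odds"),
                          interpretation = default_interpretation(),
                          discount_rate_annual = 0.03,
                          horizon_cycles = 60L,
                          wtp_thresholds = c(32787, 98361),
                          initial_state = states[[1]],
                          death_state = "death",
                          strategies = NULL,
                          settings = list(half_cycle = FALSE),
                          name = "model") {
  transitions <- normalize_transitions(transitions)
  if (is.null(strategies)) {
    strategies <- list(
      comparator   = strategy_config("comparator", apply_healing_or = FALSE),
      intervention = strategy_config("intervention", apply_healing_or = TRUE,
                                     drug_cost_states = drug$states)
    )
  }
  if (is.null(settings$half_cycle)) settings$half_cycle <- FALSE
  x <- structure(
    list(states = states, transitions = transitions, utilities = utilities,
         state_costs = state_costs, event_costs = event_costs,
         initial_cost = initial_cost, drug = drug, effect = effect,
         interpretation = interpretation,
         discount_rate_annual = discount_rate_annual,
         horizon_cycles = as.integer(horizon_cycles),
         wtp_thresholds = wtp_thresholds,
         initial_state = initial_state, death_state = death_state,
         strategies = strategies, settings = settings, name = name),
    class = "dfu_params")
  validate_parameter_set(x)
  x
}

# accept either a list-column of param_dist or base/low/high/family columns
normalize_transitions <- function(tr) {
  if (!is.data.frame(tr)) abort_model("transitions must be a data.frame")
  if (!all(c("from", "to") %in% names(tr))) {
    abort_model("transitions need 'from' and 'to' columns")
  }
  if (!"value" %in% names(tr)) {
    if (!"base" %in% names(tr)) abort_model("transitions need 'value' or 'base'")
    if (!"low" %in% names(tr)) tr$low <- tr$base
    if (!"high" %in% names(tr)) tr$high <- tr$base
    if (!"family" %in% names(tr)) tr$family <- rep("beta", nrow(tr))
    tr$value <- mapply(function(b, l, h, f) param_dist(b, l, h, f),
                       tr$base, tr$low, tr$high, tr$family, SIMPLIFY = FALSE)
  }
  tr[, c("from", "to", "value")]
}

#' Default (literal) interpretation of the printed transition rows
#'
#' @return List of interpretation tags; see [expand_transitions()].
#' @export
default_interpretation <- function() {
  list(healed_recurrence = "direct",
       idfu_self         = "self-redundant",
       postamp_gangrene  = "direct")
}

#' Validate a parameter set
#'
#' Checks the invariants of a model parameterization: probabilities in
#' `[0, 1]`, utilities in `[0, 1]`, non-negative costs, positive effect size,
#' non-negative discount rate, a horizon of at least one cycle, no transition
#' out of the death state, and that every referenced state exists. The
#' expanded transition rows must leave a non-negative residual self-transition
#' in every state; a violation names the offending row.
#'
#' @param params A `dfu_params` object.
#' @return `params`, invisibly; errors describe the first violated invariant.
#' @export
validate_parameter_set <- function(params) {
  st <- params$states
  if (anyDuplicated(st)) abort_model("duplicate state names")
  if (!params$death_state %in% st) abort_model("death state missing from state set")
  if (!params$initial_state %in% st) abort_model("initial state missing from state set")
  tr <- params$transitions
  assert_states(tr$from, st, "from-state")
  assert_states(tr$to, st, "to-state")
  if (any(tr$from == params$death_state)) {
    abort_model("transitions out of the absorbing death state are not allowed")
  }
  for (i in seq_len(nrow(tr))) {
    v <- tr$value[[i]]
    if (v$base < 0 || v$base > 1 || v$low < 0 || v$high > 1) {
      abort_model("transition %s -> %s: probability outside [0, 1]",
                  tr$from[i], tr$to[i])
    }
  }
  live <- setdiff(st, params$death_state)
  for (s in live) {
    if (is.null(params$utilities[[s]])) abort_model("missing utility for state %s", s)
    u <- params$utilities[[s]]
    if (u$base < 0 || u$base > 1) abort_model("utility of %s outside [0, 1]", s)
    if (is.null(params$state_costs[[s]])) abort_model("missing state cost for state %s", s)
    if (params$state_costs[[s]]$base < 0) abort_model("negative state cost for %s", s)
  }
  for (ec in params$event_costs) {
    assert_states(ec$from, st, "event-cost source state")
    assert_states(ec$to, st, "event-cost target state")
    if (ec$cost$base < 0) abort_model("negative event cost '%s'", ec$name)
  }
  if (params$initial_cost$base < 0) abort_model("negative initial event cost")
  if (params$drug$monthly_cost$base < 0) abort_model("negative drug cost")
  assert_states(params$drug$states, st, "drug accrual state")
  if (params$effect$or$base <= 0) abort_model("effect size must be positive")
  if (!params$effect$scale %in% c("odds", "rate")) {
    abort_model("effect scale must be 'odds' or 'rate'")
  }
  if (params$discount_rate_annual < 0) abort_model("negative discount rate")
  if (params$horizon_cycles < 1L) abort_model("horizon must be at least one cycle")
  # residual feasibility under the configured interpretation, both arms
  for (strat in params$strategies) {
    build_transition_matrix(params, strat)
  }
  invisible(params)
}

#' @export
print.dfu_params <- function(x, ...) {
  cat(sprintf("<dfu_params> %s: %d states, %d printed transition rows\n",
              x$name, length(x$states), nrow(x$transitions)))
  cat(sprintf("  horizon %d monthly cycles, discount %.1f%%/y, WTP %s\n",
              x$horizon_cycles, 100 * x$discount_rate_annual,
              paste(format(x$wtp_thresholds, big.mark = " "), collapse = " / ")))
  cat(sprintf("  effect: %s %g (%g-%g) on %s->%s, %s scale\n",
              "OR", x$effect$or$base, x$effect$or$low, x$effect$or$high,
              x$effect$target$from, x$effect$target$to, x$effect$scale))
  cat(sprintf("  interpretation: %s\n",
              paste(names(x$interpretation), unlist(x$interpretation),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# look up the base value of a printed transition row, NULL if absent
transition_base <- function(params, from, to) {
  tr <- params$transitions
  i <- which(tr$from == from & tr$to == to)
  if (length(i) == 0L) return(NULL)
  tr$value[[i[1]]]$base
}
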