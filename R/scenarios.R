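#' Define a scenario
#'
#' A scenario is a named set of overrides applied on top of the base model:
#' the simulation horizon, the discount rate, the treatment effect size (e.g.
#' a subgroup-specific odds ratio), the drug cost, or any named scalar
#' parameter ([list_parameters()]).
#'
#' @param name Scenario label.
#' @param overrides Named list. Recognized keys: `horizon_cycles`,
#'   `discount_rate_annual`, `healing_or`, `drug_cost_monthly`, plus any
#'   parameter name accepted by [set_parameter()].
#' @param description Optional free-text description.
#' @return Object of class `dfu_scenario`.
#' @export
scenario <- function(name, overrides = list(), description = "") {
  stopifnot(is.list(overrides))
  structure(list(name = name, overrides = overrides, description = description),
            class = "dfu_scenario")
}

#' Run a scenario
#'
#' Applies the scenario's overrides to a copy of the base model and returns
#' the full two-arm comparison. The base model is left untouched.
#'
#' @param base_model A `dfu_params`.
#' @param scen A [scenario()], or a bare named list of overrides.
#' @return A `dfu_basecase` for the overridden model.
#' @export
#' @examples
#' m <- load_paper_parameters()
#' run_scenario(m, scenario("1-year horizon", list(horizon_cycles = 12)))$ce
run_scenario <- function(base_model, scen) {
  if (!inherits(scen, "dfu_scenario")) scen <- scenario("scenario", scen)
  p <- base_model
  for (key in names(scen$overrides)) {
    val <- scen$overrides[[key]]
    if (key == "horizon_cycles") {
      p$horizon_cycles <- as.integer(val)
    } else if (key == "discount_rate_annual") {
      p$discount_rate_annual <- val
    } else if (key == "healing_or") {
      p$effect$or$base <- val
    } else if (key == "drug_cost_monthly") {
      p$drug$monthly_cost$base <- val
    } else {
      p <- set_parameter(p, key, val)   # errors list the valid names
    }
  }
  validate_parameter_set(p)
  out <- run_base_case(p)
  out$scenario <- scen$name
  out
}

#' Two-stage cross-setting cost adaptation
#'
#' Adapts cost estimates from a source setting to the target setting: each
#' cost is converted to the target currency at `fx_rate`, inflated to the
#' target price year by the medical consumer-price-index ratio, and scaled by
#' an anchor ratio computed from cost categories available in both settings
#' (target-setting over source-setting estimates). All three factors enter
#' multiplicatively, so their order is immaterial.
#'
#' @param source_costs Named numeric vector of costs in the source
#'   currency-year.
#' @param fx_rate Target currency units per source currency unit (> 0).
#' @param cpi_ratio Price-index ratio source-year to target-year (> 0).
#' @param anchor_ratio Dimensionless target/source cost ratio (> 0).
#' @return Named numeric vector of adapted costs.
#' @export
#' @examples
#' adapt_costs(c(dressing = 100), fx_rate = 0.7, cpi_ratio = 1.1,
#'             anchor_ratio = 0.5)
adapt_costs <- function(source_costs, fx_rate, cpi_ratio, anchor_ratio) {
  if (!is.numeric(source_costs)) abort_model("source costs must be numeric")
  for (f in c(fx_rate = fx_rate, cpi_ratio = cpi_ratio, anchor_ratio = anchor_ratio)) {
    if (!is.finite(f) || f <= 0) abort_model("all adaptation factors must be positive")
  }
  source_costs * fx_rate * cpi_ratio * anchor_ratio
}
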