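#' Define a treatment strategy
#'
#' A strategy states whether the relative healing effect is applied to the
#' target transition, in which states the drug cost accrues, for how many
#' cycles at most, and on which scale the effect size is carried onto the
#' transition probability.
#'
#' @param label Strategy name (e.g. `"GWC"`, `"ON101+GWC"`).
#' @param apply_healing_or Logical; apply the model's effect size to the
#'   target transition? Only the intervention strategy should set this.
#' @param drug_cost_states States in which the monthly drug cost accrues.
#'   Empty for a strategy without drug cost.
#' @param drug_cap_cycles Maximum number of cycles with drug cost accrual
#'   (`Inf` = uncapped).
#' @param effect_scale `"odds"` (default) or `"rate"`; see
#'   [apply_effect_size()]. `NULL` defers to the model's `effect$scale`.
#' @return An object of class `dfu_strategy`.
#' @export
strategy_config <- function(label,
                            apply_healing_or = FALSE,
                            drug_cost_states = character(),
                            drug_cap_cycles = Inf,
                            effect_scale = NULL) {
  stopifnot(is.character(label), length(label) == 1L,
            is.logical(apply_healing_or))
  if (!is.null(effect_scale) && !effect_scale %in% c("odds", "rate")) {
    abort_model("effect_scale must be 'odds' or 'rate'")
  }
  structure(list(label = label,
                 apply_healing_or = isTRUE(apply_healing_or),
                 drug_cost_states = drug_cost_states,
                 drug_cap_cycles = drug_cap_cycles,
                 effect_scale = effect_scale),
            class = "dfu_strategy")
}

#' @export
print.dfu_strategy <- function(x, ...) {
  cat(sprintf("<dfu_strategy> %s: effect %s, drug in {%s}%s\n", x$label,
              if (x$apply_healing_or) "applied" else "not applied",
              paste(x$drug_cost_states, collapse = ", "),
              if (is.finite(x$drug_cap_cycles))
                sprintf(", capped at %d cycles", x$drug_cap_cycles) else ""))
  invisible(x)
}
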