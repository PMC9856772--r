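# Named access to every scalar model parameter.
# Naming scheme: "from->to" (transition probabilities), "utility.state",
# "cost.state", "event.name", "initial_cost", "drug.monthly_cost", "effect.or".

#' List the model's named scalar parameters
#'
#' @param params A `dfu_params`.
#' @return `data.frame` with `parameter`, `base`, `low`, `high`, `family`.
#' @export
list_parameters <- function(params) {
  out <- list()
  tr <- params$transitions
  for (i in seq_len(nrow(tr))) {
    out[[paste0(tr$from[i], "->", tr$to[i])]] <- tr$value[[i]]
  }
  for (s in names(params$utilities)) out[[paste0("utility.", s)]] <- params$utilities[[s]]
  for (s in names(params$state_costs)) out[[paste0("cost.", s)]] <- params$state_costs[[s]]
  for (ec in params$event_costs) out[[paste0("event.", ec$name)]] <- ec$cost
  out[["initial_cost"]] <- params$initial_cost
  out[["drug.monthly_cost"]] <- params$drug$monthly_cost
  out[["effect.or"]] <- params$effect$or
  data.frame(parameter = names(out),
             base = vapply(out, function(d) d$base, numeric(1)),
             low = vapply(out, function(d) d$low, numeric(1)),
             high = vapply(out, function(d) d$high, numeric(1)),
             family = vapply(out, function(d) d$family, character(1)),
             row.names = NULL)
}

#' Set one named parameter's base-case value
#'
#' @param params A `dfu_params`.
#' @param name Parameter name as listed by [list_parameters()].
#' @param value New base value.
#' @return Modified copy of `params`.
#' @export
set_parameter <- function(params, name, value) {
  p <- params
  if (grepl("->", name, fixed = TRUE)) {
    ft <- strsplit(name, "->", fixed = TRUE)[[1]]
    i <- which(p$transitions$from == ft[1] & p$transitions$to == ft[2])
    if (length(i) == 0L) stop_unknown_param(params, name)
    p$transitions$value[[i[1]]]$base <- value
  } else if (startsWith(name, "utility.")) {
    s <- sub("^utility\\.", "", name)
    if (is.null(p$utilities[[s]])) stop_unknown_param(params, name)
    p$utilities[[s]]$base <- value
  } else if (startsWith(name, "cost.")) {
    s <- sub("^cost\\.", "", name)
    if (is.null(p$state_costs[[s]])) stop_unknown_param(params, name)
    p$state_costs[[s]]$base <- value
  } else if (startsWith(name, "event.")) {
    nm <- sub("^event\\.", "", name)
    hit <- FALSE
    for (i in seq_along(p$event_costs)) {
      if (p$event_costs[[i]]$name == nm) {
        p$event_costs[[i]]$cost$base <- value; hit <- TRUE
      }
    }
    if (!hit) stop_unknown_param(params, name)
  } else if (name == "initial_cost") {
    p$initial_cost$base <- value
  } else if (name == "drug.monthly_cost") {
    p$drug$monthly_cost$base <- value
  } else if (name == "effect.or") {
    p$effect$or$base <- value
  } else {
    stop_unknown_param(params, name)
  }
  p
}

stop_unknown_param <- function(params, name) {
  abort_model("unknown parameter '%s'; valid names:\n  %s", name,
              paste(list_parameters(params)$parameter, collapse = ", "))
}
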