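#' Expand printed transition rows under an interpretation configuration
#'
#' Several published per-cycle transition values admit more than one
#' structural reading. The interpretation configuration makes each reading
#' explicit and machine-checkable; [calibrate_structure()] selects the
#' configuration that best reproduces the published outcome profile.
#'
#' Interpretation tags (all default to the literal reading):
#' \describe{
#'   \item{`healed_recurrence`}{Reading of the healed-state exit rows
#'     (`healed -> uDFU`, the printed "progression" value, and
#'     `healed -> iDFU`).
#'     `"direct"`: both used as printed.
#'     `"conditional-split"`: the progression value is the total recurrence
#'     probability and the second value is the infected share, giving
#'     `healed -> uDFU = p(1 - s)` and `healed -> iDFU = p s`.
#'     `"total-to-uDFU"`: the progression value is the marginal probability of
#'     an uninfected recurrence and the second value the infected share among
#'     recurrences; every recurrence re-enters the uninfected-ulcer state
#'     (total `p / (1 - s)`), and subsequent infection is carried by the
#'     modelled `uDFU -> iDFU` pathway, so no direct `healed -> iDFU` edge.}
#'   \item{`idfu_self`}{Reading of the printed `iDFU -> iDFU` value.
#'     `"self-redundant"`: a redundant restatement of the residual
#'     self-transition; the row is dropped.
#'     `"exit-to-healed"`/`"exit-to-uDFU"`: the value is a mislabelled exit.
#'     `"printed-self-residual-healed"`/`"printed-self-residual-uDFU"`: the
#'     value *is* the self-transition probability and the unlisted residual
#'     leaves the state (to healed, i.e. infection resolution, or to uDFU).}
#'   \item{`postamp_gangrene`}{Reading of the `postamputation -> gangrene`
#'     value together with `postamputation -> iDFU`.
#'     `"direct"`: as printed.
#'     `"conditional-split"`: the iDFU value is the total post-amputation
#'     complication probability, the gangrene value its gangrenous share.
#'     `"conditional-product"`: the gangrene probability is the product of
#'     the two printed values, the iDFU row as printed.}
#' }
#'
#' @param params A `dfu_params` object.
#' @return List with `edges` (data.frame `from`, `to`, `prob` of effective
#'   direct transition probabilities; an explicit self edge fixes that state's
#'   self-transition) and `residual_to` (named character vector: for listed
#'   states the unallocated probability mass flows to the named destination
#'   instead of the default self-transition).
#' @export
expand_transitions <- function(params) {
  tr <- params$transitions
  edges <- data.frame(from = tr$from, to = tr$to,
                      prob = vapply(tr$value, function(v) v$base, numeric(1)),
                      stringsAsFactors = FALSE)
  residual_to <- character(0)
  ip <- params$interpretation

  drop_edge <- function(e, from, to) e[!(e$from == from & e$to == to), ]
  set_edge <- function(e, from, to, p) {
    i <- which(e$from == from & e$to == to)
    if (length(i) > 0L) e$prob[i[1]] <- p
    else e <- rbind(e, data.frame(from = from, to = to, prob = p,
                                  stringsAsFactors = FALSE))
    e
  }
  get_prob <- function(e, from, to) {
    i <- which(e$from == from & e$to == to)
    if (length(i) > 0L) e$prob[i[1]] else NULL
  }

  ## healed-state recurrence rows
  hr <- ip$healed_recurrence %||% "direct"
  p_rec <- get_prob(edges, "healed", "uDFU")
  s_inf <- get_prob(edges, "healed", "iDFU")
  if (hr != "direct" && !is.null(p_rec) && !is.null(s_inf)) {
    if (hr == "conditional-split") {
      edges <- set_edge(edges, "healed", "uDFU", p_rec * (1 - s_inf))
      edges <- set_edge(edges, "healed", "iDFU", p_rec * s_inf)
    } else if (hr == "total-to-uDFU") {
      edges <- set_edge(edges, "healed", "uDFU", p_rec / (1 - s_inf))
      edges <- drop_edge(edges, "healed", "iDFU")
    } else {
      abort_model("unknown healed_recurrence interpretation '%s'", hr)
    }
  }

  ## iDFU self row
  is_mode <- ip$idfu_self %||% "self-redundant"
  p_self <- get_prob(edges, "iDFU", "iDFU")
  if (!is.null(p_self)) {
    edges <- drop_edge(edges, "iDFU", "iDFU")
    if (is_mode == "self-redundant") {
      # value restates the residual; nothing to add
    } else if (is_mode == "exit-to-healed") {
      edges <- set_edge(edges, "iDFU", "healed", p_self)
    } else if (is_mode == "exit-to-uDFU") {
      edges <- set_edge(edges, "iDFU", "uDFU", p_self)
    } else if (is_mode %in% c("printed-self-residual-healed",
                              "printed-self-residual-uDFU")) {
      edges <- set_edge(edges, "iDFU", "iDFU", p_self)
      residual_to["iDFU"] <- if (is_mode == "printed-self-residual-healed")
        "healed" else "uDFU"
    } else {
      abort_model("unknown idfu_self interpretation '%s'", is_mode)
    }
  }

  ## postamputation -> gangrene row
  pg <- ip$postamp_gangrene %||% "direct"
  p_i <- get_prob(edges, "postamputation", "iDFU")
  p_g <- get_prob(edges, "postamputation", "gangrene")
  if (pg != "direct" && !is.null(p_i) && !is.null(p_g)) {
    if (pg == "conditional-split") {
      edges <- set_edge(edges, "postamputation", "iDFU", p_i * (1 - p_g))
      edges <- set_edge(edges, "postamputation", "gangrene", p_i * p_g)
    } else if (pg == "conditional-product") {
      edges <- set_edge(edges, "postamputation", "gangrene", p_i * p_g)
    } else {
      abort_model("unknown postamp_gangrene interpretation '%s'", pg)
    }
  }

  list(edges = edges, residual_to = residual_to)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a per-strategy monthly transition matrix
#'
#' Expands the printed transition rows under the model's interpretation
#' configuration, applies the strategy's relative healing effect to the target
#' transition (the uninfected-ulcer-to-healed probability in the shipped
#' model), and closes every row with its residual self-transition (or the
#' interpretation-designated residual destination). The death row is the
#' identity row.
#'
#' @param params A `dfu_params` object.
#' @param strategy A [strategy_config()].
#' @return A row-stochastic matrix of class `dfu_matrix` with the model's
#'   states as row and column names and a `cycle_length` attribute of 1 month.
#' @export
#' @examples
#' m <- load_paper_parameters()
#' P <- build_transition_matrix(m, m$strategies[[1]])
#' rowSums(P)
build_transition_matrix <- function(params, strategy) {
  st <- params$states
  n <- length(st)
  ex <- expand_transitions(params)
  edges <- ex$edges

  if (isTRUE(strategy$apply_healing_or) && !is.null(params$effect$target)) {
    tgt <- params$effect$target
    scale <- strategy$effect_scale %||% params$effect$scale %||% "odds"
    i <- which(edges$from == tgt$from & edges$to == tgt$to)
    if (length(i) == 0L) {
      abort_model("effect target %s -> %s not among model transitions",
                  tgt$from, tgt$to)
    }
    edges$prob[i[1]] <- apply_effect_size(edges$prob[i[1]],
                                          params$effect$or$base, scale)
  }

  P <- matrix(0, n, n, dimnames = list(st, st))
  explicit_self <- logical(n); names(explicit_self) <- st
  for (k in seq_len(nrow(edges))) {
    f <- edges$from[k]; t <- edges$to[k]; p <- edges$prob[k]
    if (p < 0 || p > 1) abort_model("transition %s -> %s outside [0, 1]", f, t)
    P[f, t] <- P[f, t] + p
    if (f == t) explicit_self[f] <- TRUE
  }
  for (s in st) {
    alloc <- sum(P[s, ])
    resid <- 1 - alloc
    if (resid < -1e-9) {
      abort_model("listed exits of state '%s' sum to %.6f > 1", s, alloc)
    }
    resid <- max(resid, 0)
    dest <- if (s %in% names(ex$residual_to)) ex$residual_to[[s]] else s
    if (dest == s && explicit_self[s] && resid > 1e-12) {
      abort_model(paste0("state '%s' has an explicit self-transition but its ",
                         "rows leave residual %.6f unallocated"), s, resid)
    }
    P[s, dest] <- P[s, dest] + resid
  }
  P[params$death_state, ] <- 0
  P[params$death_state, params$death_state] <- 1
  structure(P, class = c("dfu_matrix", class(P)), cycle_length = 1)
}

#' Validate a transition matrix
#'
#' @param P Matrix to check.
#' @param death_state Optional absorbing-state name to verify.
#' @param tol Row-sum tolerance.
#' @return `P`, invisibly.
#' @export
validate_transition_matrix <- function(P, death_state = NULL, tol = 1e-12) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) abort_model("not a square matrix")
  if (any(P < -tol) || any(P > 1 + tol)) abort_model("entries outside [0, 1]")
  bad <- which(abs(rowSums(P) - 1) > 1e-9)
  if (length(bad) > 0L) {
    abort_model("rows not summing to 1: %s",
                paste(rownames(P)[bad] %||% bad, collapse = ", "))
  }
  if (!is.null(death_state)) {
    row <- P[death_state, ]
    if (abs(row[death_state] - 1) > tol || any(abs(row[-match(death_state, colnames(P))]) > tol)) {
      abort_model("death row is not absorbing")
    }
  }
  invisible(P)
}
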