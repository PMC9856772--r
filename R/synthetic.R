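#' Generate a random valid model parameterization
#'
#' Property-test input generator: builds a random `n_states`-state model with
#' an absorbing death state, a random row-stochastic transition structure
#' (each live state exits with random probabilities, the residual staying
#' put), utilities uniform on `[0, 1]`, positive lognormal state costs, a
#' log-uniform effect size on `[0.5, 4]` targeting the first exit of the
#' initial state, and ±50% ranges on probabilities/costs, ±10% on utilities
#' (so sensitivity and probabilistic analyses run on generated models too).
#' Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param n_states Number of states including death, at least 2.
#' @param horizon_cycles Model horizon.
#' @param max_exit Upper bound on each live state's total exit probability.
#' @return A validated `dfu_params`.
#' @export
#' @examples
#' m <- generate_random_model(1, n_states = 5)
#' rowSums(build_transition_matrix(m, m$strategies[[1]]))
generate_random_model <- function(seed, n_states = 6L, horizon_cycles = 60L,
                                  max_exit = 0.8) {
  n_states <- as.integer(n_states)
  if (n_states < 2L) abort_model("need at least 2 states (one absorbing)")
  if (max_exit <= 0 || max_exit > 1) abort_model("max_exit must be in (0, 1]")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  live <- paste0("state", seq_len(n_states - 1L))
  states <- c(live, "death")
  rows <- list()
  for (s in live) {
    dests <- setdiff(states, s)
    k <- sample(seq_along(dests), 1L)
    to <- sample(dests, k)
    w <- stats::runif(k)
    p <- stats::runif(1, 0.05, max_exit) * w / sum(w)
    for (j in seq_len(k)) {
      rows[[length(rows) + 1L]] <- data.frame(from = s, to = to[j],
                                              base = p[j],
                                              stringsAsFactors = FALSE)
    }
  }
  tr <- do.call(rbind, rows)
  tr$low <- pmax(tr$base * 0.5, 0)
  tr$high <- pmin(tr$base * 1.5, 0.999)
  tr$family <- "beta"

  utilities <- stats::setNames(lapply(live, function(s) {
    u <- stats::runif(1)
    param_dist(u, max(0, u * 0.9), min(1, u * 1.1), "uniform")
  }), live)
  state_costs <- stats::setNames(lapply(live, function(s) {
    cc <- stats::rlnorm(1, log(100), 1)
    param_dist(cc, cc * 0.5, cc * 1.5, "triangular")
  }), live)

  init <- live[[1L]]
  or <- exp(stats::runif(1, log(0.5), log(4)))
  # the intervention multiplies the odds of the first exit of the initial
  # state; shrink that row until the adjusted exits stay clearly below 1
  repeat {
    irows <- which(tr$from == init)
    p_t <- tr$base[irows[1L]]
    adj <- (or * p_t / (1 - p_t)) / (1 + or * p_t / (1 - p_t))
    if (adj + sum(tr$base[irows[-1L]]) <= 0.95) break
    tr$base[irows] <- tr$base[irows] * 0.8
  }
  tr$low <- pmax(tr$base * 0.5, 0)
  tr$high <- pmin(tr$base * 1.5, 0.999)
  first_exit <- tr[tr$from == init, ][1L, ]
  effect <- list(or = param_dist(or, or * 0.5, or * 1.5, "lognormal"),
                 target = list(from = first_exit$from, to = first_exit$to),
                 scale = "odds")
  drug_cost <- stats::rlnorm(1, log(300), 0.5)
  parameter_set(
    states = states,
    transitions = tr,
    utilities = utilities,
    state_costs = state_costs,
    event_costs = list(),
    initial_cost = param_dist(0),
    drug = list(monthly_cost = param_dist(drug_cost, drug_cost * 0.5,
                                          drug_cost * 1.5, "triangular"),
                states = init, cap_cycles = Inf),
    effect = effect,
    interpretation = default_interpretation(),
    discount_rate_annual = 0.03,
    horizon_cycles = horizon_cycles,
    initial_state = init,
    death_state = "death",
    strategies = list(
      comparator = strategy_config("comparator"),
      intervention = strategy_config("intervention", apply_healing_or = TRUE,
                                     drug_cost_states = init)),
    name = sprintf("random-model-seed%d", seed))
}
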