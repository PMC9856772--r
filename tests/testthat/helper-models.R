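# Small models built in code for unit tests.

# two live states + death, simple direct transitions
tiny_model <- function(p_heal = 0.3, p_death = 0.01, utilities = c(a = 0.8, b = 0.6),
                       costs = c(a = 10, b = 100), drug = 50,
                       discount = 0.03, horizon = 24, half_cycle = FALSE,
                       or = 2, event_cost = 0) {
  tr <- data.frame(from = c("b", "b"), to = c("a", "death"),
                   base = c(p_heal, p_death))
  ecs <- if (event_cost > 0) {
    list(list(name = "hosp", from = "b", to = "a",
              cost = param_dist(event_cost, event_cost / 2, event_cost * 1.5,
                                "triangular")))
  } else list()
  parameter_set(
    states = c("a", "b", "death"),
    transitions = tr,
    utilities = list(a = param_dist(utilities[["a"]], utilities[["a"]] * 0.9,
                                    min(1, utilities[["a"]] * 1.1), "uniform"),
                     b = param_dist(utilities[["b"]], utilities[["b"]] * 0.9,
                                    min(1, utilities[["b"]] * 1.1), "uniform")),
    state_costs = list(a = param_dist(costs[["a"]], costs[["a"]] / 2,
                                      costs[["a"]] * 1.5, "triangular"),
                       b = param_dist(costs[["b"]], costs[["b"]] / 2,
                                      costs[["b"]] * 1.5, "triangular")),
    event_costs = ecs,
    drug = list(monthly_cost = param_dist(drug, drug / 2, drug * 1.5, "triangular"),
                states = "b", cap_cycles = Inf),
    effect = list(or = param_dist(or, or / 2, or * 1.5, "lognormal"),
                  target = list(from = "b", to = "a"), scale = "odds"),
    discount_rate_annual = discount,
    horizon_cycles = horizon,
    initial_state = "b",
    strategies = list(
      comparator = strategy_config("comparator"),
      intervention = strategy_config("intervention", apply_healing_or = TRUE,
                                     drug_cost_states = "b")),
    settings = list(half_cycle = half_cycle),
    name = "tiny")
}

# single live state occupied forever (no exits), plus death
one_state_model <- function(utility = 0.84, cost = 0, discount = 0,
                            horizon = 12) {
  parameter_set(
    states = c("healed", "death"),
    transitions = data.frame(from = character(), to = character(),
                             base = numeric()),
    utilities = list(healed = param_dist(utility)),
    state_costs = list(healed = param_dist(cost)),
    discount_rate_annual = discount,
    horizon_cycles = horizon,
    initial_state = "healed",
    name = "one-state")
}

# deterministic alternator: b -> a -> b -> a ... (never dies)
cycling_matrix <- function() {
  st <- c("a", "b", "death")
  P <- matrix(0, 3, 3, dimnames = list(st, st))
  P["a", "b"] <- 1
  P["b", "a"] <- 1
  P["death", "death"] <- 1
  structure(P, class = c("dfu_matrix", "matrix"), cycle_length = 1)
}

identity_matrix <- function(states = c("a", "b", "death")) {
  P <- diag(length(states))
  dimnames(P) <- list(states, states)
  structure(P, class = c("dfu_matrix", "matrix"), cycle_length = 1)
}

# minimal arm-outcome stub for compute_icer tests
arm_stub <- function(cost, qaly, label = "arm") {
  structure(list(strategy = label, total_cost = cost, life_years = qaly,
                 qalys = qaly,
                 mean_months_in_state = numeric(),
                 cumulative_probability = numeric(),
                 cost_components = numeric()),
            class = "dfu_arm_outcome")
}

# collapse every distribution of a model to its base value
collapse_distributions <- function(params) {
  p <- params
  for (i in seq_len(nrow(p$transitions))) {
    v <- p$transitions$value[[i]]
    v$low <- v$high <- v$base
    p$transitions$value[[i]] <- v
  }
  squash <- function(d) { d$low <- d$high <- d$base; d }
  p$utilities <- lapply(p$utilities, squash)
  p$state_costs <- lapply(p$state_costs, squash)
  for (i in seq_along(p$event_costs)) {
    p$event_costs[[i]]$cost <- squash(p$event_costs[[i]]$cost)
  }
  p$initial_cost <- squash(p$initial_cost)
  p$drug$monthly_cost <- squash(p$drug$monthly_cost)
  p$effect$or <- squash(p$effect$or)
  p
}
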