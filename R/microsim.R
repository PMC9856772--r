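#' Simulate a single patient path through the Markov model
#'
#' Draws one state trajectory: each cycle the next state is sampled from the
#' current state's matrix row as a categorical distribution. Clinical events
#' are tallied as entry transitions (a change of state into the event state),
#' counted at every occurrence.
#'
#' @param P Transition matrix.
#' @param horizon_cycles Number of cycles.
#' @param initial_state Starting state (default: first row).
#' @param event_states States whose entries are counted as events (default:
#'   every non-absorbing-entry state, i.e. all states).
#' @return Object of class `dfu_patient_path`: `states` (length
#'   `horizon+1` character vector) and `events` (named integer vector of entry
#'   counts into each event state).
#' @export
simulate_patient <- function(P, horizon_cycles,
                             initial_state = rownames(P)[1],
                             event_states = rownames(P)) {
  validate_transition_matrix(P)
  st <- rownames(P)
  if (!initial_state %in% st) abort_model("unknown initial state '%s'", initial_state)
  cum <- t(apply(P, 1, cumsum))
  path <- character(horizon_cycles + 1L)
  path[1L] <- initial_state
  events <- stats::setNames(integer(length(event_states)), event_states)
  cur <- match(initial_state, st)
  for (t in seq_len(horizon_cycles)) {
    nxt <- 1L + sum(stats::runif(1) > cum[cur, ])
    if (nxt != cur && st[nxt] %in% event_states) {
      events[st[nxt]] <- events[st[nxt]] + 1L
    }
    cur <- nxt
    path[t + 1L] <- st[cur]
  }
  structure(list(states = path, events = events), class = "dfu_patient_path")
}

#' Individual-level microsimulation of one strategy arm
#'
#' Simulates `n_patients` independent patient trajectories through the
#' transition matrix (vectorized across patients, one categorical draw per
#' patient per cycle) and aggregates entry-event counts and state occupancy.
#' Identical `(seed, inputs)` yield identical summaries; the global RNG state
#' is left untouched.
#'
#' @param P Transition matrix.
#' @param n_patients Number of simulated patients, at least 1.
#' @param horizon_cycles Number of monthly cycles.
#' @param seed Integer seed for reproducibility.
#' @param initial_state Starting state for every patient.
#' @param event_states States whose entry transitions are counted.
#' @return Object of class `dfu_event_summary`: `n_patients`, `seed`,
#'   `totals` (entry events per event state, summed over patients),
#'   `per_patient_var` (variance of per-patient event counts, for Monte-Carlo
#'   standard errors), `mean_months_in_state` (mean end-of-cycle occupancy
#'   months per state), and `final_occupancy` (state fractions at horizon).
#' @export
run_microsim <- function(P, n_patients, horizon_cycles, seed,
                         initial_state = rownames(P)[1],
                         event_states = rownames(P)) {
  validate_transition_matrix(P)
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) {
    abort_model("n_patients must be at least 1")
  }
  st <- rownames(P)
  if (!initial_state %in% st) abort_model("unknown initial state '%s'", initial_state)
  ns <- length(st)
  cum <- t(apply(P, 1, cumsum))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)

  state <- rep.int(match(initial_state, st), n_patients)
  counts <- matrix(0L, n_patients, ns, dimnames = list(NULL, st))
  months_sum <- stats::setNames(numeric(ns), st)
  for (t in seq_len(horizon_cycles)) {
    u <- stats::runif(n_patients)
    nxt <- 1L + as.integer(rowSums(u > cum[state, , drop = FALSE]))
    moved <- nxt != state
    if (any(moved)) {
      idx <- cbind(which(moved), nxt[moved])
      # tabulate entries per (patient, state)
      counts[idx] <- counts[idx] + 1L
    }
    state <- nxt
    tab <- tabulate(state, nbins = ns)
    months_sum <- months_sum + tab
  }
  keep <- intersect(event_states, st)
  totals <- colSums(counts)[keep]
  pvar <- apply(counts[, keep, drop = FALSE], 2, stats::var)
  if (n_patients == 1L) pvar[] <- 0
  structure(list(n_patients = n_patients, seed = seed,
                 horizon = as.integer(horizon_cycles),
                 totals = totals, per_patient_var = pvar,
                 mean_months_in_state = months_sum / n_patients,
                 final_occupancy = tabulate(state, nbins = ns) / n_patients),
            class = "dfu_event_summary")
}

#' @export
print.dfu_event_summary <- function(x, ...) {
  cat(sprintf("<dfu_event_summary> %d patients, %d cycles (seed %s)\n",
              x$n_patients, x$horizon, format(x$seed)))
  print(x$totals)
  invisible(x)
}

#' Compare clinical event totals between two simulated arms
#'
#' @param arm_a,arm_b `dfu_event_summary` objects with equal `n_patients` and
#'   horizon.
#' @return `data.frame` with per event state: totals in both arms, the signed
#'   difference `a - b`, and its Monte-Carlo standard error
#'   \eqn{\sqrt{n(\mathrm{var}_a + \mathrm{var}_b)}}.
#' @export
compare_event_totals <- function(arm_a, arm_b) {
  if (arm_a$n_patients != arm_b$n_patients) {
    abort_model("mismatched n_patients: %d vs %d",
                arm_a$n_patients, arm_b$n_patients)
  }
  if (arm_a$horizon != arm_b$horizon) abort_model("mismatched horizons")
  ev <- intersect(names(arm_a$totals), names(arm_b$totals))
  n <- arm_a$n_patients
  se <- sqrt(n * (arm_a$per_patient_var[ev] + arm_b$per_patient_var[ev]))
  data.frame(event_state = ev,
             total_a = as.numeric(arm_a$totals[ev]),
             total_b = as.numeric(arm_b$totals[ev]),
             difference = as.numeric(arm_a$totals[ev] - arm_b$totals[ev]),
             mc_se = as.numeric(se),
             row.names = NULL)
}

#' Microsimulate both strategies of a model and compare event counts
#'
#' Convenience wrapper: builds both strategy matrices and runs
#' [run_microsim()] on each. By default the two arms use independent random
#' streams (seeds `seed` and `seed + 1`); `common_rng = TRUE` applies common
#' random numbers (the same stream in both arms) as a variance-reduction
#' option.
#'
#' @param params A `dfu_params`.
#' @param n_patients Patients per arm.
#' @param horizon_cycles Cycles (default: model horizon).
#' @param seed Integer seed.
#' @param common_rng Use common random numbers across arms?
#' @return List with `arms` (event summaries named by strategy) and
#'   `comparison` (intervention minus comparator, from
#'   [compare_event_totals()]).
#' @export
microsim_compare <- function(params, n_patients, horizon_cycles = NULL,
                             seed = 1L, common_rng = FALSE) {
  horizon_cycles <- horizon_cycles %||% params$horizon_cycles
  comp_s <- params$strategies[[1L]]
  intv_s <- params$strategies[[2L]]
  Pc <- build_transition_matrix(params, comp_s)
  Pi <- build_transition_matrix(params, intv_s)
  seed2 <- if (common_rng) seed else seed + 1L
  a <- run_microsim(Pi, n_patients, horizon_cycles, seed2,
                    initial_state = params$initial_state)
  b <- run_microsim(Pc, n_patients, horizon_cycles, seed,
                    initial_state = params$initial_state)
  list(arms = stats::setNames(list(b, a), c(comp_s$label, intv_s$label)),
       comparison = compare_event_totals(a, b))
}
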