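test_that("discount factors follow monthly compounding of the yearly rate", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 12), 1 / 1.03)
  expect_equal(discount_factor(0, 60), 1)
  expect_equal(discount_factor(0.03, 6), 1.03^(-0.5))
  expect_error(discount_factor(0.03, -1), "negative")
  expect_error(discount_factor(-0.01, 1), "negative")
})

test_that("cohort trace satisfies its conservation invariants", {
  m <- load_paper_parameters()
  P <- build_transition_matrix(m, m$strategies[[2]])
  tr <- run_cohort(P, "uDFU", 60)
  occ <- tr$occupancy
  expect_equal(unname(occ[1, ]), c(0, 1, 0, 0, 0, 0))
  expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
  for (t in c(1, 7, 30, 60)) {
    expect_equal(colSums(tr$flows[, , t]), occ[t + 1, ], tolerance = 1e-12)
    expect_equal(rowSums(tr$flows[, , t]), occ[t, ], tolerance = 1e-12)
  }
  expect_true(all(diff(occ[, "death"]) >= -1e-15))  # death non-decreasing
})

test_that("identity and immediate-death matrices give the trivial traces", {
  P <- identity_matrix()
  tr <- run_cohort(P, "b", 60)
  expect_true(all(tr$occupancy[, "b"] == 1))

  st <- c("a", "b", "death")
  Pd <- matrix(0, 3, 3, dimnames = list(st, st))
  Pd[, "death"] <- 1
  tr <- run_cohort(Pd, "b", 10)
  expect_true(all(tr$occupancy[-1, "death"] == 1))
})

test_that("cohort occupancy equals the matrix-power oracle", {
  for (seed in c(2, 17, 101, 555)) {
    m <- generate_random_model(seed, n_states = 5)
    P <- build_transition_matrix(m, m$strategies[[2]])
    tr <- run_cohort(P, m$initial_state, 40)
    v0 <- tr$occupancy[1, ]
    Pk <- diag(nrow(P))
    for (t in 1:40) {
      Pk <- Pk %*% unclass(P)   # independent power accumulation
      expect_equal(tr$occupancy[t + 1, ], as.vector(v0 %*% Pk),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("non-stochastic matrices are rejected before simulation", {
  P <- identity_matrix()
  P["a", "b"] <- 0.5   # row a now sums to 1.5
  expect_error(run_cohort(P, "a", 5), "summing to 1|rows")
})

test_that("zero costs and utilities accumulate to zero except life-years", {
  m <- tiny_model(utilities = c(a = 0, b = 0), costs = c(a = 0, b = 0),
                  drug = 0, discount = 0)
  m$effect$or <- param_dist(1)
  out <- run_strategy(m, m$strategies[[1]])
  expect_equal(out$total_cost, 0)
  expect_equal(out$qalys, 0)
  expect_gt(out$life_years, 0)
})

test_that("a permanently healed cohort accrues utility x years", {
  m <- one_state_model(utility = 0.84, discount = 0, horizon = 12)
  out <- run_strategy(m, m$strategies[[1]])
  expect_equal(out$qalys, 0.84)          # closed form: 0.84 x 1 year
  expect_equal(out$life_years, 1)
  expect_equal(unname(out$mean_months_in_state["healed"]), 12)
})

test_that("total cost is additive across cost components", {
  base <- tiny_model(event_cost = 500)
  intv <- base$strategies[[2]]

  run_cost <- function(p) run_strategy(p, intv)$total_cost

  full <- run_cost(base)
  no_state <- base; no_state$state_costs <- lapply(no_state$state_costs,
                                                   function(d) param_dist(0))
  no_event <- base; no_event$event_costs <- list()
  no_drug <- base; no_drug$drug$monthly_cost <- param_dist(0)
  no_init <- base; no_init$initial_cost <- param_dist(0)

  out_full <- run_strategy(base, intv)
  expect_equal(sum(out_full$cost_components), full)
  # switching one component off removes exactly that component
  expect_equal(run_cost(no_state), full - out_full$cost_components[["state"]])
  expect_equal(run_cost(no_event), full - out_full$cost_components[["event"]])
  expect_equal(run_cost(no_drug), full - out_full$cost_components[["drug"]])
  expect_equal(run_cost(no_init), full - out_full$cost_components[["initial"]])
})

test_that("discounting can only shrink QALYs, equality at zero rate", {
  m <- tiny_model(discount = 0.03)
  m0 <- tiny_model(discount = 0)
  q <- run_strategy(m, m$strategies[[2]])$qalys
  q0 <- run_strategy(m0, m0$strategies[[2]])$qalys
  expect_lt(q, q0)
  m00 <- tiny_model(discount = 0)
  expect_equal(run_strategy(m00, m00$strategies[[2]])$qalys, q0)
})

test_that("death occupancy and total cost are non-decreasing in the horizon", {
  m <- load_paper_parameters()
  horizons <- c(6, 12, 24, 48, 60)
  res <- lapply(horizons, function(h) run_strategy(m, m$strategies[[2]], h))
  deaths <- vapply(res, function(o) o$cumulative_probability[["death"]], numeric(1))
  costs <- vapply(res, function(o) o$total_cost, numeric(1))
  expect_true(all(diff(deaths) > 0))
  expect_true(all(diff(costs) > 0))
})

test_that("half-cycle correction lands rewards between start and end accrual", {
  m_end <- tiny_model(half_cycle = FALSE)
  m_half <- tiny_model(half_cycle = TRUE)
  q_end <- run_strategy(m_end, m_end$strategies[[1]])$qalys
  q_half <- run_strategy(m_half, m_half$strategies[[1]])$qalys
  # the cohort flows from the low-utility start state towards the
  # higher-utility healed state, so averaging end-of-cycle occupancy with the
  # start-of-cycle occupancy must lower the QALY total
  expect_lt(q_half, q_end)
  # but never below the pure start-of-cycle accrual bound
  occ <- attr(run_strategy(m_end, m_end$strategies[[1]]), "trace")$occupancy
  u <- c(0.8, 0.6, 0)
  d <- discount_factor(0.03, seq_len(24))
  q_start <- sum(d * (occ[-nrow(occ), ] %*% u)) / 12
  expect_gt(q_half, q_start)
})

test_that("incremental comparison reproduces the ratio and its quadrants", {
  ce <- compute_icer(arm_stub(9781, 3.7402), arm_stub(9210, 3.7019),
                     c(32787, 98361))
  expect_equal(ce$delta_cost, 571)
  expect_equal(ce$delta_qaly, 0.0383)
  expect_equal(ce$icer, 571 / 0.0383)        # 14908.6...
  expect_equal(ce$status, "icer")
  expect_equal(unname(ce$nmb[2, 1]), 32787 * 3.7402 - 9781)

  same <- compute_icer(arm_stub(100, 1), arm_stub(100, 1))
  expect_equal(same$status, "undefined")
  expect_true(is.na(same$icer))

  dom <- compute_icer(arm_stub(900, 1.1), arm_stub(1000, 1.0))
  expect_equal(dom$status, "dominant")

  dominated <- compute_icer(arm_stub(1100, 0.9), arm_stub(1000, 1.0))
  expect_equal(dominated$status, "dominated")
})

test_that("trace export is tidy and consistent with the trace", {
  m <- tiny_model(horizon = 5)
  tr <- attr(run_strategy(m, m$strategies[[1]]), "trace")
  df <- trace_to_df(tr)
  expect_equal(nrow(df), 6 * 3)
  expect_equal(df$occupancy[df$cycle == 0 & df$state == "b"], 1)
})
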