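test_that("odds-ratio adjustment matches hand-computed odds arithmetic", {
  # identity and zero cases
  expect_equal(or_adjust_probability(0.259, 1.0), 0.259)
  expect_equal(or_adjust_probability(0, 2.30), 0)
  # hand computation: odds 0.259/0.741 = 0.349528, x2.30 = 0.803914,
  # back-transform 0.803914/1.803914
  odds <- 0.259 / 0.741
  expect_equal(or_adjust_probability(0.259, 2.30),
               (2.30 * odds) / (1 + 2.30 * odds))
  expect_equal(or_adjust_probability(0.259, 2.30), 0.44565, tolerance = 1e-4)
})

test_that("odds-ratio adjustment rejects degenerate inputs", {
  expect_error(or_adjust_probability(1, 2), "\\[0, 1\\)")
  expect_error(or_adjust_probability(-0.1, 2), "\\[0, 1\\)")
  expect_error(or_adjust_probability(0.5, 0), "positive")
  expect_error(or_adjust_probability(0.5, -1), "positive")
})

test_that("odds-ratio adjustment is monotone, invertible, and saturates", {
  p <- 0.259
  ors <- c(0.5, 1, 1.5, 2.3, 5, 20, 1000)
  vals <- vapply(ors, function(o) or_adjust_probability(p, o), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[length(vals)], 0.99)          # OR -> Inf gives p' -> 1
  for (o in ors) {                             # round trip within 1e-12
    expect_equal(or_adjust_probability(or_adjust_probability(p, o), 1 / o), p,
                 tolerance = 1e-12)
  }
  # monotone in p at fixed OR
  ps <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(vapply(ps, or_adjust_probability, numeric(1),
                              or_value = 2.3)) > 0))
})

test_that("rate-scale effect application agrees with the complement power", {
  expect_equal(apply_effect_size(0.259, 2.3, "rate"), 1 - (1 - 0.259)^2.3)
  expect_equal(apply_effect_size(0.259, 1, "rate"), 0.259)
  expect_equal(apply_effect_size(0.259, 2.3, "odds"),
               or_adjust_probability(0.259, 2.3))
})

test_that("literal transition matrix reproduces the printed uDFU row", {
  m <- load_paper_parameters("literal")
  P <- build_transition_matrix(m, m$strategies[["GWC"]])
  expect_equal(P["uDFU", "healed"], 0.259)
  expect_equal(P["uDFU", "iDFU"], 0.068)
  expect_equal(P["uDFU", "death"], 0.001)
  expect_equal(P["uDFU", "uDFU"], 1 - 0.259 - 0.068 - 0.001)  # residual 0.672
  # odds-scale intervention entry
  Pi <- build_transition_matrix(m, m$strategies[["ON101+GWC"]])
  expect_equal(Pi["uDFU", "healed"], 0.44565, tolerance = 1e-4)
})

test_that("strategies differ only in the treated row", {
  for (variant in c("literal", "calibrated")) {
    m <- load_paper_parameters(variant)
    Pg <- build_transition_matrix(m, m$strategies[[1]])
    Po <- build_transition_matrix(m, m$strategies[[2]])
    d <- abs(Pg - Po) > 1e-12
    expect_true(all(which(rowSums(d) > 0) == match("uDFU", rownames(Pg))))
    # exactly the target entry and the residual self-transition move
    expect_identical(sort(colnames(Pg)[d["uDFU", ]]), c("healed", "uDFU"))
  }
})

test_that("empty transition list yields the identity matrix", {
  m <- one_state_model()
  P <- build_transition_matrix(m, m$strategies[[1]])
  expect_equal(unclass(P), diag(2), ignore_attr = TRUE)
})

test_that("exit probabilities above one are rejected with the row named", {
  tr <- data.frame(from = c("b", "b"), to = c("a", "death"),
                   base = c(0.9, 0.3))
  expect_error(
    parameter_set(states = c("a", "b", "death"), transitions = tr,
                  utilities = list(a = param_dist(0.8), b = param_dist(0.6)),
                  state_costs = list(a = param_dist(0), b = param_dist(0)),
                  initial_state = "b"),
    "'b'.*sum")
})

test_that("built matrices are row-stochastic with an absorbing death row", {
  for (seed in 1:200) {
    m <- generate_random_model(seed, n_states = sample(2:8, 1))
    for (s in m$strategies) {
      P <- build_transition_matrix(m, s)
      expect_true(all(abs(rowSums(P) - 1) < 1e-12))
      expect_true(all(P >= 0 & P <= 1))
      expect_equal(unname(P["death", "death"]), 1)
    }
  }
})

test_that("interpretation tags expand the ambiguous rows as documented", {
  m <- load_paper_parameters("literal")

  m$interpretation$healed_recurrence <- "conditional-split"
  P <- build_transition_matrix(m, m$strategies[[1]])
  expect_equal(P["healed", "uDFU"], 0.038 * (1 - 0.211))
  expect_equal(P["healed", "iDFU"], 0.038 * 0.211)

  m$interpretation$healed_recurrence <- "total-to-uDFU"
  P <- build_transition_matrix(m, m$strategies[[1]])
  expect_equal(P["healed", "uDFU"], 0.038 / (1 - 0.211))
  expect_equal(P["healed", "iDFU"], 0)

  m$interpretation$idfu_self <- "printed-self-residual-healed"
  P <- build_transition_matrix(m, m$strategies[[1]])
  expect_equal(P["iDFU", "iDFU"], 0.084)
  expect_equal(P["iDFU", "healed"], 1 - 0.084 - 0.016 - 0.036 - 0.001)

  m$interpretation$postamp_gangrene <- "conditional-split"
  P <- build_transition_matrix(m, m$strategies[[1]])
  expect_equal(P["postamputation", "gangrene"], 0.007 * 0.43)
  expect_equal(P["postamputation", "iDFU"], 0.007 * (1 - 0.43))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
})
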