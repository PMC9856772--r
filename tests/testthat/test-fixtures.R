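test_that("the shipped fixture carries the published inputs verbatim", {
  m <- load_paper_parameters()
  pars <- list_parameters(m)
  val <- function(nm) pars[match(nm, pars$parameter), ]

  expect_equal(val("uDFU->healed")$base, 0.259)
  expect_equal(val("uDFU->healed")$low, 0.1295)
  expect_equal(val("uDFU->healed")$high, 0.3885)
  expect_equal(val("uDFU->healed")$family, "beta")
  expect_equal(val("iDFU->iDFU")$base, 0.084)
  expect_equal(val("healed->uDFU")$base, 0.038)
  expect_equal(val("healed->iDFU")$base, 0.211)
  expect_equal(val("postamputation->gangrene")$base, 0.43)
  expect_equal(val("gangrene->postamputation")$base, 0.313)

  expect_equal(val("utility.healed")$base, 0.84)
  expect_equal(val("utility.postamputation")$base, 0.59)
  expect_equal(val("utility.uDFU")$family, "uniform")

  expect_equal(val("cost.uDFU")$base, 97)
  expect_equal(val("cost.postamputation")$base, 504)
  expect_equal(val("event.hospitalization_infection")$base, 8847)
  expect_equal(val("event.hospitalization_amputation")$base, 7552)
  expect_equal(val("event.hospitalization_postamputation_gangrene")$base, 13583)
  expect_equal(val("initial_cost")$base, 161)
  expect_equal(val("drug.monthly_cost")$base, 608)
  expect_equal(val("drug.monthly_cost")$low, 304)
  expect_equal(val("drug.monthly_cost")$high, 912)

  expect_equal(val("effect.or")$base, 2.30)
  expect_equal(val("effect.or")$family, "lognormal")

  expect_equal(m$horizon_cycles, 60L)
  expect_equal(m$discount_rate_annual, 0.03)
  expect_equal(m$wtp_thresholds, c(32787, 98361))
  expect_equal(m$initial_state, "uDFU")
  expect_identical(m$states, health_states())

  # provenance maps every parameter to a published row label
  prov <- attr(m, "provenance")
  expect_true(all(c("uDFU->healed", "effect.or", "drug.monthly_cost") %in%
                  names(prov)))
})

test_that("fixture ranges follow the stated sensitivity conventions", {
  # probabilities, effect size and costs vary +-50%; utilities +-10%
  m <- load_paper_parameters()
  pars <- list_parameters(m)
  tr_rows <- grepl("->", pars$parameter, fixed = TRUE)
  expect_equal(pars$low[tr_rows], pars$base[tr_rows] * 0.5, tolerance = 1e-9)
  expect_equal(pars$high[tr_rows], pars$base[tr_rows] * 1.5, tolerance = 1e-9)
  ut_rows <- startsWith(pars$parameter, "utility.")
  expect_equal(pars$low[ut_rows], pars$base[ut_rows] * 0.9, tolerance = 1e-9)
  expect_equal(pars$high[ut_rows], pars$base[ut_rows] * 1.1, tolerance = 1e-9)
  expect_equal(pars[pars$parameter == "effect.or", "low"], 2.30 * 0.5)
  expect_equal(pars[pars$parameter == "effect.or", "high"], 2.30 * 1.5)
})

test_that("checksum guard rejects edited fixture files", {
  src <- system.file("extdata", "on101_dfu.yaml", package = "dfucea")
  tmp <- file.path(tempdir(), "fixture-guard")
  dir.create(tmp, showWarnings = FALSE)
  bad <- file.path(tmp, "on101_dfu.yaml")
  writeLines(c(readLines(src), "# silent edit"), bad)
  file.copy(paste0(src, ".md5"), paste0(bad, ".md5"), overwrite = TRUE)
  expect_error(dfucea:::check_fixture(bad), "checksum mismatch")
  # the pristine file passes
  expect_silent(dfucea:::check_fixture(src))
})

test_that("both fixture variants load and differ only as documented", {
  cal <- load_paper_parameters("calibrated")
  lit <- load_paper_parameters("literal")
  expect_equal(cal$interpretation$healed_recurrence, "total-to-uDFU")
  expect_equal(lit$interpretation$healed_recurrence, "direct")
  expect_equal(cal$effect$scale, "rate")
  expect_equal(lit$effect$scale, "odds")
  expect_true(cal$settings$half_cycle)
  expect_false(lit$settings$half_cycle)
  # identical printed numbers in both variants
  expect_equal(list_parameters(cal), list_parameters(lit))
})

test_that("random model generation is deterministic and valid", {
  a <- generate_random_model(123, n_states = 6)
  b <- generate_random_model(123, n_states = 6)
  expect_identical(a, b)
  expect_false(identical(a, generate_random_model(124, n_states = 6)))

  for (seed in 1:100) {
    m <- generate_random_model(seed, n_states = sample(2:7, 1),
                               horizon_cycles = 24)
    bc <- run_base_case(m)        # valid model, finite outcomes
    for (a in bc$arms) {
      expect_true(is.finite(a$total_cost) && a$total_cost >= 0)
      expect_true(is.finite(a$qalys) && a$qalys >= 0)
      expect_lte(a$qalys, a$life_years + 1e-12)
    }
  }
})

test_that("unit utilities make QALYs equal life-years", {
  m <- generate_random_model(7, n_states = 5)
  m$utilities <- lapply(m$utilities, function(u) param_dist(1))
  out <- run_strategy(m, m$strategies[[2]])
  expect_equal(out$qalys, out$life_years, tolerance = 1e-12)
})
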