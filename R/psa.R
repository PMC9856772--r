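#' Sample from a parameter distribution
#'
#' Draws from the family recorded in a [param_dist()], parameterized from the
#' `(base, low, high)` triple:
#' \describe{
#'   \item{beta}{method of moments with mean `base` and
#'     `sd = (high - low)/3.92` (the range read as an approximate 95%
#'     interval); infeasible moments (`sd^2 >= mean(1-mean)`) are an error
#'     naming the parameter.}
#'   \item{uniform}{on `[low, high]`.}
#'   \item{triangular}{with mode `base` on `[low, high]`, by inverse-CDF.}
#'   \item{lognormal}{median `base`,
#'     `sdlog = (log(high) - log(low))/3.92`.}
#' }
#' A degenerate range (`low == base == high`) yields the constant `base` for
#' every family.
#'
#' @param dist A [param_dist()].
#' @param n Number of draws.
#' @param name Parameter name used in error messages.
#' @return Numeric vector of `n` draws.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_parameter(param_dist(608, 304, 912, "triangular"), 1e4))
sample_parameter <- function(dist, n = 1L, name = "parameter") {
  stopifnot(inherits(dist, "param_dist"))
  b <- dist$base; lo <- dist$low; hi <- dist$high
  if (hi == lo) return(rep.int(b, n))
  switch(dist$family,
    uniform = stats::runif(n, lo, hi),
    lognormal = {
      if (lo <= 0 || b <= 0) abort_model("%s: lognormal needs positive bounds", name)
      stats::rlnorm(n, meanlog = log(b), sdlog = (log(hi) - log(lo)) / 3.92)
    },
    triangular = rtriangular(n, lo, b, hi),
    beta = {
      s <- (hi - lo) / 3.92
      v <- s^2
      if (b <= 0 || b >= 1) abort_model("%s: beta mean must be in (0, 1)", name)
      if (v >= b * (1 - b)) {
        abort_model("%s: beta moments infeasible (sd^2 = %.4g >= mean(1-mean) = %.4g)",
                    name, v, b * (1 - b))
      }
      nu <- b * (1 - b) / v - 1
      pmin(pmax(stats::rbeta(n, b * nu, (1 - b) * nu), 0), 1)
    })
}

# inverse-CDF sampler for the triangular(low, mode, high) distribution
rtriangular <- function(n, lo, mode, hi) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

# draw a complete parameter set; returns a modified copy of params
sample_parameter_set <- function(params) {
  p <- params
  tr <- p$transitions
  for (i in seq_len(nrow(tr))) {
    tr$value[[i]]$base <- sample_parameter(tr$value[[i]], 1L,
                                           sprintf("%s->%s", tr$from[i], tr$to[i]))
  }
  p$transitions <- tr
  for (s in names(p$utilities)) {
    p$utilities[[s]]$base <- sample_parameter(p$utilities[[s]], 1L,
                                              paste0("utility.", s))
  }
  for (s in names(p$state_costs)) {
    p$state_costs[[s]]$base <- sample_parameter(p$state_costs[[s]], 1L,
                                                paste0("cost.", s))
  }
  for (i in seq_along(p$event_costs)) {
    p$event_costs[[i]]$cost$base <-
      sample_parameter(p$event_costs[[i]]$cost, 1L, p$event_costs[[i]]$name)
  }
  p$initial_cost$base <- sample_parameter(p$initial_cost, 1L, "initial_cost")
  p$drug$monthly_cost$base <- sample_parameter(p$drug$monthly_cost, 1L, "drug")
  p$effect$or$base <- sample_parameter(p$effect$or, 1L, "effect.or")
  p
}

# TRUE if the sampled set builds valid matrices for both strategies
psa_draw_valid <- function(p) {
  ok <- TRUE
  tryCatch({
    for (s in p$strategies) build_transition_matrix(p, s)
  }, error = function(e) ok <<- FALSE)
  ok
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_iterations` Monte-Carlo iterations. Each iteration independently
#' draws every uncertain parameter from its distribution (see
#' [sample_parameter()]), rebuilds both strategy matrices, runs the cohort
#' engine for both arms and records discounted cost and QALYs. Draws producing
#' an invalid model (listed exits summing above 1 after interpretation
#' expansion) are resampled and the resample count reported. Deterministic
#' given `seed`; the global RNG state is restored afterwards.
#'
#' @param params A `dfu_params` with distributions on its parameters.
#' @param n_iterations Number of PSA iterations, at least 1.
#' @param seed Integer seed.
#' @return Object of class `dfu_psa`: `iterations` (data.frame with per-arm
#'   cost/QALY, increments, ICER and sampled effect size per iteration),
#'   `n_iterations`, `seed`, `n_resampled`, `strategies`.
#' @export
run_psa <- function(params, n_iterations, seed = 1L) {
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L) {
    abort_model("n_iterations must be at least 1")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  labs <- vapply(params$strategies[1:2], function(s) s$label, character(1))
  res <- matrix(NA_real_, n_iterations, 6L)
  ors <- numeric(n_iterations)
  n_resampled <- 0L
  for (i in seq_len(n_iterations)) {
    repeat {
      p <- sample_parameter_set(params)
      if (psa_draw_valid(p)) break
      n_resampled <- n_resampled + 1L
    }
    comp <- run_strategy(p, p$strategies[[1L]])
    intv <- run_strategy(p, p$strategies[[2L]])
    res[i, ] <- c(comp$total_cost, comp$qalys, intv$total_cost, intv$qalys,
                  intv$total_cost - comp$total_cost, intv$qalys - comp$qalys)
    ors[i] <- p$effect$or$base
  }
  it <- data.frame(iteration = seq_len(n_iterations),
                   cost_comparator = res[, 1], qaly_comparator = res[, 2],
                   cost_intervention = res[, 3], qaly_intervention = res[, 4],
                   delta_cost = res[, 5], delta_qaly = res[, 6],
                   icer = res[, 5] / res[, 6],
                   effect_or = ors)
  structure(list(iterations = it, n_iterations = n_iterations, seed = seed,
                 n_resampled = n_resampled, strategies = labs,
                 wtp_thresholds = params$wtp_thresholds),
            class = "dfu_psa")
}

#' @export
print.dfu_psa <- function(x, ...) {
  cat(sprintf("<dfu_psa> %d iterations (seed %s, %d resampled draws)\n",
              x$n_iterations, format(x$seed), x$n_resampled))
  cat(sprintf("  median ICER %.0f; mean ICER %.0f (signed-ratio mean: interpret with care)\n",
              stats::median(x$iterations$icer), mean(x$iterations$icer)))
  for (l in x$wtp_thresholds) {
    cat(sprintf("  P(cost-effective at %s/QALY) = %.3f\n",
                format(l, big.mark = " "), ceac_probability(x, l)))
  }
  invisible(x)
}

# probability intervention preferred at threshold lambda (NMB rule)
ceac_probability <- function(psa, lambda) {
  it <- psa$iterations
  mean(lambda * it$delta_qaly - it$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention is
#' preferred, i.e. the fraction of PSA iterations with higher net monetary
#' benefit than the comparator. At a threshold of 0 this is the probability of
#' being cost-saving.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Thresholds at which to evaluate the curve. The default runs
#'   0 to 150,000 in steps of 1,000 and always includes the model's own
#'   thresholds exactly.
#' @return `data.frame` with `wtp` and `probability`.
#' @export
compute_ceac <- function(psa, wtp_grid = NULL) {
  if (is.null(wtp_grid)) {
    wtp_grid <- sort(unique(c(seq(0, 150000, by = 1000), psa$wtp_thresholds)))
  }
  if (length(wtp_grid) == 0L) abort_model("empty WTP grid")
  data.frame(wtp = wtp_grid,
             probability = vapply(wtp_grid, function(l) ceac_probability(psa, l),
                                  numeric(1)))
}
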