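#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full two-arm comparison with each parameter set to its low and
#' high bound in turn, everything else at base case. The published convention
#' for the shipped model is a range of ±50% of the base value for
#' probabilities, effect sizes and costs, and ±10% for utilities; those ranges
#' are stored on the parameters themselves and used by default. Entries whose
#' ICER span exceeds 40% of the base-case ICER are flagged as influential.
#'
#' @param params A `dfu_params`.
#' @param ranges Optional named list of `c(low, high)` overriding the stored
#'   ranges; names must be valid parameter names ([list_parameters()]).
#' @param flag_threshold_pct Span threshold (% of base ICER) for the
#'   `influential` flag.
#' @return `data.frame` of class `dfu_tornado`, sorted by descending span:
#'   `parameter`, `low`, `high`, `icer_at_low`, `icer_at_high`,
#'   `span`, `span_pct_of_base`, `influential`; base-case ICER in attribute
#'   `"base_icer"`.
#' @export
one_way_dsa <- function(params, ranges = NULL, flag_threshold_pct = 40) {
  base <- run_base_case(params)
  base_icer <- base$ce$icer
  tab <- list_parameters(params)
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), tab$parameter)
    if (length(bad) > 0L) {
      abort_model("unknown parameter(s) in ranges: %s", paste(bad, collapse = ", "))
    }
    for (nm in names(ranges)) {
      i <- match(nm, tab$parameter)
      tab$low[i] <- ranges[[nm]][1]; tab$high[i] <- ranges[[nm]][2]
    }
  }
  icer_at <- function(nm, value) {
    bc <- run_base_case(set_parameter(params, nm, value))
    bc$ce$icer
  }
  lo <- hi <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    lo[i] <- icer_at(tab$parameter[i], tab$low[i])
    hi[i] <- icer_at(tab$parameter[i], tab$high[i])
  }
  out <- data.frame(parameter = tab$parameter, low = tab$low, high = tab$high,
                    icer_at_low = lo, icer_at_high = hi,
                    span = abs(hi - lo),
                    span_pct_of_base = 100 * abs(hi - lo) / abs(base_icer))
  out$influential <- out$span_pct_of_base > flag_threshold_pct
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("dfu_tornado", class(out))
  out
}

# incremental results at a given drug-cost multiplier / OR override
ce_at <- function(params, drug_multiplier = 1, or = NULL, drug_cost = NULL) {
  p <- params
  if (!is.null(drug_cost)) p$drug$monthly_cost$base <- drug_cost
  p$drug$monthly_cost$base <- p$drug$monthly_cost$base * drug_multiplier
  if (!is.null(or)) p$effect$or$base <- or
  run_base_case(p)$ce
}

# plain bisection to tolerance `tol` on x; f must change sign on [lo, hi]
bisect <- function(f, lo, hi, tol) {
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' Two-way threshold analysis: drug cost vs required healing effect
#'
#' For each candidate monthly drug cost, finds the smallest effect size (odds
#' ratio) at which the intervention is cost-effective at the given
#' willingness-to-pay threshold, by bisection on the sign of the incremental
#' net monetary benefit \eqn{\lambda \Delta Q - \Delta C} (equivalent to
#' ICER = \eqn{\lambda} where the ICER is defined, and robust where it is
#' not). If the intervention is cost-effective over the whole range the
#' threshold is reported as the range floor with status `"always"`; if it is
#' never cost-effective, status `"never"`.
#'
#' @param params A `dfu_params`.
#' @param drug_cost_values Monthly drug costs to examine.
#' @param or_range Interval searched for the threshold odds ratio.
#' @param wtp Willingness-to-pay threshold (default: the model's upper
#'   threshold).
#' @param tol Bisection tolerance on the odds ratio.
#' @return `data.frame`: `drug_cost`, `threshold_or`, `status`
#'   (`"threshold"`, `"always"`, `"never"`).
#' @export
two_way_threshold <- function(params, drug_cost_values,
                              or_range = c(1, 3.45),
                              wtp = max(params$wtp_thresholds),
                              tol = 0.005) {
  res <- lapply(drug_cost_values, function(cc) {
    g <- function(or) {
      ce <- ce_at(params, drug_cost = cc, or = or)
      wtp * ce$delta_qaly - ce$delta_cost
    }
    glo <- g(or_range[1]); ghi <- g(or_range[2])
    if (glo >= 0) {
      data.frame(drug_cost = cc, threshold_or = or_range[1], status = "always")
    } else if (ghi < 0) {
      data.frame(drug_cost = cc, threshold_or = NA_real_, status = "never")
    } else {
      root <- bisect(g, or_range[1], or_range[2], tol)
      data.frame(drug_cost = cc, threshold_or = root, status = "threshold")
    }
  })
  do.call(rbind, res)
}

#' Break-even drug-cost multiplier
#'
#' Finds the scalar multiplier of the base-case monthly drug cost at which
#' the intervention either becomes exactly cost-neutral
#' (`criterion = "cost_saving"`: incremental cost 0) or meets a
#' willingness-to-pay threshold (`criterion = "wtp"`: incremental net
#' monetary benefit 0 at `wtp`). The incremental cost is strictly increasing
#' in the multiplier (the drug cost enters one arm only), so a bracketed root
#' is unique. Solved by bisection.
#'
#' @param params A `dfu_params`.
#' @param criterion `"cost_saving"` or `"wtp"`.
#' @param wtp Threshold used when `criterion = "wtp"`.
#' @param bracket Multiplier search interval.
#' @param tol Bisection tolerance on the multiplier.
#' @return List: `multiplier` (`NA` if no root in the bracket), `criterion`,
#'   `wtp`, `bracketed` (logical).
#' @export
break_even_multiplier <- function(params, criterion = c("cost_saving", "wtp"),
                                  wtp = min(params$wtp_thresholds),
                                  bracket = c(0, 10), tol = 0.001) {
  criterion <- match.arg(criterion)
  f <- function(m) {
    ce <- ce_at(params, drug_multiplier = m)
    if (criterion == "cost_saving") ce$delta_cost
    else ce$delta_cost - wtp * ce$delta_qaly
  }
  root <- bisect(f, bracket[1], bracket[2], tol)
  list(multiplier = root, criterion = criterion,
       wtp = if (criterion == "wtp") wtp else NA_real_,
       bracketed = !is.na(root))
}
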