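#' Summarize a base-case comparison as a results table
#'
#' Mirrors the conventional cost-effectiveness results table: one row per
#' strategy with discounted total cost, life expectancy, QALYs, and the
#' incremental columns on the intervention row. Rendered values follow the
#' usual reporting precision (costs to whole currency units, QALYs to four
#' decimals, ICER to whole units); the unrounded values are what the
#' underlying objects carry.
#'
#' @param bc A `dfu_basecase`.
#' @return `data.frame` with one row per strategy.
#' @export
summary_table <- function(bc) {
  arms <- bc$arms
  ce <- bc$ce
  data.frame(
    strategy = vapply(arms, function(a) a$strategy, character(1)),
    total_cost = round(vapply(arms, function(a) a$total_cost, numeric(1))),
    life_expectancy_years = round(vapply(arms, function(a) a$life_years, numeric(1)), 4),
    qalys = round(vapply(arms, function(a) a$qalys, numeric(1)), 4),
    incremental_cost = c(NA, round(ce$delta_cost)),
    incremental_qalys = c(NA, round(ce$delta_qaly, 4)),
    icer = c(NA, if (ce$status == "icer") round(ce$icer) else NA),
    status = c(NA, ce$status),
    row.names = NULL)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac A [compute_ceac()] data frame.
#' @param thresholds Optional WTP values to mark.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac, thresholds = NULL) {
  p <- ggplot2::ggplot(ceac, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (per QALY)",
                  y = "Probability intervention is cost-effective") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot a tornado diagram
#'
#' @param tornado A [one_way_dsa()] result; only influential entries are drawn
#'   unless `all = TRUE`.
#' @param all Draw every parameter?
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, all = FALSE) {
  df <- as.data.frame(tornado)
  if (!all) df <- df[df$influential, , drop = FALSE]
  if (nrow(df) == 0L) df <- utils::head(as.data.frame(tornado), 5L)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base <- attr(tornado, "base_icer")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER (per QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the incremental cost-effectiveness plane
#'
#' @param psa A [run_psa()] result.
#' @param wtp Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = max(psa$wtp_thresholds)) {
  it <- psa$iterations
  ggplot2::ggplot(it, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost") +
    ggplot2::theme_minimal()
}

#' Write a report bundle
#'
#' Writes every supplied result object to `out_dir`: the base-case summary
#' table, scenario tables, the PSA iteration table with CEAC and
#' cost-effectiveness plane (CSV + figures), the tornado table and figure,
#' microsimulation event tables, and a machine-readable JSON manifest holding
#' the seeds, software version and input digests needed to re-run the bundle.
#'
#' @param results Named list; recognized elements: `basecase`
#'   (`dfu_basecase`), `scenarios` (list of `dfu_basecase`), `psa`
#'   (`dfu_psa`), `tornado` (`dfu_tornado`), `microsim` (result of
#'   [microsim_compare()]), `model_path` (character).
#' @param out_dir Output directory (created if absent; must be writable).
#' @return Invisibly, the manifest list. Files are written under `out_dir`.
#' @export
generate_report <- function(results, out_dir) {
  if (length(results) == 0L) abort_model("no result objects supplied")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  if (!ok) abort_model("output directory %s is not writable", out_dir)
  unlink(probe)

  manifest <- list(package = "dfucea",
                   version = as.character(utils::packageVersion("dfucea")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seeds = list(), files = character())
  emit <- function(df, fname) {
    utils::write.csv(df, file.path(out_dir, fname), row.names = FALSE)
    manifest$files <<- c(manifest$files, fname)
  }

  if (!is.null(results$model_path)) {
    manifest$model_digest <- unname(tools::md5sum(results$model_path))
    manifest$model_path <- results$model_path
  }
  if (!is.null(results$basecase)) {
    emit(summary_table(results$basecase), "basecase_summary.csv")
  }
  for (i in seq_along(results$scenarios)) {
    sc <- results$scenarios[[i]]
    emit(summary_table(sc), sprintf("scenario_%s.csv",
                                    gsub("[^A-Za-z0-9]+", "_", sc$scenario %||% i)))
  }
  if (!is.null(results$psa)) {
    psa <- results$psa
    manifest$seeds$psa <- psa$seed
    emit(psa$iterations, "psa_iterations.csv")
    ceac <- compute_ceac(psa)
    emit(ceac, "ceac.csv")
    grDevices::pdf(file.path(out_dir, "ceac.pdf"), width = 6, height = 4)
    print(plot_ceac(ceac, psa$wtp_thresholds))
    grDevices::dev.off()
    grDevices::pdf(file.path(out_dir, "ce_plane.pdf"), width = 6, height = 5)
    print(plot_ce_plane(psa))
    grDevices::dev.off()
    manifest$files <- c(manifest$files, "ceac.pdf", "ce_plane.pdf")
    manifest$psa_note <- paste("mean of signed per-iteration ICERs is reported",
                               "for completeness but is a known pathological",
                               "summary; prefer the median ICER and the CEAC")
  }
  if (!is.null(results$tornado)) {
    emit(as.data.frame(results$tornado), "tornado.csv")
    grDevices::pdf(file.path(out_dir, "tornado.pdf"), width = 7, height = 4)
    print(plot_tornado(results$tornado))
    grDevices::dev.off()
    manifest$files <- c(manifest$files, "tornado.pdf")
  }
  if (!is.null(results$microsim)) {
    ms <- results$microsim
    manifest$seeds$microsim <- vapply(ms$arms, function(a) a$seed, numeric(1))
    emit(ms$comparison, "microsim_events.csv")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
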