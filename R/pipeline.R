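# End-to-end run: simulate -> segment -> quantify -> stats -> report,
# deterministic under the master seed, with a manifest sufficient to
# reproduce the run.

#' Build a run configuration
#'
#' @param conditions Named list mapping condition labels to
#'   [optic_params()] objects (per-field seeds are overwritten by the
#'   cohort machinery).
#' @param reference Label of the reference (control) condition.
#' @param n_cells Cells per condition.
#' @param seed Master seed.
#' @param threshold,strict Positivity rule, see [classify_positive()].
#' @param segmentation Named list of overrides for [quantify_cohort()]
#'   segmentation arguments (`min_area`, `quantile`, `dilation_radius`,
#'   `cell_smooth_sigma`, `cluster_smooth_sigma`).
#' @return A validated object of class `optic_config`.
#' @export
optic_config <- function(conditions, reference, n_cells = 60, seed = 7,
                         threshold = 2, strict = FALSE,
                         segmentation = list()) {
  cfg <- structure(list(
    conditions = conditions, reference = reference,
    n_cells = n_cells, seed = as.integer(seed),
    threshold = threshold, strict = isTRUE(strict),
    segmentation = segmentation
  ), class = "optic_config")
  validate_optic_config(cfg)
  cfg
}

validate_optic_config <- function(cfg) {
  if (length(cfg$conditions) == 0 || is.null(names(cfg$conditions))) {
    stop("config error in `conditions`: a named list of conditions is required",
         call. = FALSE)
  }
  for (nm in names(cfg$conditions)) {
    if (!inherits(cfg$conditions[[nm]], "optic_params")) {
      stop("config error in `conditions`: '", nm,
           "' is not an optic_params object", call. = FALSE)
    }
  }
  if (!cfg$reference %in% names(cfg$conditions)) {
    stop("config error in `reference`: '", cfg$reference,
         "' is not a defined condition", call. = FALSE)
  }
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0) {
    stop("config error in `threshold`: must be > 0", call. = FALSE)
  }
  if (cfg$n_cells < 1) {
    stop("config error in `n_cells`: must be >= 1", call. = FALSE)
  }
  allowed <- c("min_area", "quantile", "dilation_radius",
               "cell_smooth_sigma", "cluster_smooth_sigma")
  bad <- setdiff(names(cfg$segmentation), allowed)
  if (length(bad)) {
    stop("config error in `segmentation`: unknown key(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Two-condition demonstration configuration
#'
#' One condition with three-fold enrichment versus a no-enrichment
#' control, 60 cells each — the cohort used by the packaged analysis
#' scripts and documentation examples.
#'
#' @param n_cells Cells per condition.
#' @param seed Master seed.
#' @return An `optic_config`.
#' @export
demo_config <- function(n_cells = 60, seed = 7) {
  optic_config(
    conditions = list(
      enriched = optic_params(enrichment_factor = 3),
      control = optic_params(enrichment_factor = 1)
    ),
    reference = "control", n_cells = n_cells, seed = seed
  )
}

#' Run the full quantification pipeline
#'
#' Simulates the configured cohort, segments every field, computes
#' per-cell recruitment records, aggregates condition summaries, runs the
#' ANOVA/Bonferroni report, and (optionally) writes everything plus
#' figures and a reproducibility manifest into `out_dir`. Deterministic
#' under the master seed.
#'
#' @param config An [optic_config()].
#' @param out_dir Output directory (created if missing), or `NULL` to
#'   skip writing and return results only.
#' @param figures Render the dot plot and percent-positive bar chart?
#' @return Invisibly, a list with `records`, `exclusions`, `summary`,
#'   `stats`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, figures = TRUE) {
  validate_optic_config(config)
  cohort <- simulate_cohort(config$conditions, config$n_cells, config$seed)
  seg <- config$segmentation
  q <- do.call(quantify_cohort, c(
    list(cohort = cohort, threshold = config$threshold,
         strict = config$strict), seg
  ))
  records <- q$records
  summary_df <- summarize_cohort(records)
  groups <- split(records$R, records$condition)
  stats_res <- anova_with_bonferroni(groups, reference = config$reference)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(q$exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_res$posthoc, file.path(out_dir, "posthoc.csv"),
                     row.names = FALSE)
    writeLines(stats_report_text(stats_res, config$reference),
               file.path(out_dir, "anova_report.txt"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("opticr")),
      r_version = R.version.string,
      seed = config$seed,
      n_cells = config$n_cells,
      threshold = config$threshold,
      strict = config$strict,
      reference = config$reference,
      conditions = lapply(config$conditions, function(p) {
        unclass(p)
      }),
      n_excluded = nrow(q$exclusions)
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    if (figures) {
      ggplot2::ggsave(file.path(out_dir, "recruitment_dotplot.pdf"),
                      plot_recruitment(records, summary_df),
                      width = 5, height = 4)
      ggplot2::ggsave(file.path(out_dir, "percent_positive.pdf"),
                      plot_percent_positive(summary_df),
                      width = 4, height = 4)
    }
  }
  invisible(list(records = records, exclusions = q$exclusions,
                 summary = summary_df, stats = stats_res,
                 out_dir = out_dir))
}

stats_report_text <- function(stats_res, reference) {
  c(
    sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g",
            stats_res$df_between, stats_res$df_within,
            stats_res$F_statistic, stats_res$p_value),
    sprintf("Bonferroni post-hoc versus reference '%s':", reference),
    utils::capture.output(print(stats_res$posthoc, row.names = FALSE))
  )
}

#' Per-cell recruitment dot plot with mean and 95% CI
#'
#' @param records Record table from [quantify_cohort()].
#' @param summary_df Matching [summarize_cohort()] output.
#' @return A ggplot object.
#' @export
plot_recruitment <- function(records, summary_df) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$condition, y = .data$R)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::geom_errorbar(
      data = summary_df,
      ggplot2::aes(x = .data$condition, ymin = .data$ci_low,
                   ymax = .data$ci_high),
      inherit.aes = FALSE, width = 0.25
    ) +
    ggplot2::geom_point(
      data = summary_df,
      ggplot2::aes(x = .data$condition, y = .data$mean_R),
      inherit.aes = FALSE, shape = 95, size = 8
    ) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "recruitment ratio R") +
    ggplot2::theme_classic()
}

#' Percent-positive bar chart
#'
#' @param summary_df Output of [summarize_cohort()].
#' @return A ggplot object.
#' @export
plot_percent_positive <- function(summary_df) {
  ggplot2::ggplot(summary_df,
                  ggplot2::aes(x = .data$condition,
                               y = .data$percent_positive)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = NULL, y = "cells with R >= 2 (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_classic()
}
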