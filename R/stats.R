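# Condition-level aggregation: mean R with a Student-t 95% CI, the
# percentage of positive cells, and one-way ANOVA with Bonferroni-adjusted
# post-hoc comparisons versus a reference condition.

#' Summarize recruitment records for one condition
#'
#' @param records Data frame of per-cell records (needs columns `R`,
#'   `positive`, and optionally `condition`), at least 2 rows.
#' @param conf_level Confidence level for the Student-t interval on the
#'   mean of R.
#' @return One-row data frame: `condition`, `n`, `mean_R`, `ci_low`,
#'   `ci_high`, `percent_positive`.
#' @export
summarize_condition <- function(records, conf_level = 0.95) {
  n <- nrow(records)
  if (is.null(n) || n < 2) {
    stop("insufficient data: at least 2 records are required", call. = FALSE)
  }
  m <- mean(records$R)
  half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
    stats::sd(records$R) / sqrt(n)
  cond <- if ("condition" %in% names(records))
    unique(records$condition)[1] else NA_character_
  data.frame(
    condition = cond, n = n, mean_R = m,
    ci_low = m - half, ci_high = m + half,
    percent_positive = 100 * mean(records$positive),
    stringsAsFactors = FALSE
  )
}

#' Summarize all conditions in a record table
#'
#' @param records Data frame with a `condition` column.
#' @inheritParams summarize_condition
#' @return A data frame with one row per condition.
#' @export
summarize_cohort <- function(records, conf_level = 0.95) {
  pieces <- lapply(split(records, records$condition),
                   summarize_condition, conf_level = conf_level)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"))
}

#' One-way ANOVA with Bonferroni post-hoc tests
#'
#' Fits a standard one-way ANOVA over the groups, then performs two-sided
#' pairwise t-tests using the pooled ANOVA error term (mean squared error,
#' residual degrees of freedom). By default each condition is compared to
#' the reference condition only, mirroring figure legends that test
#' differences from a negative control; `all_pairs = TRUE` compares every
#' pair. Raw p-values are Bonferroni-adjusted over the number of
#' comparisons actually performed (`adjusted = min(1, m * raw)`), and
#' significance codes `***`, `**`, `*` correspond to adjusted p below
#' 0.001, 0.01, 0.05.
#'
#' @param groups Named list of numeric vectors of per-cell R values, one
#'   per condition; at least 2 groups of at least 2 values each.
#' @param reference Name of the reference (control) condition. Defaults to
#'   the first group.
#' @param all_pairs Compare all pairs instead of versus-reference only?
#' @return A list with `F_statistic`, `p_value`, `df_between`,
#'   `df_within`, and `posthoc` (data frame: `condition`, `reference`,
#'   `mean_diff`, `t`, `df`, `raw_p`, `adjusted_p`, `significance`).
#' @export
anova_with_bonferroni <- function(groups, reference = NULL,
                                  all_pairs = FALSE) {
  if (length(groups) < 2) {
    stop("insufficient data: at least 2 groups are required", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named list", call. = FALSE)
  }
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) {
    stop("insufficient data: every group needs at least 2 values",
         call. = FALSE)
  }
  if (is.null(reference)) reference <- names(groups)[1]
  if (!reference %in% names(groups)) {
    stop("reference condition '", reference, "' is not among the groups",
         call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), ns), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  df_within <- tab["Residuals", "Df"]
  means <- vapply(groups, mean, numeric(1))

  if (all_pairs) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  } else {
    pairs <- lapply(setdiff(names(groups), reference),
                    function(g) c(g, reference))
  }
  m <- length(pairs)
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tval <- (means[[a]] - means[[b]]) / se
    raw <- 2 * stats::pt(-abs(tval), df_within)
    data.frame(condition = a, reference = b,
               mean_diff = means[[a]] - means[[b]],
               t = tval, df = df_within, raw_p = raw,
               adjusted_p = min(1, m * raw), stringsAsFactors = FALSE)
  }))
  posthoc$significance <- as.character(signif_stars(posthoc$adjusted_p))
  list(
    F_statistic = tab["group", "F value"],
    p_value = tab["group", "Pr(>F)"],
    df_between = tab["group", "Df"],
    df_within = df_within,
    posthoc = posthoc
  )
}
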