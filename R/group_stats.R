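# Group summaries and significance testing.
#
# Two groups: two-tailed unpaired Student t test (classical equal-variance
# form; Welch available via `welch = TRUE`). Three or more groups: one-way
# ANOVA F test. No multiple-testing correction is applied.

#' Per-group summary statistics
#'
#' @param values numeric vector of per-image metric values.
#' @param labels group label for each value.
#' @return data frame with `label`, `n`, `mean`, `sd`, `sem`. For singleton
#'   groups the SD is reported as 0 and flagged with `n = 1`.
#' @export
summarize_groups <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  if (length(values) == 0) stop("no values to summarize")
  labels <- as.character(labels)
  if (anyNA(values) || anyNA(labels)) stop("values and labels must be non-missing")
  out <- do.call(rbind, lapply(split(values, labels), function(v) {
    s <- if (length(v) > 1) stats::sd(v) else 0
    data.frame(n = length(v), mean = mean(v), sd = s, sem = s / sqrt(length(v)))
  }))
  out <- cbind(data.frame(label = rownames(out), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Significance stars for a p-value
#'
#' `p < 0.0001`: `"****"`; `< 0.001`: `"***"`; `< 0.01`: `"**"`; `< 0.05`:
#' `"*"`; otherwise `"ns"`. Inequalities are strict, so `p = 0.05` is
#' non-significant.
#'
#' @param p p-value in `[0, 1]`.
#' @return Character scalar.
#' @export
assign_stars <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Compare a metric across groups
#'
#' Exactly two groups are compared with a two-tailed unpaired Student t
#' test (pooled variance unless `welch = TRUE`); three or more with a
#' one-way ANOVA F test.
#'
#' @param values numeric vector of per-image metric values.
#' @param labels group label per value; every group needs `n >= 2`.
#' @param metric name of the metric (for reporting).
#' @param welch use the Welch (unequal-variance) t test for 2 groups.
#' @return A `group_comparison`: `metric`, `groups` (summary data frame),
#'   `test`, `statistic`, `df`, `p_value`, `stars`.
#' @export
compare_groups <- function(values, labels, metric = "metric", welch = FALSE) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  groups <- split(values, labels)
  if (length(groups) < 2) stop("need at least 2 groups to compare")
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small) > 0)
    stop(sprintf("group(s) with fewer than 2 values: %s", paste(small, collapse = ", ")))
  if (length(groups) == 2) {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = !welch)
    test <- if (welch) "t_welch" else "t_unpaired"
    statistic <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  } else {
    df_long <- data.frame(v = values, g = factor(labels))
    fit <- stats::anova(stats::aov(v ~ g, data = df_long))
    test <- "anova_oneway"
    statistic <- fit$`F value`[1]; df <- fit$Df[1]; p <- fit$`Pr(>F)`[1]
  }
  # identical groups give 0/0 -> NaN; no evidence of a difference
  if (is.nan(statistic)) { statistic <- 0; p <- 1 }
  if (is.nan(p)) p <- 1
  structure(list(metric = metric,
                 groups = summarize_groups(values, labels),
                 test = test, statistic = statistic, df = df,
                 p_value = p, stars = assign_stars(p)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s, statistic %.4g, p = %.3g %s\n",
              x$metric, x$test, x$statistic, x$p_value, x$stars))
  gs <- x$groups
  for (i in seq_len(nrow(gs)))
    cat(sprintf("  %s: %.4g +/- %.3g (n = %d)\n", gs$label[i], gs$mean[i], gs$sd[i], gs$n[i]))
  invisible(x)
}
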