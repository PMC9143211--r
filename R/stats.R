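# Group statistics: normality-gated two-sample comparisons, matching the
# clinical convention of testing each metric between recurrent and
# non-recurrent patients.

.lilliefors_null_cache <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

lilliefors_null <- function(n, nsim = 10000L) {
  key <- paste0("n", n, "_", nsim)
  if (!is.null(.lilliefors_null_cache[[key]])) return(.lilliefors_null_cache[[key]])
  # deterministic null table per sample size, independent of the caller's RNG
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(777000L + n)
  stats_null <- vapply(seq_len(nsim),
                       function(i) lilliefors_stat(stats::rnorm(n)), numeric(1))
  stats_null <- sort(stats_null)
  .lilliefors_null_cache[[key]] <- stats_null
  stats_null
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS distance of the sample against a normal distribution with
#' mean and SD estimated from the same sample. Because the parameters are
#' estimated, the plain KS null is anticonservative; the p-value is therefore
#' taken from a Monte-Carlo null distribution of the statistic (10^4 seeded
#' draws, memoised per sample size) -- the Lilliefors correction.
#'
#' @param sample numeric vector, n >= 4, non-constant.
#' @param nsim Monte-Carlo null size.
#' @return list with `statistic` (the KS distance D) and `p`.
#' @export
normality_test <- function(sample, nsim = 10000L) {
  sample <- as.numeric(sample)
  if (length(sample) < 4) stop("normality test needs n >= 4")
  if (stats::sd(sample) == 0) stop("constant sample: zero variance")
  d <- lilliefors_stat(sample)
  null <- lilliefors_null(length(sample), nsim)
  p <- (sum(null >= d) + 1) / (length(null) + 1)
  list(statistic = d, p = p)
}

#' Two-group comparison with a normality gate
#'
#' Tests whether a metric differs between two patient groups. If both groups
#' pass the Lilliefors normality test at `alpha` (and are large enough to test,
#' n >= 4), a pooled-variance two-sample t-test is used; otherwise the
#' Mann-Whitney U (Wilcoxon rank-sum) test: exact when group sizes are small
#' and tie-free, tie-corrected normal approximation otherwise. Two-sided
#' throughout.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param alpha normality gate level (default 0.05).
#' @param metric optional metric name carried into the result.
#' @param labels length-2 group labels.
#' @param welch use the Welch (unequal-variance) t-test instead of the pooled
#'   one; off by default to match the classical Student label.
#' @return an object of class `group_comparison`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, metric = NULL,
                           labels = c("a", "b"), welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  norm_p <- function(x) {
    if (length(x) < 4) return(NA_real_)
    tryCatch(normality_test(x)$p, error = function(e) NA_real_)
  }
  pa <- norm_p(a); pb <- norm_p(b)
  both_normal <- !is.na(pa) && !is.na(pb) && pa > alpha && pb > alpha
  if (length(unique(c(a, b))) == 1L) {
    test <- "MWW"; statistic <- 0; p <- 1
  } else if (both_normal) {
    tt <- stats::t.test(a, b, var.equal = !welch)
    test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    exact <- length(a) < 50 && length(b) < 50 &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    test <- "MWW"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(
    metric = metric, labels = labels,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    min = c(min(a), min(b)),
    max = c(max(a), max(b)),
    test = test, statistic = statistic, p = p,
    normality_p = c(pa, pb)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", if (!is.null(x$metric)) x$metric else "", "\n")
  for (g in 1:2)
    cat(sprintf("  %-12s n=%2d mean=%8.2f min=%8.2f max=%8.2f\n",
                x$labels[g], x$n[g], x$mean[g], x$min[g], x$max[g]))
  cat(sprintf("  %s test: statistic = %.4g, p = %.4g\n", x$test, x$statistic, x$p))
  invisible(x)
}

#' Tabulate osteotomy-plane classifications
#'
#' Counts planes per cortical-involvement category, optionally cross-tabulated
#' by patient group.
#'
#' @param classifications data.frame with a `category` column (values among
#'   outside / lingual_only / buccal_only / bicortical) and optionally a
#'   `group` column; or a list of `cortical_classification` objects.
#' @return list with `total` (named counts summing to the number of planes)
#'   and, when groups are present, `by_group` (category x group table).
#' @export
tabulate_osteotomies <- function(classifications) {
  lv <- c("outside", "lingual_only", "buccal_only", "bicortical")
  if (is.data.frame(classifications)) {
    cat_f <- factor(classifications$category, levels = lv)
    total <- table(cat_f)
    by_group <- if (!is.null(classifications$group))
      table(cat_f, factor(classifications$group)) else NULL
  } else {
    cats <- vapply(classifications, `[[`, character(1), "category")
    total <- table(factor(cats, levels = lv))
    by_group <- NULL
  }
  out <- list(total = total)
  if (!is.null(by_group)) out$by_group <- by_group
  out
}

#' Cohort summary and group comparisons for all metrics
#'
#' Produces the classic per-group mean/min/max summary for every metric field
#' and a normality-gated comparison between the two groups for each. Also
#' flags metrics whose stored percentage disagrees with the percentage
#' recomputed from the mL fields by more than half a percentage point.
#'
#' @param metrics data.frame with the [volume_metrics()] fields plus a group
#'   column.
#' @param group_col name of the group column (must have exactly 2 levels).
#' @param alpha normality gate level.
#' @return list with `summary` (data.frame: group x metric mean/min/max),
#'   `comparisons` (named list of `group_comparison`), and
#'   `percent_inconsistencies` (character vector of flagged fields).
#' @export
cohort_summary <- function(metrics, group_col = "group", alpha = 0.05) {
  if (!group_col %in% names(metrics))
    stop("group column '", group_col, "' not found; available: ",
         paste(names(metrics), collapse = ", "))
  groups <- unique(as.character(metrics[[group_col]]))
  if (length(groups) < 2) stop("need at least two groups, got: ",
                               paste(groups, collapse = ", "))
  if (length(groups) > 2) stop("exactly two groups supported, got: ",
                               paste(groups, collapse = ", "))
  fields <- intersect(metric_fields(), names(metrics))
  rows <- list()
  comparisons <- list()
  for (f in fields) {
    va <- metrics[[f]][metrics[[group_col]] == groups[1]]
    vb <- metrics[[f]][metrics[[group_col]] == groups[2]]
    comparisons[[f]] <- compare_groups(va, vb, alpha = alpha, metric = f,
                                       labels = groups)
    for (g in seq_along(groups)) {
      v <- if (g == 1) va else vb
      rows[[length(rows) + 1L]] <- data.frame(
        group = groups[g], metric = f, n = length(v),
        mean = mean(v), min = min(v), max = max(v))
    }
  }
  flagged <- character(0)
  pct_pairs <- list(Vm56_over_Vm = "Vm56", Vm_PTV_over_Vm = "Vm_PTV",
                    VmR_over_Vm = "VmR")
  for (pf in names(pct_pairs)) {
    if (!pf %in% names(metrics)) next
    recomputed <- 100 * metrics[[pct_pairs[[pf]]]] / metrics[["Vm"]]
    if (any(abs(recomputed - metrics[[pf]]) > 0.5, na.rm = TRUE))
      flagged <- c(flagged, pf)
  }
  list(summary = do.call(rbind, rows), comparisons = comparisons,
       percent_inconsistencies = flagged)
}
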