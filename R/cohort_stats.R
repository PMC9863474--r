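# Cohort-level descriptive and inferential statistics: per-procedure score
# summaries, between-group comparisons and contingency tests.

#' Summarize PAPVR ratios per surgical procedure
#'
#' Per-group patient count, mean ratio and sample standard deviation (n - 1
#' denominator; `NA` for singleton groups), together with between-group
#' tests: the omnibus comparison across all groups and, when more than two
#' groups are present, each group against the rest. Both are reported and
#' labelled explicitly rather than collapsed into one per-row p-value.
#'
#' @param ratio Numeric vector of PAPVR ratios.
#' @param actual Procedure labels, one per patient.
#' @return Object of class `cohort_summary`: list with `groups`
#'   (data.frame of `procedure`, `n`, `mean_ratio`, `sd_ratio`), `omnibus`
#'   (a [compare_groups()] result, or `NULL` when fewer than two groups have
#'   two or more members) and `vs_rest` (named list of group-vs-rest test
#'   results, `NULL` entries where sizes are insufficient).
#' @export
#' @examples
#' s <- summarize_cohort(c(0.4, 0.6, 0.8, 0.9),
#'                       c("SINGLE_PATCH", "SINGLE_PATCH", "WARDEN", "WARDEN"))
#' s$groups
summarize_cohort <- function(ratio, actual) {
  ratio <- as.numeric(ratio)
  if (length(ratio) == 0L) stop("empty cohort", call. = FALSE)
  if (length(ratio) != length(actual)) {
    stop("`ratio` and `actual` must have equal length", call. = FALSE)
  }
  actual <- as.character(actual)
  if (any(is.na(actual)) || any(!nzchar(actual))) {
    stop("every patient needs an actual procedure label", call. = FALSE)
  }
  lv <- intersect(c(surgical_labels(), "PATCH"), unique(actual))
  if (!length(lv)) lv <- sort(unique(actual))
  g <- factor(actual, levels = lv)
  n <- as.integer(table(g))
  groups <- data.frame(
    procedure = lv,
    n = n,
    mean_ratio = as.numeric(tapply(ratio, g, mean)),
    sd_ratio = ifelse(n >= 2L, as.numeric(tapply(ratio, g, stats::sd)), NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(groups) <- NULL

  testable <- sum(n >= 2L) >= 2L
  omnibus <- if (testable) {
    compare_groups(ratio[g %in% lv[n >= 2L]],
                   droplevels(g[g %in% lv[n >= 2L]]))
  }
  vs_rest <- NULL
  if (length(lv) > 2L) {
    vs_rest <- stats::setNames(lapply(lv, function(l) {
      dich <- factor(ifelse(actual == l, l, "rest"), levels = c(l, "rest"))
      if (min(table(dich)) < 2L) return(NULL)
      compare_groups(ratio, dich)
    }), lv)
  }
  structure(list(groups = groups, omnibus = omnibus, vs_rest = vs_rest),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Mean PAPVR ratio by surgical procedure\n")
  g <- x$groups
  cat(sprintf("  %-22s %3s %6s %6s\n", "procedure", "n", "mean", "SD"))
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-22s %3d %6.2f %6s\n", g$procedure[i], g$n[i],
                g$mean_ratio[i],
                ifelse(is.na(g$sd_ratio[i]), "-", sprintf("%.2f", g$sd_ratio[i]))))
  }
  if (!is.null(x$omnibus)) {
    cat(sprintf("omnibus (%s): p = %.3g\n", x$omnibus$method,
                x$omnibus$p_value))
  }
  if (!is.null(x$vs_rest)) {
    for (nm in names(x$vs_rest)) {
      t <- x$vs_rest[[nm]]
      if (!is.null(t)) {
        cat(sprintf("%s vs rest (%s): p = %.3g\n", nm, t$method, t$p_value))
      }
    }
  }
  invisible(x)
}

# Shapiro-type normality screen; constant samples count as non-normal
.normal_enough <- function(x, alpha = 0.05) {
  if (length(x) < 3L || stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Compare PAPVR ratios between surgical groups
#'
#' In `auto` mode a Welch two-sample t-test is used when there are exactly
#' two groups and both pass a Shapiro-Wilk normality screen at alpha = 0.05
#' (requiring n >= 3 per group); otherwise the Kruskal-Wallis rank-sum test.
#' Tests are two-sided.
#'
#' @param ratio Numeric vector of scores.
#' @param group Group labels (2 or more groups, each with >= 2 members).
#' @param mode `"auto"`, `"t_test"` (two groups only) or `"kruskal_wallis"`.
#' @return List with `method`, `statistic`, `df` (`NA` where not
#'   applicable), `p_value`, `mode`.
#' @export
#' @examples
#' set.seed(1)
#' g <- rep(c("PATCH", "WARDEN"), each = 15)
#' r <- c(rnorm(15, 0.55, 0.1), rnorm(15, 0.85, 0.1))
#' compare_groups(r, g)$p_value
compare_groups <- function(ratio, group,
                           mode = c("auto", "t_test", "kruskal_wallis")) {
  mode <- match.arg(mode)
  ratio <- as.numeric(ratio)
  if (length(ratio) != length(group)) {
    stop("`ratio` and `group` must have equal length", call. = FALSE)
  }
  g <- factor(as.character(group))
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  if (mode == "t_test" && length(sizes) != 2L) {
    stop("t-test requires exactly two groups", call. = FALSE)
  }
  use_t <- switch(mode,
    t_test = TRUE,
    kruskal_wallis = FALSE,
    auto = length(sizes) == 2L &&
      all(tapply(ratio, g, .normal_enough))
  )
  if (use_t) {
    ht <- stats::t.test(ratio ~ g)  # Welch by default
    list(method = "Welch t-test", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value, mode = mode)
  } else {
    if (stats::sd(ratio) == 0) {
      # all observations identical: no evidence of any group difference
      return(list(method = "Kruskal-Wallis rank-sum", statistic = 0,
                  df = length(sizes) - 1L, p_value = 1, mode = mode))
    }
    ht <- stats::kruskal.test(ratio, g)
    list(method = "Kruskal-Wallis rank-sum",
         statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value, mode = mode)
  }
}

#' Test association in a contingency table of nominal variables
#'
#' For a 2x2 table Fisher's exact test is used whenever any expected cell
#' count is below 5, otherwise Pearson's chi-square (without continuity
#' correction); larger tables use Pearson's chi-square. For 2x2 tables the
#' sample (cross-product) odds ratio is reported alongside.
#'
#' @param tab Matrix of non-negative integer counts, at least 2x2.
#' @return List with `method`, `statistic` (`NA` for Fisher), `p_value`,
#'   and `odds_ratio` (2x2 only, possibly `Inf`).
#' @export
#' @examples
#' association_test(matrix(c(3, 0, 0, 3), 2))$p_value   # Fisher exact, 0.1
association_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(is.na(tab)) || !is.numeric(tab) || any(tab < 0) ||
      any(tab != round(tab))) {
    stop("`tab` must contain non-negative integer counts", call. = FALSE)
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("`tab` must be at least 2x2", call. = FALSE)
  }
  storage.mode(tab) <- "integer"
  is2x2 <- all(dim(tab) == 2L)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  or <- if (is2x2) (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]) else NA_real_
  if (is2x2 && any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    list(method = "Fisher exact", statistic = NA_real_,
         p_value = ht$p.value, odds_ratio = or)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = "Pearson chi-square",
         statistic = unname(ht$statistic),
         p_value = ht$p.value, odds_ratio = or)
  }
}
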