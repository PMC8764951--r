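#' Mean and standard error of the mean
#'
#' Summary convention of the emulated study's figures (mean +/- SEM), with
#' the sample (n-1) SD.
#'
#' @param values numeric vector, `n >= 2`.
#' @return named vector `mean`, `sem`, `n`.
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop_input("SEM undefined for n = %d (need n >= 2)", length(values))
  c(mean = mean(values), sem = stats::sd(values) / sqrt(length(values)),
    n = length(values))
}

stat_result <- function(comparison, test_name, statistic, p_value, n,
                        pairwise = NULL) {
  structure(list(comparison = comparison, test_name = test_name,
                 statistic = unname(statistic), p_value = unname(p_value),
                 significant = is.finite(p_value) && p_value < 0.05,
                 n = n, pairwise = pairwise),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g, p = %.4g%s (n = %s)\n",
              x$comparison, x$test_name, x$statistic, x$p_value,
              if (x$significant) " *" else "", paste(x$n, collapse = "/")))
  if (!is.null(x$pairwise)) {
    cat("  pairwise Mann-Whitney follow-ups:\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s vs %s: p = %.4g%s\n", x$pairwise$a[i],
                  x$pairwise$b[i], x$pairwise$p_value[i],
                  if (x$pairwise$p_value[i] < 0.05) " *" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.stat_result <- function(x, ...) {
  data.frame(comparison = x$comparison, test_name = x$test_name,
             statistic = x$statistic, p_value = x$p_value,
             significant = x$significant, n = paste(x$n, collapse = "/"))
}

# Shapiro-Wilk gate at alpha = 0.05; degenerate samples count as non-normal
is_normalish <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3L || length(x) < 3L || length(x) > 5000L)
    return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

# exact distributions only for small, tie-free samples
use_exact <- function(x, max_n = 12L) length(x) <= max_n && !any(duplicated(x))

#' Within-group paired comparison with a normality gate
#'
#' The study's within-group scheme: the paired differences are tested for
#' normality (Shapiro-Wilk at alpha = 0.05); normal differences get a paired
#' t-test, otherwise a Wilcoxon signed-rank test (exact for n <= 12 without
#' ties or zeros, normal approximation with continuity correction otherwise).
#' All tests two-sided at alpha = 0.05. All-zero differences yield p = 1 by
#' convention.
#'
#' @param values_a,values_b paired samples, equal length `n >= 3`.
#' @param comparison label stored in the result.
#' @param test `"auto"` (the normality gate) or a forced choice.
#' @return a `stat_result`.
#' @export
compare_within <- function(values_a, values_b, comparison = "within",
                           test = c("auto", "paired_t",
                                    "wilcoxon_signed_rank")) {
  test <- match.arg(test)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b))
    stop_input("paired samples must have equal length (%d vs %d)",
               length(a), length(b))
  if (length(a) < 3L) stop_input("need n >= 3 pairs (got %d)", length(a))
  d <- b - a
  if (all(d == 0))
    return(stat_result(comparison, "wilcoxon_signed_rank", 0, 1, length(a)))
  if (test == "paired_t" || (test == "auto" && is_normalish(d))) {
    tt <- stats::t.test(b, a, paired = TRUE)
    stat_result(comparison, "paired_t", tt$statistic, tt$p.value, length(a))
  } else {
    nz <- d[d != 0]
    wt <- suppressWarnings(stats::wilcox.test(
      b, a, paired = TRUE, exact = use_exact(abs(nz)), correct = TRUE))
    stat_result(comparison, "wilcoxon_signed_rank", wt$statistic, wt$p.value,
                length(a))
  }
}

#' Between-group comparison with a normality gate
#'
#' The study's between-group scheme: if every group passes the Shapiro-Wilk
#' gate, a one-way ANOVA; otherwise Mann-Whitney U for two groups or
#' Kruskal-Wallis for three or more, with pairwise Mann-Whitney follow-ups
#' when the omnibus test is significant. Exact Mann-Whitney distributions
#' for small tie-free samples. No multiple-testing correction is applied
#' (matching the emulated analysis); reports flag this.
#'
#' @param groups named list of numeric vectors, each `n >= 3`.
#' @param comparison label stored in the result.
#' @param test `"auto"` (the normality gate) or a forced choice
#'   (`"nonparametric"` selects Mann-Whitney or Kruskal-Wallis by group
#'   count).
#' @return a `stat_result`; pairwise follow-ups (if any) in `$pairwise`.
#' @export
compare_between <- function(groups, comparison = "between",
                            test = c("auto", "anova", "nonparametric")) {
  test <- match.arg(test)
  if (!is.list(groups) || length(groups) < 2L)
    stop_input("need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 3L)) stop_input("each group needs n >= 3 (got %s)",
                               paste(ns, collapse = ", "))
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), ns), levels = names(groups))
  if (test == "anova" ||
      (test == "auto" && all(vapply(groups, is_normalish, logical(1))))) {
    if (stats::var(vals) == 0)
      return(stat_result(comparison, "anova", 0, 1, ns))
    fit <- stats::aov(vals ~ fac)
    s <- summary(fit)[[1L]]
    return(stat_result(comparison, "anova", s[["F value"]][1L],
                       s[["Pr(>F)"]][1L], ns))
  }
  mw <- function(x, y) suppressWarnings(stats::wilcox.test(
    x, y, exact = length(x) <= 12L && length(y) <= 12L &&
      !any(duplicated(c(x, y))), correct = TRUE))
  if (length(groups) == 2L) {
    wt <- mw(groups[[1L]], groups[[2L]])
    return(stat_result(comparison, "mann_whitney_u", wt$statistic, wt$p.value,
                       ns))
  }
  kw <- stats::kruskal.test(vals, fac)
  pairwise <- NULL
  if (kw$p.value < 0.05) {
    cmb <- utils::combn(names(groups), 2L)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      wt <- mw(groups[[cmb[1L, j]]], groups[[cmb[2L, j]]])
      data.frame(a = cmb[1L, j], b = cmb[2L, j], U = unname(wt$statistic),
                 p_value = wt$p.value)
    }))
  }
  stat_result(comparison, "kruskal_wallis", kw$statistic, kw$p.value, ns,
              pairwise = pairwise)
}
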