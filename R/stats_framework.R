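# Statistical comparison framework: independence-preserving subsampling
# from time series, assumption-driven test selection (parametric vs
# rank-based), post-hoc comparisons, and FDR adjustment.

#' Random subsample of a time series
#'
#' Draws n values at uniformly random time indices without replacement.
#' Random index sampling decorrelates autocorrelated series so that
#' downstream tests can treat the values as independent.
#'
#' @param series Numeric vector.
#' @param n Sample size (<= length of the series).
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return Numeric vector of n values.
#' @export
subsample_series <- function(series, n, seed) {
  if (n > length(series)) {
    stop(sprintf("subsample size %d exceeds series length %d",
                 n, length(series)))
  }
  .with_seed(seed, series[sample.int(length(series), n)])
}

#' Assumption-driven group comparison
#'
#' Checks normality (Shapiro-Wilk per group) and variance homogeneity
#' (Levene, mean-centered) at the given alpha. If both hold, uses one-way
#' ANOVA with Tukey HSD post-hoc (for > 2 groups) or a pooled-variance
#' t-test (2 groups); otherwise Kruskal-Wallis with Dunn post-hoc or
#' Mann-Whitney. Post-hoc p-values are FDR-adjusted. Groups of identical
#' constant values are degenerate and reported as non-significant with a
#' warning.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (same length).
#' @param alpha Significance level for assumption checks (default 0.05).
#' @return A `comparison_result`: list with `test`, `statistic`, `p`,
#'   `assumptions` (normality / equal-variance outcomes), `n_per_group`,
#'   `posthoc` (data.frame comparison, p, p_adjusted; NULL for 2 groups).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  split_vals <- split(values, groups)
  k <- length(split_vals)
  if (k < 2) stop("need at least 2 groups")
  if (any(lengths(split_vals) < 3)) stop("every group needs n >= 3")

  if (stats::var(values) == 0) {
    warning("all values identical across groups; comparison is degenerate")
    return(structure(list(test = "degenerate", statistic = NA_real_, p = 1,
                          assumptions = list(normal = NA, equal_var = NA),
                          n_per_group = lengths(split_vals), posthoc = NULL),
                     class = "comparison_result"))
  }

  normal_p <- vapply(split_vals, function(v) {
    if (stats::var(v) == 0) return(0)  # constant group: not normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(normal_p > alpha)
  lev <- car::leveneTest(values ~ groups, center = mean)
  equal_var <- lev[["Pr(>F)"]][1] > alpha

  posthoc <- NULL
  if (normal && equal_var) {
    if (k == 2) {
      tt <- stats::t.test(split_vals[[1]], split_vals[[2]],
                          var.equal = TRUE)
      test <- "t-test"; statistic <- unname(tt$statistic); p <- tt$p.value
    } else {
      fit <- stats::aov(values ~ groups)
      an <- summary(fit)[[1]]
      test <- "anova"; statistic <- an[["F value"]][1]
      p <- an[["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$groups
      posthoc <- data.frame(comparison = rownames(tk),
                            p = tk[, "p adj"],
                            p_adjusted = fdr_adjust(tk[, "p adj"]),
                            row.names = NULL)
    }
  } else {
    if (k == 2) {
      wt <- stats::wilcox.test(split_vals[[1]], split_vals[[2]],
                               exact = FALSE)
      test <- "mann-whitney"; statistic <- unname(wt$statistic)
      p <- wt$p.value
    } else {
      kw <- stats::kruskal.test(values, groups)
      test <- "kruskal-wallis"; statistic <- unname(kw$statistic)
      p <- kw$p.value
      posthoc <- .dunn_test(values, groups)
    }
  }
  structure(list(test = test, statistic = statistic, p = p,
                 assumptions = list(normal = normal, equal_var = equal_var,
                                    shapiro_p = normal_p,
                                    levene_p = lev[["Pr(>F)"]][1]),
                 n_per_group = lengths(split_vals), posthoc = posthoc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g>\n", x$test,
              x$statistic, x$p))
  invisible(x)
}

# Dunn's rank-based post-hoc test with tie correction; pairwise z tests on
# mean ranks, two-sided, FDR-adjusted.
.dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lev <- levels(groups)
  out <- list()
  for (i in seq_along(lev)[-length(lev)]) {
    for (j in (i + 1):length(lev)) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
      z <- (rbar[i] - rbar[j]) / se
      out[[length(out) + 1L]] <- data.frame(
        comparison = paste(lev[j], lev[i], sep = "-"),
        p = 2 * stats::pnorm(-abs(z)))
    }
  }
  res <- do.call(rbind, out)
  res$p_adjusted <- fdr_adjust(res$p)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-preserving and capped at 1.
#'
#' @param p_values Numeric vector in [0, 1].
#' @param method `"BH"` (default) or `"BY"` (Benjamini-Yekutieli).
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.04, 0.03, 0.005)) # 0.02 0.04 0.04 0.02
fdr_adjust <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Full subsample-compare-adjust pipeline on grouped time series
#'
#' For each group, subsamples n values at random time indices, runs the
#' assumption-driven comparison, and FDR-adjusts the resulting p-value(s).
#'
#' @param data data.frame with columns `group`, `value` (and optionally
#'   `time`), as produced by [make_null_timeseries()].
#' @param n Subsample size per group (default 100).
#' @param seed RNG seed for the subsampling.
#' @param alpha Assumption-check level.
#' @return A `comparison_result` with an extra `p_adjusted` field.
#' @export
compare_timeseries_groups <- function(data, n = 100, seed = 1,
                                      alpha = 0.05) {
  groups <- unique(data$group)
  vals <- list()
  for (gi in seq_along(groups)) {
    series <- data$value[data$group == groups[gi]]
    vals[[gi]] <- subsample_series(series, n, seed + gi)
  }
  res <- compare_groups(unlist(vals),
                        rep(groups, vapply(vals, length, integer(1))),
                        alpha = alpha)
  res$p_adjusted <- fdr_adjust(res$p)
  res
}
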