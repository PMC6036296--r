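# Normality-gated group comparisons: Shapiro-Wilk decides between
# parametric (Student's t / one-way ANOVA with Tukey post hoc) and
# nonparametric (Mann-Whitney U) routes; significance at two-sided
# alpha = 0.05. Test internals are delegated to base R; this module owns
# the gating, orchestration and reporting.

#' @importFrom stats shapiro.test t.test wilcox.test aov TukeyHSD
NULL

# Internal: per-group descriptive summary.
.group_summary <- function(groups) {
  do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(group = g, n = length(x), mean = mean(x),
               median = median(x), sd = sd(x),
               sem = sd(x) / sqrt(length(x)), stringsAsFactors = FALSE)
  }))
}

.name_groups <- function(groups, default = c("a", "b")) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- if (length(groups) == length(default)) default
                     else paste0("g", seq_along(groups))
  groups
}

#' Normality gate for a set of samples
#'
#' Applies the Shapiro-Wilk test to every group; the comparison is routed
#' to the parametric tests only if *every* group is consistent with
#' normality at `alpha` (a single non-normal group makes the whole
#' comparison nonparametric — the conservative reading when the testing
#' protocol does not say otherwise). Groups with fewer than 3 observations
#' cannot be tested and force the nonparametric route with a warning.
#'
#' @param groups list of numeric vectors (names optional).
#' @param alpha Shapiro-Wilk rejection level (default 0.05).
#' @return list of class `"normality_gate"`: `route` (`"parametric"` or
#'   `"nonparametric"`) and `shapiro`, a data.frame of per-group W and p.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  groups <- .name_groups(groups)
  res <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) < 3L)
      return(data.frame(group = g, n = length(x), W = NA_real_,
                        p = NA_real_, normal = FALSE))
    sw <- shapiro.test(x)
    data.frame(group = g, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, normal = sw$p.value >= alpha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (any(res$n < 3L))
    warning("group(s) with n < 3 cannot be tested for normality; ",
            "routing to nonparametric tests")
  structure(list(route = if (all(res$normal)) "parametric"
                         else "nonparametric",
                 shapiro = res, alpha = alpha),
            class = "normality_gate")
}

#' Two-group comparison with normality gating
#'
#' Runs a two-sided Student's t-test (parametric route) or Mann-Whitney U
#' test (nonparametric route) between two samples, the route taken from a
#' [normality_gate()] over both groups unless supplied.
#'
#' @param a,b numeric samples.
#' @param gate `NULL` (gate computed from `a` and `b`), a
#'   `"normality_gate"` object, or `"parametric"`/`"nonparametric"`.
#' @param paired paired comparison (default `FALSE`).
#' @param alpha significance level (default 0.05).
#' @param labels length-2 character group labels.
#' @return list of class `"comparison_result"`: `test_name`, `statistic`,
#'   `p_value`, `significant` (`p_value < alpha`), `route`, `summaries`.
#' @examples
#' set.seed(1)
#' compare_two(rnorm(10), rnorm(10, 2))
#' @export
compare_two <- function(a, b, gate = NULL, paired = FALSE, alpha = 0.05,
                        labels = c("a", "b")) {
  if (!length(a) || !length(b)) stop("empty group")
  groups <- stats::setNames(list(a, b), labels)
  if (is.null(gate)) gate <- normality_gate(groups, alpha)
  route <- if (inherits(gate, "normality_gate")) gate$route
           else match.arg(gate, c("parametric", "nonparametric"))
  if (route == "parametric") {
    tt <- t.test(a, b, paired = paired, var.equal = TRUE)
    test_name <- if (paired) "paired Student's t-test"
                 else "Student's t-test"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = paired,
                                       exact = FALSE, correct = TRUE))
    test_name <- if (paired) "Wilcoxon signed-rank test"
                 else "Mann-Whitney U test"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p, alpha = alpha, significant = p < alpha,
                 route = route, summaries = .group_summary(groups)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test_name, ": statistic ", signif(x$statistic, 4), ", p ",
      signif(x$p_value, 4),
      if (x$significant) " (significant)" else " (ns)", "\n", sep = "")
  print(x$summaries, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("Tukey HSD:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Multi-group comparison: one-way ANOVA with Tukey post hoc
#'
#' Omnibus one-way ANOVA over three or more groups followed by Tukey
#' honest-significant-difference pairwise comparisons.
#'
#' @param groups named list of 3 or more numeric samples.
#' @param alpha significance level (default 0.05).
#' @return `"comparison_result"` with an additional `posthoc` data.frame
#'   (`comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
compare_many <- function(groups, alpha = 0.05) {
  if (length(groups) < 3L)
    stop("compare_many needs >= 3 groups; use compare_two()")
  groups <- .name_groups(groups)
  if (any(!vapply(groups, length, 1L)))
    stop("empty group")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  if (stats::var(y) == 0)
    stop("degenerate input: all observations identical")
  fit <- aov(y ~ g)
  sm <- summary(fit)[[1L]]
  f <- sm$`F value`[1L]
  p <- sm$`Pr(>F)`[1L]
  tk <- TukeyHSD(fit)$g
  posthoc <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(posthoc) <- NULL
  structure(list(test_name = "one-way ANOVA with Tukey post hoc",
                 statistic = f, p_value = p, alpha = alpha,
                 significant = p < alpha, route = "parametric",
                 summaries = .group_summary(groups), posthoc = posthoc),
            class = "comparison_result")
}

#' Fold change between group means
#'
#' Ratio of the numerator group's mean to the denominator group's mean, for
#' normalized quantities (e.g. glycogen per protein content).
#'
#' @param numerator,denominator numeric samples (or single summary values).
#' @return dimensionless ratio of means.
#' @examples
#' fold_change(c(29, 31, 30), c(9, 11, 10)) # 3
#' @export
fold_change <- function(numerator, denominator) {
  dm <- mean(denominator)
  if (dm <= 0) stop("denominator mean must be positive")
  mean(numerator) / dm
}
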