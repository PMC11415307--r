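# Group-comparison statistics with the normality-gated decision tree:
# Shapiro-Wilk per group; if all groups look normal, one-way ANOVA with
# Tukey's post hoc, otherwise Kruskal-Wallis with Dunn's post hoc. Pairwise
# comparisons use the Mann-Whitney rank-sum test.

#' Compare groups of permeability estimates
#'
#' Runs a Shapiro-Wilk normality test in each group at level `alpha`. If
#' every group passes, the omnibus test is one-way ANOVA with Tukey's HSD
#' post hoc; if any group fails (including degenerate groups on which the
#' normality test cannot run), the omnibus test is Kruskal-Wallis with Dunn's
#' post hoc (p-values adjusted with `p_adjust`). Established routines
#' ([stats::aov()], [stats::TukeyHSD()], [stats::kruskal.test()]) do the
#' testing; only Dunn's z-statistics are computed here (see [dunn_test()]).
#'
#' @param values Either a named list of numeric vectors (one per group) or a
#'   numeric vector accompanied by `groups`.
#' @param groups Group labels, when `values` is a vector.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @param p_adjust Adjustment method for Dunn's pairwise p-values (default
#'   `"holm"`); Tukey's HSD carries its own family-wise adjustment.
#' @return An object of class `group_comparison`: `branch` ("anova" or
#'   "kruskal"), `shapiro` (per-group p-values), `omnibus_p`, `pairwise`
#'   (data.frame with `group1`, `group2`, `p_adj`), `alpha`.
#' @export
compare_groups <- function(values, groups = NULL, alpha = 0.05,
                           p_adjust = "holm") {
  if (is.list(values) && is.null(groups)) {
    if (is.null(names(values))) {
      names(values) <- paste0("group", seq_along(values))
    }
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  stopifnot(is.numeric(values), length(groups) == length(values))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 3)) {
    stop("every group needs at least 3 values", call. = FALSE)
  }
  shapiro_p <- vapply(levels(g), function(lv) {
    x <- values[g == lv]
    tryCatch(stats::shapiro.test(x)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  normal <- !is.na(shapiro_p) & shapiro_p >= alpha
  if (all(normal)) {
    fit <- stats::aov(values ~ g)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    # rows follow combn(levels, 2) order as "second-first"; pair labels are
    # reconstructed positionally (group labels may themselves contain "-")
    combos <- utils::combn(levels(g), 2)
    pairwise <- data.frame(
      group1 = combos[1, ],
      group2 = combos[2, ],
      estimate = tk[, "diff"],
      p_adj = tk[, "p adj"],
      row.names = NULL)
    branch <- "anova"
    adjust_used <- "tukey"
  } else {
    kw <- stats::kruskal.test(values, g)
    omnibus_p <- kw$p.value
    pairwise <- dunn_test(values, g, p_adjust = p_adjust)
    branch <- "kruskal"
    adjust_used <- p_adjust
  }
  structure(list(branch = branch,
                 shapiro = data.frame(group = levels(g),
                                      n = as.integer(sizes),
                                      shapiro_p = shapiro_p,
                                      normal = normal, row.names = NULL),
                 omnibus_p = omnibus_p,
                 pairwise = pairwise,
                 p_adjust = adjust_used,
                 alpha = alpha), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s branch (normality gate at alpha = %g)\n",
              x$branch, x$alpha))
  cat(sprintf("  omnibus p = %.4g\n", x$omnibus_p))
  cat(sprintf("  pairwise (%s-adjusted):\n", x$p_adjust))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Dunn's post hoc test
#'
#' Rank-based pairwise comparisons following a Kruskal-Wallis test: all
#' observations are ranked jointly (average ranks for ties) and each pair of
#' groups is compared with
#' \deqn{z = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - T\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' where `T = sum(t^3 - t) / (12 (N - 1))` corrects for tied ranks. Two-sided
#' normal p-values are adjusted with [stats::p.adjust()].
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels.
#' @param p_adjust Adjustment method (default `"holm"`).
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "holm") {
  g <- factor(groups)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  n_tot <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  rbar <- tapply(r, g, mean)
  sizes <- table(g)
  combos <- utils::combn(levels(g), 2)
  z <- apply(combos, 2, function(pr) {
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) *
                 (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combos[1, ], group2 = combos[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust),
             row.names = NULL)
}

#' Pairwise Mann-Whitney comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test via [stats::wilcox.test()],
#' which uses the exact distribution for small tie-free samples and the
#' normal approximation otherwise.
#'
#' @param a,b Numeric samples, each with at least 3 values.
#' @param ... Passed to [stats::wilcox.test()].
#' @return List with `statistic` (U), `p_value`, `n` (sample sizes), `method`.
#' @export
compare_pairwise <- function(a, b, ...) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample needs at least 3 values", call. = FALSE)
  }
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", ...)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(length(a), length(b)), method = wt$method)
}
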