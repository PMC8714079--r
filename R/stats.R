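#' Shapiro-Wilk normality p-value
#'
#' Thin, validated wrapper over [stats::shapiro.test()] used by the
#' decision tree to gate parametric tests.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return the Shapiro-Wilk p-value.
#' @export
assess_normality <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 5000L)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  stats::shapiro.test(values)$p.value
}

#' Choose the statistical test for a set of groups
#'
#' Implements the decision tree applied to normalized intensity
#' measurements: every group is screened with a Shapiro-Wilk test. If all
#' groups are consistent with normality (each p >= 0.05), two groups are
#' compared with a two-tailed unpaired Student's t-test when their sample
#' variances differ by less than 3-fold, and with Welch's t-test otherwise;
#' more than two groups go to one-way ANOVA with a Tukey-Kramer post hoc.
#' If any group fails the normality screen, the whole comparison switches
#' to Kruskal-Wallis with Dunn's post hoc and Benjamini-Hochberg adjusted
#' p-values. The significance level is alpha = 0.05 throughout.
#'
#' @param groups named list of numeric vectors (each n >= 3).
#' @param alpha significance level (default 0.05).
#' @return object of class `"test_plan"`: `test` (one of `"student_t"`,
#'   `"welch_t"`, `"anova_tukey_kramer"`, `"kruskal_dunn_bh"`),
#'   `normality_p` per group, `variance_ratio`, `rationale`.
#' @export
choose_test <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  sw <- vapply(groups, assess_normality, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  vratio <- if (min(vars) == 0) Inf else max(vars) / min(vars)
  all_normal <- all(sw >= alpha)
  k <- length(groups)
  if (!all_normal) {
    test <- "kruskal_dunn_bh"
    why <- sprintf("group(s) %s failed the Shapiro-Wilk screen (p < %.2f): non-parametric branch",
                   paste(names(sw)[sw < alpha], collapse = ", "), alpha)
  } else if (k == 2L) {
    if (vratio < 3) {
      test <- "student_t"
      why <- sprintf("both groups normal, variance ratio %.2f < 3: Student's t", vratio)
    } else {
      test <- "welch_t"
      why <- sprintf("both groups normal, variance ratio %.2f >= 3: Welch's t", vratio)
    }
  } else {
    test <- "anova_tukey_kramer"
    why <- sprintf("%d normal groups: one-way ANOVA with Tukey-Kramer post hoc", k)
  }
  structure(list(test = test, normality_p = sw, variance_ratio = vratio,
                 n_groups = k, alpha = alpha, rationale = why),
            class = "test_plan")
}

#' @export
print.test_plan <- function(x, ...) {
  cat(sprintf("<test_plan> %s (alpha = %g)\n  %s\n", x$test, x$alpha, x$rationale))
  invisible(x)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, as.numeric)
  ns <- lengths(groups)
  if (any(ns < 3L))
    stopf("every group needs n >= 3 (got %s)", paste(ns, collapse = ", "))
  groups
}

#' Run the planned group comparison
#'
#' Executes the test chosen by [choose_test()] and reports per-pair
#' statistics with raw and adjusted p-values. Tukey-Kramer p-values come
#' from the studentized-range distribution with the unequal-n correction;
#' Dunn's test uses rank z-statistics with tie correction and
#' Benjamini-Hochberg adjustment across all pairs.
#'
#' @param groups named list of numeric vectors.
#' @param plan a `"test_plan"`; computed with [choose_test()] when omitted.
#' @return object of class `"comparison_result"`: `pairs` data.frame
#'   (`group1`, `group2`, `statistic`, `p_raw`, `p_adj`, `significant`),
#'   `overall` (omnibus statistic and p-value where the test has one),
#'   `plan`, `adjust_method`.
#' @export
run_comparison <- function(groups, plan = NULL) {
  groups <- check_groups(groups)
  if (length(unique(unlist(groups))) == 1L)
    stopf("degenerate data: all values identical in all groups")
  if (is.null(plan)) plan <- choose_test(groups)
  stopifnot(inherits(plan, "test_plan"))
  if (plan$n_groups != length(groups))
    stopf("plan was made for %d groups, got %d", plan$n_groups, length(groups))
  if (plan$test %in% c("student_t", "welch_t") && length(groups) != 2L)
    stopf("two-sample tests need exactly 2 groups")
  alpha <- plan$alpha
  res <- switch(plan$test,
    student_t = two_sample_pair(groups, var_equal = TRUE),
    welch_t = two_sample_pair(groups, var_equal = FALSE),
    anova_tukey_kramer = tukey_kramer(groups),
    kruskal_dunn_bh = dunn_test(groups),
    stopf("unknown test '%s'", plan$test))
  res$pairs$significant <- res$pairs$p_adj < alpha
  structure(list(pairs = res$pairs, overall = res$overall, plan = plan,
                 adjust_method = res$adjust_method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (p adjustment: %s)\n",
              x$plan$test, x$adjust_method))
  if (!is.null(x$overall$p))
    cat(sprintf("  omnibus: statistic %.4g, p = %.4g\n",
                x$overall$statistic, x$overall$p))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

two_sample_pair <- function(groups, var_equal) {
  tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = var_equal)
  list(pairs = data.frame(group1 = names(groups)[1L], group2 = names(groups)[2L],
                          statistic = unname(tt$statistic),
                          p_raw = tt$p.value, p_adj = tt$p.value,
                          stringsAsFactors = FALSE),
       overall = list(statistic = unname(tt$statistic), p = tt$p.value),
       adjust_method = "none")
}

tukey_kramer <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  N <- sum(ns)
  df <- N - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  if (mse == 0) stopf("degenerate data: zero within-group variance")
  # one-way ANOVA omnibus
  grand <- sum(unlist(groups)) / N
  ssb <- sum(ns * (means - grand)^2)
  fstat <- (ssb / (k - 1)) / mse
  p_f <- stats::pf(fstat, k - 1, df, lower.tail = FALSE)
  cmb <- utils::combn(k, 2)
  pairs <- data.frame(group1 = names(groups)[cmb[1L, ]],
                      group2 = names(groups)[cmb[2L, ]],
                      stringsAsFactors = FALSE)
  se <- sqrt(mse * (1 / ns[cmb[1L, ]] + 1 / ns[cmb[2L, ]]))
  tval <- (means[cmb[1L, ]] - means[cmb[2L, ]]) / se
  q <- sqrt(2) * abs(tval)
  pairs$statistic <- unname(q)
  pairs$p_raw <- unname(2 * stats::pt(-abs(tval), df))
  pairs$p_adj <- unname(stats::ptukey(q, k, df, lower.tail = FALSE))
  list(pairs = pairs,
       overall = list(statistic = fstat, p = p_f),
       adjust_method = "tukey")
}

#' Dunn's post hoc test with Benjamini-Hochberg adjustment
#'
#' Rank-based pairwise z-tests following a Kruskal-Wallis comparison, with
#' the usual tie correction of the rank variance; raw two-sided p-values
#' are adjusted across all pairs with [benjamini_hochberg()].
#'
#' @param groups named list of numeric vectors.
#' @return list with `pairs`, `overall` (Kruskal-Wallis), `adjust_method`.
#' @export
dunn_test <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ns <- lengths(groups)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  kw <- stats::kruskal.test(values, g)
  cmb <- utils::combn(k, 2)
  sigma <- sqrt((N * (N + 1) / 12 - tie_term) *
                  (1 / ns[cmb[1L, ]] + 1 / ns[cmb[2L, ]]))
  z <- (rbar[cmb[1L, ]] - rbar[cmb[2L, ]]) / sigma
  p_raw <- 2 * stats::pnorm(-abs(z))
  pairs <- data.frame(group1 = names(groups)[cmb[1L, ]],
                      group2 = names(groups)[cmb[2L, ]],
                      statistic = unname(as.numeric(z)),
                      p_raw = unname(as.numeric(p_raw)),
                      stringsAsFactors = FALSE)
  pairs$p_adj <- benjamini_hochberg(pairs$p_raw)
  list(pairs = pairs,
       overall = list(statistic = unname(kw$statistic), p = kw$p.value),
       adjust_method = "BH")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper over [stats::p.adjust()] with `method = "BH"`:
#' adjusted values are monotone, never smaller than the raw values, and
#' capped at 1.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
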