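#' Mann-Whitney U test
#'
#' Two-sided rank-sum test reporting the U statistic of the first sample
#' (ties counted as 1/2). For combined sample sizes up to `exact_max` the
#' p-value is computed by full enumeration of all group labelings of the
#' pooled values (so ties are handled exactly); beyond that, the normal
#' approximation with tie correction is used (delegated to
#' [stats::wilcox.test()] without continuity correction).
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Largest combined size for which the exact permutation
#'   distribution is enumerated.
#' @return List with `U`, `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U   # 0: full separation
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    sets <- combn(n1 + n2, n1)
    rsum <- colSums(matrix(r[sets], nrow = n1))
    Uall <- rsum - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = p, method = method)
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correct Apply Yates continuity correction (off by default).
#' @return List with `statistic`, `p_value`, `df`, `expected`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    abort("cells must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("all margins must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), expected = ht$expected)
}

#' Mixed-model group effect with the CI-crossing-zero decision rule
#'
#' Fits a linear mixed model `value ~ group + (1 | cluster)` (random
#' intercept per neuron or culture) and reports the group coefficient with
#' confidence intervals at the ladder of levels used for reporting; an
#' effect is significant at a level when that CI excludes zero. Intervals
#' use the Satterthwaite degrees of freedom of the coefficient. When any
#' group has fewer than two clusters the model falls back to an ordinary
#' linear model interval, with a message.
#'
#' @param data Tibble with the value, group and cluster columns.
#' @param value,group,cluster Column names (strings).
#' @param levels Confidence levels of the reporting ladder.
#' @return An `effect_report`: list with `estimate`, `se`, `df`, `ci`
#'   (tibble `level`, `lower`, `upper`, `significant`), `test`,
#'   `n_per_group`, `fallback`.
#' @export
lmm_group_effect <- function(data, value = "value", group = "group",
                             cluster = "cluster",
                             levels = c(0.95, 0.99, 0.995, 0.999, 0.9995,
                                        0.9999)) {
  stopifnot(all(c(value, group, cluster) %in% names(data)))
  d <- data.frame(value = data[[value]],
                  group = factor(data[[group]]),
                  cluster = factor(data[[cluster]]))
  if (nlevels(d$group) != 2) {
    abort("`lmm_group_effect` compares exactly two groups")
  }
  cl_per_group <- tapply(d$cluster, d$group,
                         function(x) length(unique(x)))
  n_per_group <- table(d$group)
  fallback <- any(cl_per_group < 2)
  cf <- NULL
  if (!fallback) {
    cf <- tryCatch(
      coef(summary(suppressMessages(
        lmerTest::lmer(value ~ group + (1 | cluster), data = d)))),
      error = function(e) NULL)
    if (is.null(cf)) {
      fallback <- TRUE
      inform("mixed model degenerate for these data")
    }
  } else {
    inform("fewer than 2 clusters in a group: ordinary linear-model interval")
  }
  if (fallback) {
    fit <- lm(value ~ group, data = d)
    est <- coef(fit)[2]
    se <- sqrt(diag(stats::vcov(fit)))[2]
    df <- fit$df.residual
    test <- "linear model (fallback)"
  } else {
    est <- cf[2, "Estimate"]
    se <- cf[2, "Std. Error"]
    df <- cf[2, "df"]
    test <- "linear mixed model, random intercept per cluster"
  }
  if (!is.finite(df) || df <= 0) df <- max(1, nrow(d) - 2)
  ci <- tibble::tibble(
    level = levels,
    lower = est - qt(1 - (1 - levels) / 2, df) * se,
    upper = est + qt(1 - (1 - levels) / 2, df) * se)
  ci$significant <- ci$lower > 0 | ci$upper < 0
  structure(list(estimate = unname(est), se = unname(se), df = unname(df),
                 ci = ci, test = test,
                 n_per_group = as.integer(n_per_group), fallback = fallback),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf("<effect_report> estimate %.4g (se %.3g, df %.1f), %s\n",
              x$estimate, x$se, x$df, x$test))
  ci95 <- x$ci[x$ci$level == 0.95, ]
  if (nrow(ci95)) {
    cat(sprintf("  95%% CI [%.4g, %.4g] -> %s\n", ci95$lower, ci95$upper,
                if (ci95$significant) "significant" else
                  "not significant (CI crosses zero)"))
  }
  invisible(x)
}

#' Tidy an effect report
#'
#' @param x An `effect_report`.
#' @param ... Unused.
#' @return Tibble with one row per confidence level.
#' @method tidy effect_report
#' @export
tidy.effect_report <- function(x, ...) {
  dplyr::mutate(x$ci, estimate = x$estimate, se = x$se, df = x$df,
                .before = 1)
}

#' One-row summary of an effect report
#'
#' @param x An `effect_report`.
#' @param ... Unused.
#' @return One-row tibble with the estimate and the 95% decision.
#' @method glance effect_report
#' @export
glance.effect_report <- function(x, ...) {
  ci95 <- x$ci[x$ci$level == 0.95, ]
  tibble::tibble(estimate = x$estimate, se = x$se, df = x$df,
                 conf_low_95 = ci95$lower, conf_high_95 = ci95$upper,
                 significant_95 = ci95$significant, test = x$test,
                 fallback = x$fallback)
}
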