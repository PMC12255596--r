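#' Welch two-sample t statistic
#'
#' The unequal-variance t statistic
#' \eqn{t_d = (\bar x_n - \bar y_m) / S_d} with the non-pooled variance
#' \eqn{S_d^2 = S_X^2/n + S_Y^2/m} built from unbiased sample variances, and
#' Welch-Satterthwaite degrees of freedom. When both samples are constant
#' and equal, the statistic is defined as 0 with p = 1.
#'
#' @param x,y numeric samples with at least two values each.
#' @return object of class `welch_result`: `statistic`, `df`, `p.value`
#'   (two-sided), `s2_x`, `s2_y`, `s2_d`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) stop("both samples need at least 2 values")
  welch_from_moments(mean(x), stats::var(x), n, mean(y), stats::var(y), m)
}

# Welch test from sufficient statistics; shared with accuracy_test so that
# self-referencing yields an exactly zero numerator.
welch_from_moments <- function(mx, vx, n, my, vy, m) {
  s2d <- vx / n + vy / m
  num <- mx - my
  if (s2d == 0) {
    t <- if (num == 0) 0 else sign(num) * Inf
    df <- n + m - 2
  } else {
    t <- num / sqrt(s2d)
    df <- s2d^2 / ((vx / n)^2 / (n - 1) + (vy / m)^2 / (m - 1))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  structure(list(statistic = t, df = df, p.value = p,
                 s2_x = vx, s2_y = vy, s2_d = s2d,
                 mean_x = mx, mean_y = my),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.2f, p = %.4g\n", x$statistic, x$df,
              x$p.value))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA F test across two or more groups
#' (delegated to [stats::oneway.test()] with pooled variance).
#'
#' @param groups named list of numeric vectors, each with >= 2 values.
#' @return list with `F`, `p`, `df` (numerator, denominator).
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  res <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter))
}

#' Tukey-Kramer pairwise comparisons
#'
#' Post-hoc studentized-range comparisons of all group pairs, with the
#' Kramer adjustment for unequal group sizes: for groups i, j the statistic
#' is \eqn{q = |\bar x_i - \bar x_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}}
#' referred to the studentized range distribution with k groups and N - k
#' error degrees of freedom.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean difference), `p` (Tukey-adjusted).
#' @export
tukey_kramer <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  N <- sum(ns)
  mse <- sum(vapply(groups, function(v) (length(v) - 1) * stats::var(v),
                    numeric(1))) / (N - k)
  df <- N - k
  pairs <- utils::combn(names(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    diff = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dmean <- means[[a]] - means[[b]]
    se <- sqrt((mse / 2) * (1 / ns[[a]] + 1 / ns[[b]]))
    q <- if (se == 0) {if (dmean == 0) 0 else Inf} else abs(dmean) / se
    out$diff[i] <- dmean
    out$p[i] <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  }
  out
}

#' Age correction by pooled linear regression
#'
#' Removes a common linear age trend from (referenced) ROI values: fits one
#' regression of value on age across all subjects and returns residuals plus
#' the grand mean, so corrected values stay on the ppm scale. Applied after
#' referencing and before group testing.
#'
#' @param values numeric vector of per-subject ROI values (ppm).
#' @param ages numeric vector of ages in years (not constant).
#' @param groups optional factor; if supplied, a separate slope is fitted
#'   per group instead of the pooled model.
#' @return corrected values with the fitted slope (ppm/year) in attribute
#'   `"slope"`.
#' @export
age_correct <- function(values, ages, groups = NULL) {
  if (length(values) != length(ages)) stop("values and ages differ in length")
  if (length(values) < 3L) stop("need at least 3 subjects")
  if (length(unique(ages)) < 2L) stop("age column is constant")
  fit <- if (is.null(groups)) stats::lm(values ~ ages)
         else stats::lm(values ~ ages * groups)
  out <- stats::residuals(fit) + mean(values)
  slope <- unname(stats::coef(fit)["ages"])
  attributes(out) <- NULL
  attr(out, "slope") <- slope
  out
}

#' Percentage variance change due to referencing
#'
#' \eqn{100 [\mathrm{Var}(x - r) - \mathrm{Var}(x)] / \mathrm{Var}(x)} over
#' subjects, with unbiased sample variances: negative values mean the
#' reference co-varies with the ROI and sharpens the group test, positive
#' values mean it injects variance and weakens it.
#'
#' @param roi_means per-subject ROI means (ppm).
#' @param ref_values per-subject reference values (ppm), same length.
#' @return percentage (scalar).
#' @export
variance_change <- function(roi_means, ref_values) {
  if (length(roi_means) != length(ref_values))
    stop("roi_means and ref_values differ in length")
  if (length(roi_means) < 2L) stop("need at least 2 subjects")
  v0 <- stats::var(roi_means)
  if (v0 == 0) stop("Var(roi_means) is zero; relative change undefined")
  100 * (stats::var(roi_means - ref_values) - v0) / v0
}

#' Variance decomposition of referencing
#'
#' Sample-moment version of the identity
#' \eqn{\mathrm{Var}(X - R) = \mathrm{Var}(X) + \mathrm{Var}(R) -
#' 2\,\mathrm{Cov}(X, R)}: all four moments with the same unbiased (n - 1)
#' normalization, so the identity holds to machine precision.
#'
#' @param x,r equal-length numeric vectors (>= 2).
#' @return list with `var_x`, `var_r`, `cov`, `var_diff`.
#' @export
bienayme_decomposition <- function(x, r) {
  if (length(x) != length(r)) stop("x and r differ in length")
  if (length(x) < 2L) stop("need at least 2 observations")
  list(var_x = stats::var(x), var_r = stats::var(r),
       cov = stats::cov(x, r), var_diff = stats::var(x - r))
}
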