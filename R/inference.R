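# Inferential toolkit: paired / independent t-tests with Cohen's d and 95%
# CI, noncentral-t power, assumption checks, and the joint significance rule
# (P < alpha AND |d| > d_min). t-tests are delegated to stats::t.test;
# effect sizes, power and the joint rule are added here.

.new_comparison <- function(estimate, t_stat, df, p, d, ci, power, alpha,
                            d_min, flag = NA_character_) {
  structure(list(estimate = estimate, t_stat = t_stat, df = df,
                 p_two_sided = p, cohen_d = d, ci_low = ci[1], ci_high = ci[2],
                 power = power, alpha = alpha, d_min = d_min,
                 significant = joint_significance(p, d, alpha, d_min),
                 flag = flag),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, digits = 4, ...) {
  cat(sprintf("estimate = %.*f, t = %.3f, df = %.4g, P = %.3g\n",
              digits, x$estimate, x$t_stat, x$df, x$p_two_sided))
  cat(sprintf("Cohen's d = %.3f, 95%% CI [%.3f, %.3f]", x$cohen_d,
              x$ci_low, x$ci_high))
  if (is.finite(x$power)) cat(sprintf(", power = %.3f", x$power))
  cat("\n")
  cat(sprintf("significant (P < %g and |d| > %g): %s\n", x$alpha, x$d_min,
              x$significant))
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Paired-samples t-test with Cohen's d
#'
#' Classical paired t-test on the differences `a - b` (df = n - 1), with the
#' paired Cohen's d = mean(diff) / sd(diff), the 95% CI on the mean
#' difference, achieved power at the observed effect, and the joint
#' significance verdict. A zero-variance difference vector is flagged rather
#' than an error: with a non-zero mean difference the test is degenerate
#' (reported as p = 0), with a zero mean it is the null identity (t = 0,
#' p = 1, d = 0).
#'
#' @param a,b Numeric vectors of equal length (n >= 2).
#' @param alpha Significance level of the joint rule (default 0.05).
#' @param d_min Minimum absolute effect size of the joint rule (default 0.2).
#' @return A `"comparison_result"` with `estimate` (mean difference),
#'   `t_stat`, `df`, `p_two_sided`, `cohen_d`, `ci_low`/`ci_high`, `power`,
#'   `significant`, `flag`.
#' @export
#' @examples
#' paired_t(c(5, 7, 9, 11), c(4, 5, 8, 9))
paired_t <- function(a, b, alpha = 0.05, d_min = 0.2) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  diffs <- a - b
  md <- mean(diffs)
  sdd <- stats::sd(diffs)
  if (sdd == 0) {
    if (md == 0) {
      return(.new_comparison(0, 0, n - 1, 1, 0, c(0, 0), NA_real_, alpha,
                             d_min, "degenerate: zero differences"))
    }
    return(.new_comparison(md, sign(md) * Inf, n - 1, 0, sign(md) * Inf,
                           c(md, md), NA_real_, alpha, d_min,
                           "degenerate: zero variance of differences"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  d <- md / sdd
  power <- .paired_power(d, n, alpha)
  .new_comparison(md, unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, d, as.numeric(tt$conf.int), power, alpha, d_min)
}

.paired_power <- function(d, n, alpha) {
  df <- n - 1
  ncp <- d * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Independent-samples t-test with Cohen's d
#'
#' Welch's t-test by default (pooled-variance Student's t with
#' `welch = FALSE`), with Cohen's d computed from the pooled standard
#' deviation in either case, the 95% CI on the mean difference, achieved
#' power at the observed effect via [power_two_sample()], and the joint
#' significance verdict.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch unequal-variance test (default `TRUE`).
#' @inheritParams paired_t
#' @return A `"comparison_result"` (see [paired_t()]).
#' @export
independent_t <- function(a, b, welch = TRUE, alpha = 0.05, d_min = 0.2) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    md <- mean(a) - mean(b)
    if (md == 0) {
      return(.new_comparison(0, 0, n1 + n2 - 2, 1, 0, c(0, 0), NA_real_,
                             alpha, d_min, "degenerate: zero variance"))
    }
    return(.new_comparison(md, sign(md) * Inf, n1 + n2 - 2, 0,
                           sign(md) * Inf, c(md, md), NA_real_, alpha, d_min,
                           "degenerate: zero variance"))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  power <- power_two_sample(d, n1, n2, alpha)
  .new_comparison(mean(a) - mean(b), unname(tt$statistic),
                  unname(tt$parameter), tt$p.value, d,
                  as.numeric(tt$conf.int), power, alpha, d_min)
}

#' Power of the two-sided two-sample t-test
#'
#' Exact power at effect size `d` (Cohen's d) via the noncentral t
#' distribution with `n1 + n2 - 2` degrees of freedom and noncentrality
#' \eqn{d \sqrt{n_1 n_2 / (n_1 + n_2)}}. At `d = 0` the power equals `alpha`.
#'
#' @param d Standardised effect size.
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' power_two_sample(0.8, 30, 83)
power_two_sample <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("invalid alpha: must lie in (0, 1)", call. = FALSE)
  }
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Normality and homoscedasticity checks
#'
#' Advisory assumption report: Levene's test for homogeneity of variance
#' (centred on the mean) across groups, and a Shapiro-Wilk normality test per
#' group. The report never gates any downstream test.
#'
#' @param groups A named or unnamed list of numeric vectors (each n >= 3).
#' @return A list with `levene` (`statistic`, `df`, `p`) and `normality`
#'   (one row per group: `group`, `n`, `shapiro_w`, `shapiro_p`; `NA` for a
#'   constant group).
#' @export
check_assumptions <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 3L)) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)))
  lev <- car::leveneTest(y, g, center = mean)
  norm <- do.call(rbind, lapply(names(groups), function(k) {
    x <- groups[[k]]
    sw <- tryCatch(stats::shapiro.test(x), error = function(e) NULL)
    data.frame(group = k, n = length(x),
               shapiro_w = if (is.null(sw)) NA_real_ else unname(sw$statistic),
               shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
               stringsAsFactors = FALSE)
  }))
  list(levene = list(statistic = lev[1, "F value"],
                     df = c(lev[1, "Df"], lev[2, "Df"]),
                     p = lev[1, "Pr(>F)"]),
       normality = norm)
}

#' Joint significance rule
#'
#' Effect-size-gated significance: a comparison is called significant only
#' when the p-value is below `alpha` and the absolute Cohen's d exceeds
#' `d_min`, guarding against trivially small but "significant" effects.
#'
#' @param p Two-sided p-value in \[0, 1\].
#' @param d Cohen's d.
#' @param alpha Significance level (default 0.05).
#' @param d_min Minimum absolute effect size (default 0.2).
#' @return Logical.
#' @export
#' @examples
#' joint_significance(0.01, 1.8)   # TRUE
#' joint_significance(0.01, 0.1)   # FALSE
joint_significance <- function(p, d, alpha = 0.05, d_min = 0.2) {
  stopifnot(all(p >= 0 & p <= 1))
  (p < alpha) & (abs(d) > d_min)
}
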