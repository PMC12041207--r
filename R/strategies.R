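# The three control-strategy diagnostics. Each returns a strategy_verdict
# whose `supported` flag follows deterministically from the evidence at the
# configured alpha. Directional slope criteria (b > 1, lambda < 1) use the
# one-sided reading of the slope-vs-1 test; the two-sided p is reported too.

.new_verdict <- function(strategy, nutrient_context, supported, evidence,
                         criterion, alpha, excluded = 0L) {
  structure(list(strategy = strategy, nutrient_context = nutrient_context,
                 supported = supported, evidence = evidence,
                 criterion = criterion, alpha = alpha, excluded = excluded),
            class = "strategy_verdict")
}

#' @export
print.strategy_verdict <- function(x, ...) {
  cat("Strategy:", x$strategy, "(", x$nutrient_context, ")\n")
  cat("  criterion:", x$criterion, "\n")
  cat("  supported:", x$supported, "at alpha =", x$alpha, "\n")
  if (x$excluded > 0L) cat("  excluded sites:", x$excluded, "\n")
  invisible(x)
}

#' Concentration-control diagnostic
#'
#' Tests whether resorption is more efficient in leaves with low mature
#' nutrient concentration. Under the power law
#' \eqn{Nu_{sen} = a Nu_{mat}^{b}}, efficiency is
#' \eqn{NuRE = (1 - a Nu_{mat}^{b-1}) \times 100}, so an exponent \eqn{b > 1}
#' means efficiency falls as the mature concentration rises. The strategy is
#' supported when the log10-log10 regression of senesced on mature
#' concentration is itself significant at `alpha` and its slope is
#' significantly greater than 1 (one-sided).
#'
#' @param pairs A `"leaf_pairs"` object from [pair_site_periods()].
#' @param nutrient `"N"` or `"P"`.
#' @param alpha Significance level (default 0.05, unadjusted).
#' @param mode Regression mode passed to [fit_loglog()]; `"mixed"` uses the
#'   replicate-level pairs with a site random intercept.
#' @return A `"strategy_verdict"`; `$evidence$fit` holds the
#'   [fit_loglog()] fit updated by [test_slope_against()] (null slope 1).
#' @export
concentration_control_test <- function(pairs, nutrient = c("N", "P"),
                                       alpha = 0.05,
                                       mode = c("site_means", "mixed")) {
  stopifnot(inherits(pairs, "leaf_pairs"))
  nutrient <- match.arg(nutrient)
  mode <- match.arg(mode)
  if (nrow(pairs$sites) < 3L) {
    stop("insufficiency error: need at least 3 sites", call. = FALSE)
  }
  mat_col <- if (nutrient == "N") "mat_n" else "mat_p"
  sen_col <- if (nutrient == "N") "sen_n" else "sen_p"
  if (mode == "mixed") {
    d <- pairs$replicates
    fit <- fit_loglog(d[[mat_col]], d[[sen_col]], mode = "mixed",
                      site = d$site_id,
                      xlab = paste0("mature ", nutrient),
                      ylab = paste0("senesced ", nutrient))
  } else {
    d <- pairs$sites
    fit <- fit_loglog(d[[mat_col]], d[[sen_col]], mode = "site_means",
                      xlab = paste0("mature ", nutrient),
                      ylab = paste0("senesced ", nutrient))
  }
  fit <- tryCatch(test_slope_against(fit, 1), error = function(e) {
    fit$null_slope <- 1
    fit$t_vs_null <- if (fit$slope == 1) 0 else sign(fit$slope - 1) * Inf
    fit$p_slope_vs_null <- if (fit$slope == 1) 1 else 0
    fit
  })
  p_gt1 <- .one_sided_slope_p(fit, 1, "greater")
  regression_sig <- fit$p_slope_zero < alpha
  supported <- regression_sig && (p_gt1 < alpha)
  .new_verdict(
    "concentration_control", nutrient, supported,
    list(fit = fit, p_slope_greater_1 = p_gt1),
    sprintf("log10(sen) ~ log10(mat) significant at %g AND slope > 1 (one-sided P = %.3g)",
            alpha, p_gt1),
    alpha
  )
}

#' Stoichiometry-control diagnostic
#'
#' Tests whether N and P are resorbed in proportion to their mature-leaf
#' stoichiometry: supported when (i) leaf N and P resorption efficiencies are
#' positively and significantly correlated across sites and (ii) the resorbed
#' N:P ratio increases significantly with the mature-leaf N:P concentration
#' ratio (positive regression slope).
#'
#' @param sites A `"site_resorption"` table from [site_resorption()].
#' @param alpha Significance level (default 0.05, unadjusted).
#' @return A `"strategy_verdict"`; `$evidence` carries the Pearson
#'   correlation test (`cor_nre_pre`) and the ratio regression (`ratio_fit`).
#'   Sites with undefined resorbed N:P (non-positive resorbed P) are excluded
#'   with a logged count; fewer than 3 remaining is an error.
#' @export
stoichiometry_control_test <- function(sites, alpha = 0.05) {
  stopifnot(is.data.frame(sites))
  ok <- is.finite(sites$resorbed_np) & is.finite(sites$mature_np)
  excluded <- sum(!ok)
  if (excluded > 0L) {
    message("stoichiometry_control_test: excluded ", excluded,
            " site(s) with undefined resorbed N:P")
  }
  d <- sites[ok, ]
  if (nrow(d) < 3L) {
    stop("insufficiency error: fewer than 3 sites with defined ratios",
         call. = FALSE)
  }
  ct <- stats::cor.test(d$nre, d$pre, method = "pearson")
  rfit <- .fit_linear(d$mature_np, d$resorbed_np, mode = "site_means",
                      xlab = "mature N:P", ylab = "resorbed N:P")
  class(rfit) <- "tradeoff_fit"
  cor_ok <- ct$estimate > 0 && ct$p.value < alpha
  slope_ok <- rfit$slope > 0 && rfit$p_slope_zero < alpha
  .new_verdict(
    "stoichiometry_control", "N vs P", cor_ok && slope_ok,
    list(cor_nre_pre = ct, ratio_fit = rfit),
    sprintf("cor(NRE, PRE) > 0 significant at %g AND slope of resorbed N:P on mature N:P > 0 significant",
            alpha),
    alpha, excluded
  )
}

#' Limitation-control diagnostic
#'
#' Tests whether the more limiting nutrient is preferentially resorbed. Under
#' the power law \eqn{resorbed\ N{:}P = \varepsilon (leaf\ N{:}P)^{\lambda}},
#' the efficiency ratio obeys
#' \eqn{NRE{:}PRE = \varepsilon (leaf\ N{:}P)^{\lambda - 1}}: an exponent
#' \eqn{\lambda < 1} means relative N resorption falls — and relative P
#' resorption rises — as the mature leaf N:P ratio (an indicator of
#' aggravated P limitation) increases. Supported when the fitted
#' \eqn{\lambda} is significantly below 1 (one-sided).
#'
#' @inheritParams stoichiometry_control_test
#' @return A `"strategy_verdict"`; `$evidence$fit` holds the log10-log10
#'   ratio regression with the slope-vs-1 test applied, and
#'   `$evidence$lambda` the fitted exponent.
#' @export
limitation_control_test <- function(sites, alpha = 0.05) {
  stopifnot(is.data.frame(sites))
  ok <- is.finite(sites$resorbed_np) & is.finite(sites$mature_np) &
    sites$resorbed_np > 0 & sites$mature_np > 0
  excluded <- sum(!ok)
  if (excluded > 0L) {
    message("limitation_control_test: excluded ", excluded,
            " site(s) with undefined or non-positive ratios")
  }
  d <- sites[ok, ]
  if (nrow(d) < 3L) {
    stop("insufficiency error: fewer than 3 sites with defined ratios",
         call. = FALSE)
  }
  fit <- fit_loglog(d$mature_np, d$resorbed_np, mode = "site_means",
                    xlab = "mature N:P", ylab = "resorbed N:P")
  fit <- tryCatch(test_slope_against(fit, 1), error = function(e) {
    fit$null_slope <- 1
    fit$t_vs_null <- if (fit$slope == 1) 0 else sign(fit$slope - 1) * Inf
    fit$p_slope_vs_null <- if (fit$slope == 1) 1 else 0
    fit
  })
  p_lt1 <- .one_sided_slope_p(fit, 1, "less")
  .new_verdict(
    "limitation_control", "N relative to P", p_lt1 < alpha,
    list(fit = fit, lambda = fit$slope, p_slope_less_1 = p_lt1),
    sprintf("slope lambda of log10(resorbed N:P) on log10(mature N:P) < 1 (one-sided P = %.3g)",
            p_lt1),
    alpha, excluded
  )
}
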