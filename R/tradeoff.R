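# Resorption-versus-soil-supply trade-off fits: Gaussian identity-link
# linear fits of per-site efficiency (or efficiency ratio) on per-site
# mineralization rate (or rate ratio). A "negative trade-off" is a negative
# slope significant at alpha.

#' Fit a resorption-supply trade-off
#'
#' Linear (Gaussian, identity link) regression of a per-site resorption
#' response on a per-site soil-supply predictor, e.g. leaf N resorption
#' efficiency on the soil net N mineralization rate. In `"mixed"` mode the
#' fit is over replicate-level values with a site random intercept.
#'
#' @param response Numeric response vector (e.g. NRE, percent).
#' @param predictor Numeric predictor vector (e.g. N mineralization rate,
#'   ng cm\eqn{^{-2}} d\eqn{^{-1}}); must not be constant.
#' @param mode `"site_means"` (default) or `"mixed"`.
#' @param site Grouping vector for `"mixed"` mode.
#' @param alpha Significance level for the trade-off call (default 0.05).
#' @param response_name,predictor_name Labels carried into printouts.
#' @return An object of class `"tradeoff_fit"`: the regression fields
#'   (`slope`, `intercept`, `slope_se`, `r2`, `n`, `df`, `p_slope_zero`) plus
#'   `negative_tradeoff` (slope < 0 and significant at `alpha`).
#' @export
#' @examples
#' nmin <- seq(120, 480, length.out = 30)
#' nre <- 70 - 0.05 * nmin + rnorm(30, 0, 2)
#' fit_tradeoff(nre, nmin)
fit_tradeoff <- function(response, predictor,
                         mode = c("site_means", "mixed"), site = NULL,
                         alpha = 0.05,
                         response_name = deparse1(substitute(response)),
                         predictor_name = deparse1(substitute(predictor))) {
  ok <- is.finite(response) & is.finite(predictor)
  if (!all(ok)) {
    stop("domain error: non-finite value at index ", which(!ok)[1L],
         call. = FALSE)
  }
  out <- .fit_linear(predictor, response, mode = mode, site = site,
                     xlab = predictor_name, ylab = response_name)
  out$alpha <- alpha
  out$negative_tradeoff <- (out$slope < 0) && (out$p_slope_zero < alpha)
  out$scale <- "identity"
  class(out) <- "tradeoff_fit"
  out
}

#' Ratio-on-ratio trade-off
#'
#' [fit_tradeoff()] applied to the per-site NRE:PRE efficiency ratio against
#' the per-site N:P mineralization rate ratio. Pairs with an undefined ratio
#' (`NA`/non-finite, from a non-positive denominator upstream) are excluded
#' with a logged count; fewer than 3 remaining pairs is an error.
#'
#' @param nre_pre_ratio Per-site NRE/PRE values.
#' @param min_ratio Per-site N:P mineralization rate ratios.
#' @inheritParams fit_tradeoff
#' @return A `"tradeoff_fit"` with an `excluded` count attached.
#' @export
ratio_tradeoff <- function(nre_pre_ratio, min_ratio, alpha = 0.05) {
  stopifnot(length(nre_pre_ratio) == length(min_ratio))
  ok <- is.finite(nre_pre_ratio) & is.finite(min_ratio)
  excluded <- sum(!ok)
  if (excluded > 0L) {
    message("ratio_tradeoff: excluded ", excluded,
            " site(s) with undefined ratio(s)")
  }
  if (sum(ok) < 3L) {
    stop("insufficiency error: fewer than 3 sites with defined ratios",
         call. = FALSE)
  }
  out <- fit_tradeoff(nre_pre_ratio[ok], min_ratio[ok], alpha = alpha,
                      response_name = "NRE:PRE",
                      predictor_name = "Nmin:Pmin")
  out$excluded <- excluded
  out
}

#' @export
print.tradeoff_fit <- function(x, digits = 4, ...) {
  cat("Trade-off fit: ", x$ylab, " ~ ", x$xlab, "  [", x$mode, "]\n", sep = "")
  cat(sprintf("  slope = %.*g (SE %.*g), intercept = %.*g\n", digits, x$slope,
              digits, x$slope_se, digits, x$intercept))
  cat(sprintf("  R2 = %.*f, n = %d, df = %d, P = %.3g\n", digits, x$r2, x$n,
              x$df, x$p_slope_zero))
  if (!is.null(x$negative_tradeoff)) {
    cat("  negative trade-off:", x$negative_tradeoff, "\n")
  }
  invisible(x)
}

#' @export
coef.tradeoff_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.tradeoff_fit <- function(object, ...) object

#' @export
#' @method predict tradeoff_fit
predict.tradeoff_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$x
  object$intercept + object$slope * newdata
}

#' @export
#' @method residuals tradeoff_fit
residuals.tradeoff_fit <- function(object, ...) {
  object$y - (object$intercept + object$slope * object$x)
}

#' @export
#' @method plot tradeoff_fit
plot.tradeoff_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xlab, ylab = x$ylab, ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}
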