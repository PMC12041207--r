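# Power-law (log10-log10) regression core used by all three control-strategy
# diagnostics, plus the slope test against an arbitrary null. Two estimation
# modes: OLS on site means (default, n = number of sites) and a site-grouped
# mixed model over replicates (random intercept per site, via lme4).

# Shared linear fit on already-transformed values. `site` is a grouping
# vector (only used in mixed mode). Returns the RegressionFit field set.
.fit_linear <- function(x, y, mode = c("site_means", "mixed"), site = NULL,
                        xlab = "x", ylab = "y") {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("domain error: non-finite value at index ",
         which(!is.finite(x) | !is.finite(y))[1L], call. = FALSE)
  }
  if (mode == "site_means" && !is.null(site)) {
    x <- as.numeric(tapply(x, site, mean))
    y <- as.numeric(tapply(y, site, mean))
    site <- NULL
  }
  n <- length(x)
  if (n < 3L) stop("insufficiency error: need at least 3 observations", call. = FALSE)
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0) {
    stop("degeneracy error: predictor '", xlab, "' is constant", call. = FALSE)
  }
  used_mixed <- FALSE
  if (mode == "mixed") {
    if (is.null(site)) stop("mixed mode requires a 'site' grouping vector", call. = FALSE)
    n_sites <- length(unique(site))
    if (n_sites < 3L) stop("insufficiency error: need at least 3 sites", call. = FALSE)
    if (n_sites < n) {
      fit <- lme4::lmer(y ~ x + (1 | site),
                        data = data.frame(x = x, y = y, site = site),
                        REML = TRUE)
      fe <- summary(fit)$coefficients
      slope <- fe["x", "Estimate"]
      intercept <- fe["(Intercept)", "Estimate"]
      slope_se <- fe["x", "Std. Error"]
      df <- n_sites - 2L  # site-level information bound; see methods vignette
      r2 <- stats::cor(stats::fitted(fit), y)^2
      sigma <- stats::sigma(fit)
      used_mixed <- TRUE
    }
    # exactly one observation per site: identical to OLS by construction
  }
  if (!used_mixed) {
    fit <- stats::lm(y ~ x)
    # noiseless constructions hit summary.lm's perfect-fit warning; the
    # zero residual variance is legitimate here
    sm <- withCallingHandlers(summary(fit), warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
    cf <- sm$coefficients
    slope <- cf["x", "Estimate"]
    intercept <- cf["(Intercept)", "Estimate"]
    slope_se <- cf["x", "Std. Error"]
    df <- fit$df.residual
    r2 <- sm$r.squared
    sigma <- sm$sigma
  }
  tval <- slope / slope_se
  p0 <- if (slope_se > 0) 2 * stats::pt(-abs(tval), df) else as.numeric(slope != 0) * 0
  list(slope = slope, intercept = intercept, slope_se = slope_se,
       r2 = r2, sigma = sigma, n = n, df = df, p_slope_zero = p0,
       p_slope_vs_null = NA_real_, null_slope = NA_real_,
       mode = if (used_mixed) "mixed" else "site_means",
       xlab = xlab, ylab = ylab, x = x, y = y, site = site)
}

#' Fit a power law by log10-log10 regression
#'
#' Fits \eqn{y = a x^b} as the linear regression
#' \eqn{\log_{10} y = \log_{10} a + b \log_{10} x}. In `"site_means"` mode the
#' fit is ordinary least squares on per-site values (when `site` is supplied,
#' replicates are first averaged per site); in `"mixed"` mode the same fixed
#' effect is estimated over replicate-level data with a random intercept per
#' site. The two modes coincide exactly when each site contributes a single
#' observation.
#'
#' @param x,y Strictly positive numeric vectors of equal length (e.g. mature
#'   and senesced leaf concentrations, g kg\eqn{^{-1}}).
#' @param mode `"site_means"` (default) or `"mixed"`.
#' @param site Optional grouping vector (required for `"mixed"`).
#' @param xlab,ylab Variable labels carried into printouts.
#' @return An object of class `"powerlaw_fit"` with components `slope` (the
#'   exponent \eqn{b}), `intercept` (\eqn{\log_{10} a}), `slope_se`, `r2`,
#'   `sigma` (residual SD on the log10 scale), `n`, `df`, `p_slope_zero`,
#'   and — after [test_slope_against()] — `p_slope_vs_null` and `null_slope`.
#' @seealso [test_slope_against()], [concentration_control_test()]
#' @export
#' @examples
#' x <- c(5, 8, 11, 14, 17, 20)
#' fit <- fit_loglog(x, 2 * x^1.5)
#' coef(fit)                 # recovers b = 1.5, log10(a) = log10(2)
#' predict(fit, newdata = 10)
fit_loglog <- function(x, y, mode = c("site_means", "mixed"), site = NULL,
                       xlab = deparse1(substitute(x)),
                       ylab = deparse1(substitute(y))) {
  if (any(!is.finite(x) | x <= 0)) {
    stop("domain error: non-positive x at index ",
         which(!is.finite(x) | x <= 0)[1L], call. = FALSE)
  }
  if (any(!is.finite(y) | y <= 0)) {
    stop("domain error: non-positive y at index ",
         which(!is.finite(y) | y <= 0)[1L], call. = FALSE)
  }
  out <- .fit_linear(log10(x), log10(y), mode = mode, site = site,
                     xlab = xlab, ylab = ylab)
  out$scale <- "log10"
  class(out) <- "powerlaw_fit"
  out
}

#' Test a fitted slope against an arbitrary null value
#'
#' Computes \eqn{t = (\hat b - b_0) / SE(\hat b)} and the two-sided p-value
#' from the t distribution with the fit's residual degrees of freedom. Used
#' to compare power-law exponents with 1 (the 1:1 line) in the concentration
#' and limitation control diagnostics. Directional (one-sided) readings are
#' taken by halving this p-value on the appropriate side.
#'
#' @param fit A `"powerlaw_fit"` or `"tradeoff_fit"` object with positive
#'   `slope_se`.
#' @param null_slope The null value \eqn{b_0}.
#' @return The fit, updated with `null_slope`, `t_vs_null` and
#'   `p_slope_vs_null`.
#' @export
#' @examples
#' x <- exp(seq(1, 3, length.out = 30))
#' f <- fit_loglog(x, x^1.2 * 10^rnorm(30, 0, 0.05))
#' test_slope_against(f, 1)$p_slope_vs_null
test_slope_against <- function(fit, null_slope) {
  stopifnot(is.list(fit), is.numeric(null_slope), length(null_slope) == 1L)
  if (!is.finite(fit$slope_se) || fit$slope_se <= 0) {
    stop("degenerate-fit error: slope standard error is zero", call. = FALSE)
  }
  tval <- (fit$slope - null_slope) / fit$slope_se
  fit$null_slope <- null_slope
  fit$t_vs_null <- tval
  fit$p_slope_vs_null <- 2 * stats::pt(-abs(tval), fit$df)
  fit
}

# One-sided p for a directional alternative on the slope; returns the limit
# values 0/1 for an exactly-degenerate (zero-residual) fit.
.one_sided_slope_p <- function(fit, null_slope, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!is.finite(fit$slope_se) || fit$slope_se <= 0) {
    on_side <- if (direction == "greater") fit$slope > null_slope
               else fit$slope < null_slope
    return(if (on_side) 0 else 1)
  }
  tval <- (fit$slope - null_slope) / fit$slope_se
  stats::pt(tval, fit$df, lower.tail = (direction == "less"))
}

#' @export
print.powerlaw_fit <- function(x, digits = 4, ...) {
  cat("Power-law fit: log10(", x$ylab, ") ~ log10(", x$xlab, ")  [",
      x$mode, "]\n", sep = "")
  cat(sprintf("  slope (b)   = %.*f  (SE %.*f)\n", digits, x$slope, digits,
              x$slope_se))
  cat(sprintf("  intercept   = %.*f  (a = %.*f)\n", digits, x$intercept,
              digits, 10^x$intercept))
  cat(sprintf("  R2 = %.*f, n = %d, df = %d, P(slope = 0) = %.3g\n",
              digits, x$r2, x$n, x$df, x$p_slope_zero))
  if (!is.na(x$null_slope)) {
    cat(sprintf("  vs null slope %g: t = %.3f, two-sided P = %.3g\n",
                x$null_slope, x$t_vs_null, x$p_slope_vs_null))
  }
  invisible(x)
}

#' @export
summary.powerlaw_fit <- function(object, ...) {
  object
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
#' @method predict powerlaw_fit
predict.powerlaw_fit <- function(object, newdata = NULL, ...) {
  # prediction on the original (concentration) scale: a * x^b
  if (is.null(newdata)) newdata <- 10^object$x
  stopifnot(is.numeric(newdata), all(newdata > 0))
  10^(object$intercept + object$slope * log10(newdata))
}

#' @export
#' @method residuals powerlaw_fit
residuals.powerlaw_fit <- function(object, ...) {
  object$y - (object$intercept + object$slope * object$x)
}

#' @export
#' @method simulate powerlaw_fit
simulate.powerlaw_fit <- function(object, nsim = 1, seed = NULL,
                                  newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- 10^object$x
  out <- replicate(nsim, {
    10^(object$intercept + object$slope * log10(newdata) +
          stats::rnorm(length(newdata), 0, object$sigma))
  }, simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
#' @method plot powerlaw_fit
plot.powerlaw_fit <- function(x, ...) {
  graphics::plot(x$x, x$y,
                 xlab = paste0("log10(", x$xlab, ")"),
                 ylab = paste0("log10(", x$ylab, ")"), ...)
  graphics::abline(x$intercept, x$slope)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
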