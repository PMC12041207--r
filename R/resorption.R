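# Resorption efficiency, absolute resorption, proficiency class and the
# mass <-> concentration basis conversion. Percent (0-100) is the canonical
# scale throughout; mass-based efficiencies are fractions in [0, 1).

#' Leaf nutrient resorption efficiency
#'
#' Percentage of a nutrient withdrawn from leaves before abscission,
#' \deqn{NuRE = (Nu_{mat} - Nu_{sen}) / Nu_{mat} \times 100,}
#' where \eqn{Nu_{mat}} and \eqn{Nu_{sen}} are the mature and senesced leaf
#' nutrient concentrations (g kg\eqn{^{-1}}). Negative values (senesced above
#' mature, possible under measurement noise) are permitted with a warning and
#' never clamped, so that diagnostics retain the information.
#'
#' @param nu_mat Mature leaf concentration, g kg\eqn{^{-1}}; must be positive.
#' @param nu_sen Senesced leaf concentration, g kg\eqn{^{-1}}; non-negative.
#' @return Resorption efficiency in percent (vectorised). Always `< 100`.
#' @export
#' @examples
#' resorption_efficiency(10, 5)   # 50
#' resorption_efficiency(8.2, 3.1)
resorption_efficiency <- function(nu_mat, nu_sen) {
  if (any(!is.finite(nu_mat)) || any(nu_mat <= 0)) {
    stop("domain error: nu_mat must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(nu_sen)) || any(nu_sen < 0)) {
    stop("domain error: nu_sen must be non-negative and finite", call. = FALSE)
  }
  out <- (nu_mat - nu_sen) / nu_mat * 100
  if (any(out < 0)) {
    warning("negative resorption efficiency: senesced concentration exceeds ",
            "mature for ", sum(out < 0), " value(s)", call. = FALSE)
  }
  out
}

#' Absolute nutrient resorption
#'
#' The difference between mature and senesced leaf nutrient concentrations,
#' in g kg\eqn{^{-1}} — the quantity whose N:P ratio enters the limitation
#' control diagnostic.
#'
#' @inheritParams resorption_efficiency
#' @return `nu_mat - nu_sen` (vectorised), g kg\eqn{^{-1}}.
#' @export
absolute_resorption <- function(nu_mat, nu_sen) {
  if (any(!is.finite(nu_mat)) || any(nu_mat <= 0)) {
    stop("domain error: nu_mat must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(nu_sen)) || any(nu_sen < 0)) {
    stop("domain error: nu_sen must be non-negative and finite", call. = FALSE)
  }
  nu_mat - nu_sen
}

#' Resorption proficiency class
#'
#' Classifies a senesced-leaf nutrient concentration against the complete
#' resorption boundary of Killingbeck: resorption is "complete" when the
#' senesced concentration lies strictly below the boundary. The default
#' boundary for P is 0.4 g kg\eqn{^{-1}}; no accepted default exists for N,
#' so it must be supplied.
#'
#' @param nutrient `"N"` or `"P"`.
#' @param sen_conc Senesced leaf concentration, g kg\eqn{^{-1}}.
#' @param boundary Complete-resorption boundary, g kg\eqn{^{-1}}. Defaults to
#'   0.4 for P; required for N.
#' @return A `data.frame` of class `"proficiency_verdict"` with columns
#'   `nutrient`, `sen_conc`, `boundary` and logical `complete`.
#' @export
#' @examples
#' proficiency_class("P", c(0.3, 0.4, 0.9))
proficiency_class <- function(nutrient, sen_conc, boundary = NULL) {
  nutrient <- match.arg(nutrient, c("N", "P"))
  if (is.null(boundary)) {
    if (nutrient == "P") boundary <- 0.4
    else stop("configuration error: no default complete-resorption boundary ",
              "for N; supply 'boundary'", call. = FALSE)
  }
  stopifnot(is.numeric(boundary), length(boundary) == 1L, boundary > 0)
  if (any(!is.finite(sen_conc)) || any(sen_conc < 0)) {
    stop("domain error: sen_conc must be non-negative and finite", call. = FALSE)
  }
  out <- data.frame(nutrient = nutrient, sen_conc = sen_conc,
                    boundary = boundary, complete = sen_conc < boundary)
  class(out) <- c("proficiency_verdict", "data.frame")
  out
}

#' Growth-form mass loss correction factors
#'
#' The five MLCF constants used to harmonise mass-based resorption
#' efficiencies from the literature onto a concentration basis: leaves lose
#' mass during senescence, so an uncorrected mass-based efficiency
#' underestimates the concentration-based one.
#'
#' @param overrides Optional named numeric vector replacing individual
#'   factors (names must be growth forms; values in (0, 1]).
#' @return Named numeric vector over the five growth forms
#'   (`evergreen_broadleaf`, `deciduous_broadleaf`, `conifer`, `forb`,
#'   `graminoid`).
#' @export
#' @examples
#' mlcf_table()
#' mlcf_table(c(forb = 0.7))
mlcf_table <- function(overrides = NULL) {
  tab <- c(evergreen_broadleaf = 0.780, deciduous_broadleaf = 0.784,
           conifer = 0.745, forb = 0.640, graminoid = 0.713)
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    unknown <- setdiff(names(overrides), names(tab))
    if (length(unknown) > 0L) {
      stop("unknown growth form(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(overrides <= 0 | overrides > 1)) {
      stop("MLCF values must lie in (0, 1]", call. = FALSE)
    }
    tab[names(overrides)] <- overrides
  }
  tab
}

#' Convert mass-based to concentration-based resorption efficiency
#'
#' Applies the growth-form mass loss correction
#' \deqn{NuRE = (1 - (1 - NuRE_m) \times MLCF) \times 100,}
#' with \eqn{NuRE_m} the mass-based efficiency as a fraction.
#'
#' @param nure_m Mass-based efficiency, fraction in \[0, 1) (vectorised).
#' @param growth_form Growth form(s), recycled against `nure_m`.
#' @param table MLCF lookup, as from [mlcf_table()].
#' @return Concentration-based efficiency in percent.
#' @seealso [concentration_to_mass_basis()] for the algebraic inverse.
#' @export
#' @examples
#' mass_to_concentration_basis(0.5, "forb")   # 68
mass_to_concentration_basis <- function(nure_m, growth_form, table = mlcf_table()) {
  stopifnot(is.numeric(nure_m))
  if (any(!is.finite(nure_m)) || any(nure_m < 0 | nure_m >= 1)) {
    stop("domain error: nure_m must lie in [0, 1)", call. = FALSE)
  }
  unknown <- setdiff(unique(growth_form), names(table))
  if (length(unknown) > 0L) {
    stop("lookup error: growth form(s) not in MLCF table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mlcf <- unname(table[growth_form])
  (1 - (1 - nure_m) * mlcf) * 100
}

#' Invert the mass loss correction
#'
#' Recovers the mass-based efficiency fraction from a concentration-based
#' percentage: `1 - (1 - nure/100) / mlcf`.
#'
#' @param nure Concentration-based efficiency, percent.
#' @inheritParams mass_to_concentration_basis
#' @return Mass-based efficiency fraction.
#' @export
concentration_to_mass_basis <- function(nure, growth_form, table = mlcf_table()) {
  unknown <- setdiff(unique(growth_form), names(table))
  if (length(unknown) > 0L) {
    stop("lookup error: growth form(s) not in MLCF table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mlcf <- unname(table[growth_form])
  1 - (1 - nure / 100) / mlcf
}

#' Per-site resorption summary
#'
#' Builds the per-site resorption table from paired leaf chemistry: N and P
#' resorption efficiencies (percent), absolute resorbed N and P
#' (g kg\eqn{^{-1}}), the resorbed N:P ratio, the mature-leaf N:P
#' concentration ratio, and the senesced P concentration (the proficiency
#' variable). `resorbed_np` is `NA` (flagged, with a message) where resorbed
#' P is not positive.
#'
#' @param pairs A `"leaf_pairs"` object from [pair_site_periods()].
#' @return A `data.frame` of class `"site_resorption"`, one row per site:
#'   `site_id`, `nre`, `pre`, `resorbed_n`, `resorbed_p`, `resorbed_np`,
#'   `mature_np`, `sen_p`.
#' @export
site_resorption <- function(pairs) {
  stopifnot(inherits(pairs, "leaf_pairs"))
  s <- pairs$sites
  out <- data.frame(
    site_id = s$site_id,
    nre = resorption_efficiency(s$mat_n, s$sen_n),
    pre = resorption_efficiency(s$mat_p, s$sen_p),
    resorbed_n = absolute_resorption(s$mat_n, s$sen_n),
    resorbed_p = absolute_resorption(s$mat_p, s$sen_p),
    mature_np = s$mat_n / s$mat_p,
    sen_p = s$sen_p,
    stringsAsFactors = FALSE
  )
  out$resorbed_np <- ifelse(out$resorbed_p > 0,
                            out$resorbed_n / out$resorbed_p, NA_real_)
  n_undef <- sum(is.na(out$resorbed_np))
  if (n_undef > 0L) {
    message(n_undef, " site(s) with non-positive resorbed P: resorbed N:P ",
            "flagged undefined")
  }
  out <- out[, c("site_id", "nre", "pre", "resorbed_n", "resorbed_p",
                 "resorbed_np", "mature_np", "sen_p")]
  class(out) <- c("site_resorption", "data.frame")
  out
}
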