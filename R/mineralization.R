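# Net soil N and P mineralization from resin-core incubation budgets. The
# rate is the change in inorganic nutrient (soil + resin capture) per tube
# bottom area per day; negative rates mean net immobilization and are kept.

#' Net mineralization rate from an incubation budget
#'
#' For each tube, the net rate is
#' \deqn{(post_{soil} + resin - pre_{soil}) / (\pi (d/2)^2 \cdot days)}
#' in ng cm\eqn{^{-2}} d\eqn{^{-1}}, where `d` is the tube diameter (cm).
#' Inorganic N is the sum of NH4+-N and NO3--N and multiple monthly resin
#' bags are summed into `resin_ng` upstream (by the table reader).
#'
#' @param records An incubation `data.frame` as from
#'   [read_incubation_table()] (columns `site_id`, `replicate_id`,
#'   `nutrient`, `pre_soil_ng`, `post_soil_ng`, `resin_ng`,
#'   `tube_diameter_cm`, `days`).
#' @return A `data.frame` with `site_id`, `replicate_id`, `nutrient` and
#'   `rate` (ng cm\eqn{^{-2}} d\eqn{^{-1}}; may be negative).
#' @export
#' @examples
#' rec <- data.frame(site_id = "S1", replicate_id = "T1", nutrient = "N",
#'                   pre_soil_ng = 100, post_soil_ng = 150, resin_ng = 50,
#'                   tube_diameter_cm = 5, days = 90)
#' net_mineralization_rate(rec)$rate   # 100 / (pi * 2.5^2 * 90)
net_mineralization_rate <- function(records) {
  stopifnot(is.data.frame(records))
  .require_columns(records, INCUBATION_COLUMNS, "<in-memory incubation table>")
  if (any(!is.finite(records$tube_diameter_cm) | records$tube_diameter_cm <= 0)) {
    stop("domain error: tube_diameter_cm must be positive", call. = FALSE)
  }
  if (any(!is.finite(records$days) | records$days <= 0)) {
    stop("domain error: days must be positive", call. = FALSE)
  }
  area <- pi * (records$tube_diameter_cm / 2)^2
  rate <- (records$post_soil_ng + records$resin_ng - records$pre_soil_ng) /
    (area * records$days)
  data.frame(site_id = records$site_id, replicate_id = records$replicate_id,
             nutrient = records$nutrient, rate = rate,
             stringsAsFactors = FALSE)
}

#' Aggregate replicate mineralization rates to site level
#'
#' Computes the per-site mean and standard error of replicate-tube rates for
#' each nutrient (mean-of-replicates convention) and the site-level N:P rate
#' ratio from the site means. The SE is `NA` for a single replicate; the
#' ratio is `NA` (flagged with a message) where the P mean is not positive.
#'
#' @param rates A `data.frame` from [net_mineralization_rate()].
#' @return A `data.frame`, one row per site: `site_id`, `n_rate`, `n_rate_se`,
#'   `n_reps`, `p_rate`, `p_rate_se`, `p_reps`, `np_rate_ratio`.
#' @export
aggregate_rates <- function(rates) {
  stopifnot(is.data.frame(rates), all(c("site_id", "nutrient", "rate") %in%
                                        names(rates)))
  sites <- sort(unique(rates$site_id))
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  one <- function(s, nu) {
    x <- rates$rate[rates$site_id == s & rates$nutrient == nu]
    c(mean = if (length(x) > 0L) mean(x) else NA_real_, se = se(x),
      n = length(x))
  }
  out <- do.call(rbind, lapply(sites, function(s) {
    n <- one(s, "N"); p <- one(s, "P")
    data.frame(site_id = s, n_rate = n[["mean"]], n_rate_se = n[["se"]],
               n_reps = n[["n"]], p_rate = p[["mean"]], p_rate_se = p[["se"]],
               p_reps = p[["n"]], stringsAsFactors = FALSE)
  }))
  out$np_rate_ratio <- ifelse(is.finite(out$p_rate) & out$p_rate > 0,
                              out$n_rate / out$p_rate, NA_real_)
  n_undef <- sum(is.na(out$np_rate_ratio))
  if (n_undef > 0L) {
    message(n_undef, " site(s) with non-positive or missing P rate: N:P rate ",
            "ratio flagged undefined")
  }
  out
}
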