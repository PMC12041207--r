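# Tabular I/O for the leaf-chemistry and resin-core incubation schemas.
# Dialect: comma-separated, UTF-8, one header row, empty cell = missing
# (always an error in a required column; no imputation).

LEAF_COLUMNS <- c("site_id", "quadrat_id", "period", "n_conc_g_kg", "p_conc_g_kg")
INCUBATION_COLUMNS <- c("site_id", "replicate_id", "nutrient", "pre_soil_ng",
                        "post_soil_ng", "resin_ng", "tube_diameter_cm", "days")
PERIOD_LEVELS <- c("mature", "senesced")
NUTRIENT_LEVELS <- c("N", "P")

.require_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in '", path, "': missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.check_numeric_positive <- function(x, name, rows = seq_along(x), strict = TRUE) {
  bad <- if (strict) which(!is.finite(x) | x <= 0) else which(!is.finite(x) | x < 0)
  if (length(bad) > 0L) {
    stop("validation error: column '", name, "' must be ",
         if (strict) "positive" else "non-negative",
         " and non-missing; offending row(s): ",
         paste(utils::head(rows[bad], 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a leaf-chemistry table
#'
#' Reads the comma-separated leaf-chemistry schema: one row per quadrat and
#' sampling period holding community-level leaf N and P concentrations
#' (g kg\eqn{^{-1}}). Required columns are `site_id`, `quadrat_id`, `period`
#' (`"mature"` or `"senesced"`), `n_conc_g_kg` and `p_conc_g_kg`; unknown
#' columns are ignored.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` with the five schema columns, one row per record.
#'   Concentrations are numeric and strictly positive; `period` is a character
#'   vector restricted to the two period labels.
#' @seealso [write_results()], [pair_site_periods()]
#' @export
#' @examples
#' sim <- simulate_transect(synthetic_config(n_sites = 3, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_results(sim$leaf, f)
#' head(read_leaf_table(f))
read_leaf_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, LEAF_COLUMNS, path)
  df <- df[, LEAF_COLUMNS, drop = FALSE]
  if (nrow(df) == 0L) return(df)
  bad_period <- which(!df$period %in% PERIOD_LEVELS)
  if (length(bad_period) > 0L) {
    stop("validation error: unknown period value(s) '",
         paste(unique(df$period[bad_period]), collapse = "', '"),
         "' at row(s): ", paste(utils::head(bad_period, 5L), collapse = ", "),
         " (expected 'mature' or 'senesced')", call. = FALSE)
  }
  df$n_conc_g_kg <- as.numeric(df$n_conc_g_kg)
  df$p_conc_g_kg <- as.numeric(df$p_conc_g_kg)
  .check_numeric_positive(df$n_conc_g_kg, "n_conc_g_kg")
  .check_numeric_positive(df$p_conc_g_kg, "p_conc_g_kg")
  df$site_id <- as.character(df$site_id)
  df$quadrat_id <- as.character(df$quadrat_id)
  df
}

#' Read a resin-core incubation table
#'
#' Reads the incubation schema: one row per tube and nutrient carrying the
#' inorganic nutrient budget (ng) before and after incubation, the total
#' captured on the ion-exchange resin bags (multiple monthly bags pre-summed),
#' the tube diameter (cm) and the incubation length (days).
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` with the eight schema columns.
#' @seealso [net_mineralization_rate()]
#' @export
read_incubation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, INCUBATION_COLUMNS, path)
  df <- df[, INCUBATION_COLUMNS, drop = FALSE]
  if (nrow(df) == 0L) return(df)
  bad_nu <- which(!df$nutrient %in% NUTRIENT_LEVELS)
  if (length(bad_nu) > 0L) {
    stop("validation error: unknown nutrient value(s) at row(s): ",
         paste(utils::head(bad_nu, 5L), collapse = ", "),
         " (expected 'N' or 'P')", call. = FALSE)
  }
  for (col in c("pre_soil_ng", "post_soil_ng", "resin_ng")) {
    df[[col]] <- as.numeric(df[[col]])
    .check_numeric_positive(df[[col]], col, strict = FALSE)
  }
  df$tube_diameter_cm <- as.numeric(df$tube_diameter_cm)
  df$days <- as.numeric(df$days)
  .check_numeric_positive(df$tube_diameter_cm, "tube_diameter_cm")
  .check_numeric_positive(df$days, "days")
  df$site_id <- as.character(df$site_id)
  df$replicate_id <- as.character(df$replicate_id)
  df
}

#' Write a result table to CSV
#'
#' Writes any stage's tabular result so that reading it back yields an
#' equivalent table (round-trip up to floating-point formatting; values are
#' written with full precision).
#'
#' @param records A `data.frame` (possibly empty — the header is still written).
#' @param path Output path; its directory must exist.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("I/O error: directory does not exist: ", dir, call. = FALSE)
  }
  utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair mature and senesced records by site
#'
#' Aggregates quadrat replicates to per-site mean mature and senesced N and P
#' concentrations with replicate standard errors, and retains replicate-level
#' pairs for mixed-model fitting. Periods are matched by site only: senesced
#' quadrats are sampled adjacent to (not identical with) mature quadrats, so
#' replicate pairing within a site is positional by sorted `quadrat_id`.
#'
#' @param records A leaf-chemistry `data.frame` as from [read_leaf_table()].
#' @return An object of class `"leaf_pairs"`: a list with
#'   \describe{
#'     \item{`sites`}{one row per site: `mat_n`, `mat_p`, `sen_n`, `sen_p`
#'       (means, g kg\eqn{^{-1}}) and their standard errors (`*_se`, `NA`
#'       for a single replicate), plus replicate counts.}
#'     \item{`replicates`}{positionally paired replicate rows (`site_id`,
#'       `pair`, `mat_n`, `mat_p`, `sen_n`, `sen_p`); when a site has unequal
#'       replicate counts per period, pairs are formed up to the shorter
#'       count and the remainder contributes to the site means only.}
#'   }
#' @export
pair_site_periods <- function(records) {
  stopifnot(is.data.frame(records))
  need_cols <- LEAF_COLUMNS
  .require_columns(records, need_cols, "<in-memory leaf table>")
  sites <- sort(unique(records$site_id))
  has_mat <- tapply(records$period == "mature", records$site_id, any)
  has_sen <- tapply(records$period == "senesced", records$site_id, any)
  incomplete <- sites[!(has_mat[sites] & has_sen[sites])]
  if (length(incomplete) > 0L) {
    stop("pairing error: site(s) missing one period: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  site_rows <- lapply(sites, function(s) {
    mat <- records[records$site_id == s & records$period == "mature", ]
    sen <- records[records$site_id == s & records$period == "senesced", ]
    data.frame(
      site_id = s,
      mat_n = mean(mat$n_conc_g_kg), mat_n_se = se(mat$n_conc_g_kg),
      mat_p = mean(mat$p_conc_g_kg), mat_p_se = se(mat$p_conc_g_kg),
      sen_n = mean(sen$n_conc_g_kg), sen_n_se = se(sen$n_conc_g_kg),
      sen_p = mean(sen$p_conc_g_kg), sen_p_se = se(sen$p_conc_g_kg),
      n_mature = nrow(mat), n_senesced = nrow(sen),
      stringsAsFactors = FALSE
    )
  })
  rep_rows <- lapply(sites, function(s) {
    mat <- records[records$site_id == s & records$period == "mature", ]
    sen <- records[records$site_id == s & records$period == "senesced", ]
    mat <- mat[order(mat$quadrat_id), ]
    sen <- sen[order(sen$quadrat_id), ]
    k <- min(nrow(mat), nrow(sen))
    data.frame(
      site_id = s, pair = seq_len(k),
      mat_n = mat$n_conc_g_kg[seq_len(k)], mat_p = mat$p_conc_g_kg[seq_len(k)],
      sen_n = sen$n_conc_g_kg[seq_len(k)], sen_p = sen$p_conc_g_kg[seq_len(k)],
      stringsAsFactors = FALSE
    )
  })
  out <- list(sites = do.call(rbind, site_rows),
              replicates = do.call(rbind, rep_rows))
  class(out) <- "leaf_pairs"
  out
}

#' @export
print.leaf_pairs <- function(x, ...) {
  cat("Paired leaf chemistry:", nrow(x$sites), "site(s),",
      nrow(x$replicates), "replicate pair(s)\n")
  print(utils::head(x$sites, 6L), ...)
  if (nrow(x$sites) > 6L) cat("...", nrow(x$sites) - 6L, "more site(s)\n")
  invisible(x)
}

#' Write a key/value run report
#'
#' Plain-text `key = value` report capturing the configuration and package
#' version of a pipeline run, for reproducibility audits.
#'
#' @param values Named list of scalar values.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(values, path) {
  stopifnot(is.list(values), !is.null(names(values)))
  lines <- vapply(names(values), function(k) {
    paste0(k, " = ", paste(format(values[[k]]), collapse = ",")) }, character(1))
  writeLines(c(paste0("package = resorb ",
                      as.character(utils::packageVersion("resorb"))),
               paste0("r_version = ", R.version.string),
               lines), path)
  invisible(path)
}
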