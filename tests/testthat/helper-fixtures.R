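# Fixtures built in code: small leaf tables and independent regression
# oracles used across test files.

# leaf-chemistry table for one or more sites, given per-site mature and
# senesced N/P levels (one quadrat per period unless reps > 1)
make_leaf_table <- function(mat_n, sen_n, mat_p = rep(1.5, length(mat_n)),
                            sen_p = rep(0.4, length(mat_n)), reps = 1L) {
  ns <- length(mat_n)
  do.call(rbind, lapply(seq_len(ns), function(i) {
    rbind(
      data.frame(site_id = sprintf("S%02d", i),
                 quadrat_id = sprintf("Q%d", seq_len(reps)),
                 period = "mature", n_conc_g_kg = mat_n[i],
                 p_conc_g_kg = mat_p[i]),
      data.frame(site_id = sprintf("S%02d", i),
                 quadrat_id = sprintf("Q%d", seq_len(reps)),
                 period = "senesced", n_conc_g_kg = sen_n[i],
                 p_conc_g_kg = sen_p[i])
    )
  }))
}

# brute-force simple linear regression oracle (textbook formulas), kept
# independent of the package's fitting path
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sigma2 <- sum(res^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  list(slope = slope, intercept = intercept, se = se, df = n - 2,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# a pure power-law configuration: no site intensity effect and no
# mineralization coupling, i.e. exactly Nu_sen = a * Nu_mat^b with
# log-normal replicate noise
pure_config <- function(...) {
  synthetic_config(site_effect_sd = 0, tradeoff_slope = 0, ...)
}
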