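test_that("musical-activity coding follows the questionnaire rule", {
  prof <- function(q4, instr, sing) {
    data.frame(musa_q4 = q4, musa_instrument = instr, musa_singing = sing)
  }
  expect_equal(code_musical(prof("no", "daily", "daily")), "not_active")
  expect_equal(code_musical(prof("yes", "2-3 times a month", "Not at all")),
               "active")
  expect_equal(code_musical(prof("yes", "Not at all", "Not at all")),
               "not_active")
  expect_error(code_musical(data.frame(musa_q4 = "yes")), "missing answers")
  expect_error(code_musical(prof("yes", NA, "daily")), "NA answers")
})

test_that("sum coding gives +1/-1 with the grand-mean and 2-beta identities", {
  x <- c("weak", "strong", "strong", "weak")
  code <- sum_code(x, "strong")
  expect_equal(as.numeric(code), c(-1, 1, 1, -1))
  expect_equal(attr(code, "positive"), "strong")
  expect_error(sum_code(c("a", "b", "c")), "two levels")

  # balanced 2x2: intercept of the sum-coded fit is exactly the grand mean
  # of cell means, and the predicted two-level difference is twice the slope
  cells <- expand.grid(stress = c("weak", "strong"),
                       meter = c("iambic", "trochaic"))
  cells <- cells[rep(1:4, each = 5), ]
  set.seed(1)
  cells$y <- 100 + 10 * (cells$stress == "strong") -
    4 * (cells$meter == "iambic") + rnorm(nrow(cells), 0, 2)
  cells$stress_c <- as.numeric(sum_code(cells$stress, "strong"))
  cells$meter_c <- as.numeric(sum_code(cells$meter, "iambic"))
  fit <- lm(y ~ stress_c * meter_c, data = cells)
  cell_means <- tapply(cells$y, paste(cells$stress, cells$meter), mean)
  expect_equal(unname(coef(fit)["(Intercept)"]), mean(cell_means),
               tolerance = 1e-10)
  pred_diff <- predict(fit, data.frame(stress_c = 1, meter_c = 0)) -
    predict(fit, data.frame(stress_c = -1, meter_c = 0))
  expect_equal(unname(pred_diff), 2 * unname(coef(fit)["stress_c"]),
               tolerance = 1e-10)
})

test_that("Cohen's d follows d = 2t/sqrt(df)", {
  expect_equal(round(cohens_d(3.09, 16.53), 2), 1.52)
  expect_equal(cohens_d(0, 10), 0)
  expect_equal(round(cohens_d(11.99, 23.98), 2), 4.90)
  expect_error(cohens_d(1, 0), "positive")
})

test_that("ICC is the intercept-variance share of total variance", {
  expect_equal(round(icc_from_varcomp(c(5982.17, 406.63), 2623.56), 2), 0.71)
  expect_equal(icc_from_varcomp(0, 10), 0)
  expect_equal(icc_from_varcomp(c(3, 2), 0), 1)
})

test_that("noise-free synthetic data identifies every fixed effect exactly", {
  tok <- simulate_novar(round_times = FALSE)
  f <- filter_max_soi(compute_soi(tok))
  cases <- list(list(spec_regular("soi_ms"), "regular_soi"),
                list(spec_regular("i_mean_db"), "regular_intensity"),
                list(spec_tack("soi_ms"), "tack_soi"))
  for (case in cases) {
    sp <- case[[1]]
    fit <- fit_mixed(f, sp)
    truth <- novar_params(case[[2]])$fixed_effects
    names(truth)[names(truth) == "intercept"] <- "(Intercept)"
    est <- setNames(fit$coefficients$beta, fit$coefficients$term)
    expect_equal(est[names(truth)], truth, tolerance = 1e-6)
  }
})

test_that("zero generating variances drive fitted variance components to the boundary", {
  tok <- simulate_novar(round_times = FALSE)
  f <- filter_max_soi(compute_soi(tok))
  fit <- fit_mixed(f, spec_regular("soi_ms"))
  expect_lt(sum(fit$varcomp$tau00), 1e-4)
  expect_lt(fit$varcomp$sigma2, 1e-4)
  # with no random variance the fixed effects match ordinary least squares
  ols <- lm(soi_ms ~ stress_c * musical_c * meter_c, data = fit$data)
  expect_equal(unname(fit$coefficients$beta), unname(coef(ols)),
               tolerance = 1e-4)
})

test_that("the residual df fallback reports n - p", {
  lin <- simulate_lines(two_small_poems(), four_participants(), seed = 6)
  sp <- spec_line("npvi_soi", "tacks_per_line", df_method = "residual")
  fit <- fit_mixed(lin, sp)
  expect_true(all(fit$coefficients$df == fit$n_obs - nrow(fit$coefficients)))
  expect_true(all(fit$coefficients$p > 0 & fit$coefficients$p <= 1))
})

test_that("two-pass outlier filtering reproduces a direct Tukey-fence oracle", {
  lin <- simulate_lines(study_poems(seed = 31), study_participants(),
                        seed = 32)
  sp <- spec_line("npvi_soi", "tacks_per_line")
  tp <- two_pass_outlier_fit(lin, sp)
  r <- residuals(tp$first_fit$fit)
  fn <- stats::fivenum(as.numeric(r))
  lower <- fn[2] - 1.5 * (fn[4] - fn[2])
  upper <- fn[4] + 1.5 * (fn[4] - fn[2])
  keep_oracle <- as.numeric(r) >= lower & as.numeric(r) <= upper
  expect_equal(nrow(tp$retained), sum(keep_oracle))
  expect_equal(tp$n_dropped, sum(!keep_oracle))
  expect_equal(unname(tp$fences), c(lower, upper))
  # row-for-row: the retained rows are exactly the oracle-kept rows
  expect_equal(tp$retained$npvi_soi,
               prepare_model_data(lin, sp)$npvi_soi[keep_oracle])
})

test_that("a gross injected outlier is the row removed by the second pass", {
  lin <- simulate_lines(study_poems(seed = 41), study_participants(),
                        seed = 42)
  sp <- spec_line("npvi_soi", "tacks_per_line")
  clean <- two_pass_outlier_fit(lin, sp)
  victim <- 777
  lin$npvi_soi[victim] <- lin$npvi_soi[victim] +
    10 * sqrt(282.25)   # +10 residual SD
  tp <- two_pass_outlier_fit(lin, sp)
  r <- as.numeric(residuals(tp$first_fit$fit))
  expect_gt(abs(r[victim]), tp$fences["upper"])
  dropped <- setdiff(seq_len(tp$first_fit$n_obs),
                     which(r >= tp$fences["lower"] & r <= tp$fences["upper"]))
  expect_true(victim %in% dropped)
  # the filter acts on residuals, not raw responses: a constant response
  # shift leaves the removed set unchanged
  lin2 <- lin
  lin2$npvi_soi <- lin2$npvi_soi + 1000
  tp2 <- two_pass_outlier_fit(lin2, sp)
  expect_equal(tp2$n_dropped, tp$n_dropped)
  r2 <- as.numeric(residuals(tp2$first_fit$fit))
  expect_equal(which(!(r2 >= tp2$fences["lower"] & r2 <= tp2$fences["upper"])),
               dropped)
  expect_gte(clean$first_fit$n_obs, tp$first_fit$n_obs - 1)
})

test_that("fits with all residuals inside the fences keep every row", {
  # tiny residual noise, wide data: nothing can cross a 1.5-IQR fence
  lin <- simulate_lines(two_small_poems(), four_participants(), seed = 51,
                        params = generative_params(
                          "line_tacks_per_line_soi",
                          resid_sd = 1e-6,
                          participant_re = list(intercept_sd = 0, slope_sd = 0,
                                                corr = 0,
                                                slope_term = "tacks_per_line"),
                          poem_re_sd = 0))
  tp <- two_pass_outlier_fit(lin, spec_line("npvi_soi", "tacks_per_line"))
  expect_equal(tp$n_dropped, 0L)
  expect_equal(tp$final_fit$coefficients$beta, tp$first_fit$coefficients$beta,
               tolerance = 1e-8)
})

test_that("report tables carry the coefficient layout and hide tiny effect sizes", {
  lin <- simulate_lines(two_small_poems(), four_participants(), seed = 61)
  fit <- fit_mixed(lin, spec_line("npvi_soi", "tacks_per_line"))
  rep_tab <- report_table(fit)
  expect_named(rep_tab, c("term", "beta", "ste", "df", "t", "p", "d"))
  expect_equal(nrow(rep_tab), 8L)
  small <- abs(fit$coefficients$cohens_d) <= 0.1
  expect_true(all(is.na(rep_tab$d[small])))
  expect_output(print(fit), "Random effects")
})

test_that("the instruction-variant line model fits with sum-coded instruction", {
  lin <- simulate_lines(study_poems(seed = 71), study_participants(),
                        seed = 72)
  fit <- fit_mixed(lin, spec_line("npvi_soi", "tacks_per_line",
                                  with_instruction = TRUE))
  expect_true(any(grepl("instruction", fit$coefficients$term)))
  expect_true(any(grepl("tacks_per_line:instruction",
                        fit$coefficients$term)))
  # sum contrasts: instruction columns sum to zero over the design
  expect_equal(sum(stats::contr.sum(3)), 0)
})

test_that("the musically-active subset refit of the tack model is supported", {
  poems <- study_poems(seed = 81)
  pp <- study_participants()
  tok <- simulate_syllables(poems, pp, seed = 82)
  f <- filter_max_soi(compute_soi(tok))
  fit <- fit_mixed(f, spec_tack("soi_ms", musical_only = "active"))
  expect_false(any(grepl("musical", fit$coefficients$term)))
  expect_true(all(fit$data$musical == "active"))
  expect_true("stress:meter:tack_index" %in% fit$coefficients$term)
})
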