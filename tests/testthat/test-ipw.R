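toy_panel <- function(n = 400, p_meas = 0.3, seed = 101, months = 12L) {
  set.seed(seed)
  grid <- data.table::CJ(patient_id = seq_len(n), month = seq_len(months))
  grid[, `:=`(arm = "a", obesity = rep(rbinom(n, 1, 0.5), each = months),
              age10 = 5, sexF = 0L, lwc = 0)]
  grid[, measured := rbinom(.N, 1, p_meas)]
  grid[, y := rnorm(.N)]
  grid
}

test_that("an uninformative measurement process yields flat weights near 1/p", {
  p <- toy_panel(n = 1500, p_meas = 0.3)
  fit <- fit_measurement_weights(p, spec = ipw_spec(use_arm = FALSE,
                                                    time_varying = NULL,
                                                    baseline = "obesity"))
  w <- fit$table[measured == 1L, w_meas]
  expect_equal(mean(1 / w), 0.3, tolerance = 0.02)
  expect_lt(diff(range(w)) / mean(w), 0.25)
})

test_that("all rows measured gives unit weights exactly at the floor cap", {
  p <- toy_panel(n = 120, p_meas = 1)
  fit <- fit_measurement_weights(p, spec = ipw_spec(use_arm = FALSE,
                                                    time_varying = NULL,
                                                    baseline = "obesity"))
  # fitted probabilities are clipped just below 1, so weights sit at ~1
  expect_true(all(abs(fit$table$w_meas - 1) < 1e-5))
})

test_that("a planted measurement coefficient is recovered within 3 SE", {
  set.seed(77)
  n <- 10000L
  months <- 6L
  grid <- data.table::CJ(patient_id = seq_len(n), month = seq_len(months))
  x <- rbinom(n, 1, 0.5)
  grid[, `:=`(arm = "a", obesity = rep(x, each = months), age10 = 5,
              sexF = 0L, lwc = 0)]
  eta <- qlogis(0.25) + 1.0 * grid$obesity
  grid[, measured := rbinom(.N, 1, plogis(eta))]
  grid[, y := 0]
  spec <- ipw_spec(use_arm = FALSE, time_varying = NULL, baseline = "obesity")
  fit <- fit_measurement_weights(grid, spec = spec)
  bx <- fit$coef[["obesity"]]
  # SE from the inverse information at the fit
  X <- cbind(1, grid$obesity)
  ph <- plogis(fit$coef[["(Intercept)"]] + bx * grid$obesity)
  H <- t(X) %*% (X * (ph * (1 - ph)))
  se <- sqrt(solve(H)[2, 2])
  expect_lt(abs(bx - 1.0), 3 * se)
})

test_that("no deviations means unit censoring weights without fitting", {
  p <- toy_panel(n = 60)
  ci <- data.table::data.table(patient_id = 1:60,
                               censor_month = NA_integer_,
                               exhaustion_day = NA_real_,
                               reason = "end-of-follow-up")
  fit <- fit_adherence_weights(p, ci, spec = ipw_spec(use_arm = FALSE,
                                                      time_varying = NULL,
                                                      baseline = "obesity"))
  expect_equal(fit$n_events, 0L)
  expect_true(all(fit$table$w_cens == 1))
})

test_that("a constant stop hazard gives the lagged geometric censoring weights", {
  set.seed(404)
  n <- 20000L
  months <- 8L
  h <- 0.1
  stopm <- 1L + stats::rgeom(n, h) # first non-adhered month
  p <- data.table::CJ(patient_id = seq_len(n), month = seq_len(months))
  p[, `:=`(arm = "a", obesity = 0L, age10 = 5, sexF = 0L, lwc = 0,
           measured = 1L, y = 0)]
  ci <- data.table::data.table(
    patient_id = seq_len(n),
    censor_month = stopm + 1L, # grace shifts the censor month past the stop
    exhaustion_day = 30 * stopm,
    reason = "nonadherence")
  fit <- fit_adherence_weights(p, ci,
                               spec = ipw_spec(use_arm = FALSE,
                                               time_varying = NULL,
                                               baseline = NULL,
                                               time_trend = "factor"))
  wk <- fit$table[, .(w = mean(w_cens)), keyby = month]
  # inclusion at month t requires surviving months 1..t-1
  expect_equal(wk$w, (1 - h)^(-(wk$month - 1)), tolerance = 0.06)
})

test_that("truncation caps at the inverse-ECDF percentile and preserves order below it", {
  w <- data.table::data.table(patient_id = 1:200, month = 1L,
                              measured = 1L, p_meas = 1 / (1:200),
                              w_meas = as.numeric(1:200))
  meas <- list(table = w)
  out <- combine_and_truncate(meas, percentile = 99)
  cap <- sort(w$w_meas)[ceiling(0.99 * 200)] # order statistic: 198
  expect_equal(attr(out, "cap"), cap)
  expect_equal(max(out$w_trunc), cap)
  expect_lte(var(out$w_trunc), var(out$w_comb))
  below <- out[w_comb < cap]
  expect_equal(order(below$w_trunc), order(below$w_comb))
  # percentile 100 leaves the weights untouched
  out100 <- combine_and_truncate(meas, percentile = 100)
  expect_equal(out100$w_trunc, out100$w_comb)
  # constant weights are unchanged by truncation
  wc <- data.table::data.table(patient_id = 1:50, month = 1L, measured = 1L,
                               p_meas = 0.5, w_meas = 2)
  outc <- combine_and_truncate(list(table = wc), percentile = 99)
  expect_true(all(outc$w_trunc == 2))
})

test_that("measurement weights debias a covariate-driven missingness process", {
  set.seed(99)
  n <- 4000L
  months <- 4L
  x <- rbinom(n, 1, 0.5)
  p <- data.table::CJ(patient_id = seq_len(n), month = seq_len(months))
  p[, `:=`(arm = "a", obesity = rep(x, each = months), age10 = 5, sexF = 0L,
           lwc = 0)]
  p[, y := 2 * obesity + rnorm(.N)] # truth: E[y] = 1
  p[, measured := rbinom(.N, 1, plogis(-1.5 + 2 * obesity))]
  spec <- ipw_spec(use_arm = FALSE, time_varying = NULL, baseline = "obesity")
  fit <- fit_measurement_weights(p, spec = spec)
  wt <- combine_and_truncate(fit, percentile = 99)
  m <- p[wt, on = .(patient_id, month)]
  naive <- m[, mean(y)]
  weighted <- m[, sum(y * w_trunc) / sum(w_trunc)]
  expect_gt(naive, 1.25) # selection pushes the unweighted mean up
  expect_lt(abs(weighted - 1), 0.1)
})
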