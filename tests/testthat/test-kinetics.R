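test_that("single-exponential MLE recovers the rate and matches survreg", {
  set.seed(21)
  d <- rexp(2000, 2)
  fit <- fit_dwell_exponential(durations = d, censored = rep(FALSE, 2000))
  expect_equal(fit$rates, 2, tolerance = 0.05)
  expect_equal(fit$rates, 1 / mean(d), tolerance = 1e-9)  # rate-dwell duality

  # censored fit cross-checked against the survival package
  skip_if_not_installed("survival")
  cens <- d > 0.6
  dc <- pmin(d, 0.6)
  mine <- fit_dwell_exponential(durations = dc, censored = cens)
  sv <- survival::survreg(survival::Surv(dc, !cens) ~ 1,
                          dist = "exponential")
  expect_equal(mine$rates, exp(-unname(coef(sv))), tolerance = 1e-6)
})

test_that("censoring-aware MLE is unbiased where the naive mean is not", {
  set.seed(22)
  k <- 3
  d <- rexp(2000, k)
  cutoff <- quantile(d, 0.7)  # right-censor the longest 30% of dwells
  cens <- d > cutoff
  dc <- pmin(d, cutoff)
  fit <- fit_dwell_exponential(durations = dc, censored = cens)
  expect_lt(abs(fit$rates - k) / k, 0.05)
  naive <- 1 / mean(dc[!cens])
  expect_gt(naive / k, 1.25)  # naive mean-of-uncensored is badly inflated
})

test_that("two-exponential fits resolve a kinetic mixture and BIC prefers it", {
  set.seed(23)
  d <- c(rexp(2100, 5.9), rexp(900, 1.3))
  fit <- fit_dwell_exponential(durations = d, censored = rep(FALSE, 3000),
                               n_components = 2)
  expect_lt(abs(fit$rates[1] - 5.9) / 5.9, 0.15)
  expect_lt(abs(fit$rates[2] - 1.3) / 1.3, 0.15)
  sel <- select_exp_model(durations = d, censored = rep(FALSE, 3000))
  expect_equal(sel$n_components, 2L)

  # a pure exponential stays monophasic
  pure <- rexp(2000, 2)
  expect_equal(select_exp_model(durations = pure,
                                censored = rep(FALSE, 2000))$n_components, 1L)

  # too few dwells force the single-exponential model
  few <- rexp(30, 2)
  self <- select_exp_model(durations = few, censored = rep(FALSE, 30))
  expect_equal(self$n_components, 1L)
  expect_true(self$forced)

  expect_error(fit_dwell_exponential(durations = 0.5, censored = FALSE),
               "insufficient")
  expect_error(
    fit_dwell_exponential(durations = rexp(10), censored = rep(TRUE, 10)),
    "censored"
  )
})

test_that("trace-level mixture reports molecule fractions, not dwell fractions", {
  set.seed(24)
  # 70% fast molecules contribute ~4.5x more dwells each; the dwell-level
  # amplitude would sit far above 0.7 while the molecule fraction is 0.7
  rows <- list()
  for (j in 1:200) {
    fast <- j <= 140
    n <- rpois(1, if (fast) 45 else 10) + 2
    rows[[j]] <- data.frame(
      trace_id = j, state = "N", state_mean = 0.73,
      start_frame = 0, n_frames = 1,
      duration_s = rexp(n, if (fast) 5.9 else 1.3),
      censored_left = FALSE, censored_right = FALSE,
      end_cause = "transition"
    )
  }
  dw <- do.call(rbind, rows)
  class(dw) <- c("dwell_table", "data.frame")
  mix <- fit_dwell_mixture_traces(dw, "N")
  expect_lt(abs(mix$fraction_fast - 0.7), 0.04)
  expect_lt(abs(mix$rates[1] - 5.9) / 5.9, 0.15)
  expect_lt(abs(mix$rates[2] - 1.3) / 1.3, 0.15)
  # the pooled dwell-level amplitude is visibly larger than 0.7
  pooled <- fit_dwell_exponential(dwells = dw, state = "N", n_components = 2)
  expect_gt(pooled$fractions[1], 0.8)
})

test_that("the dead-time correction inverts the merging bias model", {
  # forward model: with dead time theta, observed inverse rates are
  # 1/k_raw = (1+m)/k + m*E[tau_b | tau_b < theta]; the correction must
  # invert this exactly
  theta <- 1 / 30
  for (k in list(c(1, 1.5), c(2, 6), c(5.9, 2.9))) {
    qb <- 1 - exp(-k[2] * theta); ma <- qb / (1 - qb)
    etb <- 1 / k[2] - theta * exp(-k[2] * theta) / qb
    qa <- 1 - exp(-k[1] * theta); mb <- qa / (1 - qa)
    eta <- 1 / k[1] - theta * exp(-k[1] * theta) / qa
    raw_a <- 1 / ((1 + ma) / k[1] + ma * etb)
    raw_b <- 1 / ((1 + mb) / k[2] + mb * eta)
    rec <- correct_missed_events(raw_a, raw_b, theta)
    expect_equal(rec, k, tolerance = 1e-6)
  }
  # no dead time, no change
  expect_equal(correct_missed_events(2, 3, 0), c(2, 3))
})

test_that("photobleach rate is recovered from static traces", {
  fx <- scenario_fixture("bleach_calibration")
  ts <- simulate_scenario(fx, 300, seed = 25)
  est <- estimate_photobleach_rate(ts)
  # combined dye-pair rate: donor 0.05 + acceptor 0.05
  expect_lt(abs(est$mean - 0.10) / 0.10, 0.15)
  expect_error(estimate_photobleach_rate(ts$traces[1:5]), "at least")

  # nothing bleaches inside the window: only an upper bound
  fx2 <- fx
  fx2$emission$bleach_rate_donor <- 0
  fx2$emission$bleach_rate_acceptor <- 0
  ts2 <- simulate_scenario(fx2, 30, seed = 26, duration = 5)
  est2 <- estimate_photobleach_rate(ts2$traces)
  expect_true(est2$bound)
  expect_true(is.na(est2$mean))
})

test_that("photobleaching correction subtracts, propagates and bounds", {
  c1 <- correct_koff(6.0, 0.1, sd_obs = 0.3, sd_bleach = 0.05)
  expect_equal(c1$mean, 5.9)
  expect_equal(c1$sd, sqrt(0.3^2 + 0.05^2))
  expect_true(c1$corrected)
  expect_false(c1$bound)

  # unresolvable against the bleach rate: a detection-limit bound
  c2 <- correct_koff(0.15, 0.12, sd_obs = 0.02, sd_bleach = 0.02)
  expect_true(c2$bound)
  expect_equal(c2$limit, 0.2)
  expect_true(is.na(c2$mean))

  # k_obs below k_bleach can never yield a negative rate
  c3 <- correct_koff(0.08, 0.12, sd_obs = 0.02, sd_bleach = 0.02)
  expect_true(c3$bound)
})

test_that("replicate aggregation gives mean, sample sd and bound propagation", {
  a <- aggregate_replicates(list(
    rate_estimate("k_off", 2.0), rate_estimate("k_off", 2.2),
    rate_estimate("k_off", 2.4)
  ))
  expect_equal(a$mean, 2.2)
  expect_equal(a$sd, 0.2)

  single <- aggregate_replicates(list(rate_estimate("k_off", 2.0)))
  expect_true(is.na(single$sd))

  withbound <- aggregate_replicates(list(
    rate_estimate("k_off", 0.15),
    rate_estimate("k_off", NA, bound = TRUE, limit = 0.2)
  ))
  expect_true(withbound$bound)
  expect_equal(withbound$limit, 0.2)

  expect_error(
    aggregate_replicates(list(rate_estimate("k_off", 1),
                              rate_estimate("k_on", 1))),
    "different quantities"
  )
})
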