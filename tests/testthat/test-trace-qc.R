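test_that("three-point smoother handles interiors and edges", {
  expect_equal(smooth3(rep(4, 10)), rep(4, 10))      # constant unchanged
  expect_equal(smooth3(5), 5)                        # length-1 unchanged
  x <- c(0, 0, 0, 3, 0, 0, 0)
  expect_equal(smooth3(x), c(0, 0, 1, 1, 1, 0, 0))   # impulse spreads to 1,1,1
  # never leaves the input range
  set.seed(1)
  y <- rnorm(100)
  expect_true(all(smooth3(y) >= min(y) & smooth3(y) <= max(y)))
})

test_that("bleed-through correction is exact arithmetic and invertible", {
  tr <- structure(list(frame = 0:1, time_s = c(0, 1 / 30),
                       donor = c(1000, 1000), acceptor = c(830, 830),
                       frame_rate = 30, meta = list(), truth = NULL),
                  class = "fret_trace")
  out <- correct_bleedthrough(tr, 0.13)
  expect_equal(out$acceptor, c(700, 700))
  expect_equal(correct_bleedthrough(tr, 0)$acceptor, tr$acceptor)
  expect_error(correct_bleedthrough(tr, 1), "beta")

  # generator/corrector inverse: rendering with beta then correcting equals
  # the beta = 0 render, frame by frame
  s <- kinetic_scheme("A", 0.62, 0.05, matrix(0, 1, 1))
  p <- sample_state_path(s, 2, seed = 1)
  with_beta <- render_trace(p, s, noiseless_emission(beta = 0.13))
  without <- render_trace(p, s, noiseless_emission(beta = 0))
  expect_equal(correct_bleedthrough(with_beta, 0.13)$acceptor,
               without$acceptor, tolerance = 1e-9)
})

test_that("FRET computation masks degenerate frames", {
  tr <- structure(list(frame = 0:3, time_s = (0:3) / 30,
                       donor = c(300, 1000, 0, 0),
                       acceptor = c(700, 0, 0, 700),
                       frame_rate = 30, meta = list(), truth = NULL),
                  class = "fret_trace")
  f <- compute_fret(tr, smooth = FALSE, total_floor = 1)
  expect_equal(f$fret[1], 0.7)
  expect_equal(f$fret[2], 0)
  expect_false(f$valid[3])   # both channels zero -> masked
  expect_true(is.na(f$fret[3]))
})

test_that("bleach step detection finds planted steps and nothing else", {
  x <- c(rep(1000, 50), rep(0, 50))
  det <- detect_bleach_steps(x)
  expect_equal(det$n_steps, 1)
  expect_equal(det$step_frames, 50)

  expect_equal(detect_bleach_steps(rep(500, 80))$n_steps, 0)

  two <- c(rep(1000, 40), rep(500, 30), rep(0, 30))
  det2 <- detect_bleach_steps(two, min_drop_frac = 0.3)
  expect_equal(det2$n_steps, 2)
  expect_equal(det2$step_frames, c(40, 70))

  # noisy single step is still found at the planted frame
  set.seed(4)
  noisy <- c(rnorm(60, 1000, 70), rnorm(60, 0, 70))
  detn <- detect_bleach_steps(noisy)
  expect_equal(detn$n_steps, 1)
  expect_lt(abs(detn$step_frames - 60), 3)

  # reversible FRET-state intensity changes are not bleach steps
  fret_like <- rep(c(rep(700, 20), rep(400, 20)), 3)
  expect_equal(detect_bleach_steps(fret_like)$n_steps, 0)
})

test_that("bleed-through estimation inverts the generator exactly", {
  s <- kinetic_scheme("A", 0.62, 0.05, matrix(0, 1, 1))
  mk <- function(beta) {
    p <- sample_state_path(s, 10, seed = 2)
    p$bleach_time_acceptor <- 4
    render_trace(p, s, noiseless_emission(beta = beta))
  }
  expect_equal(estimate_bleedthrough(list(mk(0.13)))$beta_hat, 0.13,
               tolerance = 1e-9)
  expect_equal(estimate_bleedthrough(list(mk(0)))$beta_hat, 0,
               tolerance = 1e-9)
  # no qualifying (acceptor-bleached, donor-alive) segment anywhere
  p <- sample_state_path(s, 10, seed = 2)
  tr <- render_trace(p, s, noiseless_emission(beta = 0.13))
  expect_error(estimate_bleedthrough(list(tr)), "calibration")
})

test_that("trace selection accepts good molecules and labels rejections", {
  s <- two_state_scheme(k12 = 1.5, k21 = 1.5, means = c(0.5, 0.7))
  em <- emission_model(bleach_rate_donor = 0, bleach_rate_acceptor = 0)
  set.seed(5)
  traces <- lapply(1:8, function(i) {
    render_trace(sample_state_path(s, 10, seed = i), s, em, seed = 100 + i)
  })
  # a co-varying (aggregate-like) trace: a static molecule whose channels
  # share a common intensity flicker rises and falls in both channels
  st <- kinetic_scheme("A", 0.6, 0.05, matrix(0, 1, 1))
  bad <- render_trace(sample_state_path(st, 10, seed = 99), st, em, seed = 99)
  flick <- 1 + rnorm(length(bad$frame), 0, 0.3)
  bad$donor <- bad$donor * flick
  bad$acceptor <- bad$acceptor * flick
  traces[[8]] <- bad

  sel <- select_traces(traces, beta = 0.13)
  expect_true(all(1:7 %in% sel$accepted))
  expect_false(8 %in% sel$accepted)
  expect_equal(sel$report$reason[8], "correlation")
  # anti-correlated fluctuating traces have strongly negative correlation
  expect_true(all(sel$report$correlation[1:7] < 0.1))

  # two donor bleach steps -> rejected as multistep
  ms <- traces[[1]]
  n <- length(ms$frame)
  ms$donor <- c(rep(1000, n %/% 2), rep(500, n %/% 4), rep(0, n - n %/% 2 - n %/% 4)) +
    rnorm(n, 0, 20)
  ms$acceptor <- rep(100, n) + rnorm(n, 0, 20)
  sel2 <- select_traces(c(traces[1:3], list(ms)), beta = 0.13)
  expect_equal(sel2$report$reason[4], "multistep_donor")

  # acceptor dead before the recording: flat near-zero FRET, no information
  dark <- traces[[2]]
  n2 <- length(dark$frame)
  dark$donor <- rnorm(n2, 1000, 70)
  dark$acceptor <- 0.13 * dark$donor + rnorm(n2, 0, 20)
  sel3 <- select_traces(c(traces[1:3], list(dark)), beta = 0.13)
  expect_equal(sel3$report$reason[4], "no_acceptor")
  # ...but dark periods are fine in binding mode
  sel4 <- select_traces(c(traces[1:3], list(dark)), beta = 0.13,
                        check_acceptor_steps = FALSE)
  expect_true(4 %in% sel4$accepted)

  # empty input: empty report, no error
  empty <- select_traces(list())
  expect_equal(nrow(empty$report), 0)
  expect_length(empty$accepted, 0)
})

test_that("clean sets pass QC at >= 90% and aggregates are rejected at >= 95%", {
  ts <- simulate_scenario("posthc_s6l9", 60, seed = 17)
  sel <- select_traces(ts, beta = 0.13)
  expect_gte(length(sel$accepted) / 60, 0.90)

  doped <- simulate_doped_set("posthc_s6l9", 100, frac_aggregate = 0.2,
                              seed = 23)
  seld <- select_traces(doped, beta = 0.13)
  agg_idx <- which(doped$manifest$is_aggregate)
  rejected <- setdiff(agg_idx, seld$accepted)
  expect_gte(length(rejected) / length(agg_idx), 0.95)
})
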