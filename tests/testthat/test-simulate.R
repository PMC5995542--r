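test_that("all-zero rates give a single full-length segment", {
  s <- kinetic_scheme(c("N", "R"), c(0.7, 0.5), c(0.05, 0.05),
                      matrix(0, 2, 2), initial_probs = c(1, 0))
  p <- sample_state_path(s, 10, seed = 1)
  expect_equal(nrow(p$segments), 1)
  expect_equal(p$segments$state, "N")
  expect_equal(p$segments$t_start, 0)
  expect_equal(p$segments$t_end, 10)
})

test_that("sojourn times follow the exponential exit-rate law", {
  s <- two_state_scheme(k12 = 1, k21 = 1)
  p <- sample_state_path(s, 12000, seed = 7)
  d <- p$segments$t_end - p$segments$t_start
  d <- d[-c(1, length(d))]  # interior sojourns only
  expect_gt(length(d), 5000)
  # analytic mean of Exponential(1) is 1
  expect_equal(mean(d), 1, tolerance = 0.02)
  # distributional check against the exponential with the exit rate
  ks <- suppressWarnings(stats::ks.test(d, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("long-run occupancy matches the analytic stationary distribution", {
  s <- two_state_scheme(k12 = 5.9, k21 = 2.9)  # lo -> hi at 5.9
  p <- sample_state_path(s, 12000, seed = 11)
  d <- p$segments$t_end - p$segments$t_start
  frac_hi <- sum(d[p$segments$state == "hi"]) / sum(d)
  expect_equal(frac_hi, 5.9 / (5.9 + 2.9), tolerance = 0.02)
})

test_that("noiseless rendering follows the emission arithmetic", {
  s <- kinetic_scheme("A", 0.7, 0.05, matrix(0, 1, 1))
  p <- sample_state_path(s, 1, seed = 1)
  tr <- render_trace(p, s, noiseless_emission(beta = 0))
  expect_equal(tr$donor, rep(300, 30))
  expect_equal(tr$acceptor, rep(700, 30))

  # dark state with bleed-through: all intensity in the donor, beta leaks
  sd_ <- kinetic_scheme("d", 0.5, 0.05, matrix(0, 1, 1), dark_states = "d")
  trd <- render_trace(sample_state_path(sd_, 1, seed = 1), sd_,
                      noiseless_emission(beta = 0.13))
  expect_equal(trd$donor, rep(1000, 30))
  expect_equal(trd$acceptor, rep(130, 30))
})

test_that("photobleaching zeroes the affected frames", {
  s <- kinetic_scheme("A", 0.7, 0.05, matrix(0, 1, 1))
  p <- sample_state_path(s, 4, seed = 1)
  p$bleach_time_donor <- 50 / 30
  tr <- render_trace(p, s, noiseless_emission())
  expect_true(all(tr$donor[tr$frame >= 50] == 0))
  expect_true(all(tr$acceptor[tr$frame >= 50] == 0))
  expect_true(all(abs(tr$donor[tr$frame < 50] - 300) < 1e-9))

  # acceptor bleach first: intensity returns to the donor, bleed-through stays
  p$bleach_time_donor <- Inf
  p$bleach_time_acceptor <- 20 / 30
  tr2 <- render_trace(p, s, noiseless_emission(beta = 0.13))
  expect_true(all(tr2$donor[tr2$frame >= 20] == 1000))
  expect_equal(tr2$acceptor[tr2$frame >= 20],
               rep(130, sum(tr2$frame >= 20)))
})

test_that("frame-averaged FRET conserves intensity and occupancy", {
  s <- two_state_scheme(k12 = 2, k21 = 3, means = c(0.3, 0.8))
  p <- sample_state_path(s, 5, seed = 3)
  em <- noiseless_emission(beta = 0.13)
  tr <- render_trace(p, s, em)
  # donor + acceptor - beta * donor = I_tot on every pre-bleach frame
  expect_equal(tr$donor + tr$acceptor - 0.13 * tr$donor,
               rep(1000, length(tr$frame)), tolerance = 1e-9)
  # exact occupancy integration: frames fully inside a segment carry the
  # state FRET value exactly
  f <- compute_fret(correct_bleedthrough(tr, 0.13), smooth = FALSE)
  seg <- p$segments
  inner <- which(vapply(seq_along(tr$frame), function(i) {
    t0 <- tr$frame[i] / 30; t1 <- t0 + 1 / 30
    any(seg$t_start <= t0 + 1e-12 & seg$t_end >= t1 - 1e-12)
  }, logical(1)))
  truth <- tr$truth$mean_fret
  expect_equal(f$fret[inner], truth[inner], tolerance = 1e-9)
  states_at <- seg$state[findInterval(tr$frame[inner] / 30 + 1e-9, seg$t_start)]
  expect_equal(truth[inner],
               s$fret_mean[match(states_at, s$state_ids)], tolerance = 1e-12)
})

test_that("scenario simulation is reproducible and mixture-faithful", {
  a <- simulate_scenario("posthc_s6l9", 4, seed = 9, duration = 3)
  b <- simulate_scenario("posthc_s6l9", 4, seed = 9, duration = 3)
  expect_identical(a$traces[[2]]$donor, b$traces[[2]]$donor)
  expect_identical(a$manifest$truth[[3]]$segments,
                   b$manifest$truth[[3]]$segments)

  e <- simulate_scenario("posthc_s6l9", 0, seed = 1)
  expect_length(e$traces, 0)
  expect_equal(e$manifest$n_traces, 0)

  # binomial subpopulation sampling of the 70/30 mixture
  m <- simulate_scenario("rf1gaq_rf3_rotation", 1000, seed = 13, duration = 0.2)
  sub <- vapply(m$manifest$truth, function(t) t$subpopulation, numeric(1))
  expect_equal(mean(sub == 1), 0.7, tolerance = 0.03)
})

test_that("trace sets round-trip through TSV plus manifest", {
  ts <- simulate_scenario("prehc_s6l9", 3, seed = 2, duration = 2)
  dir <- withr::local_tempdir()
  write_trace_set(ts, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_trace_set(dir)
  expect_length(back$traces, 3)
  expect_equal(back$traces[[1]]$donor, ts$traces[[1]]$donor,
               tolerance = 1e-4)
  expect_equal(back$manifest$scenario, "prehc_s6l9")

  # identical seed, identical bytes
  dir2 <- withr::local_tempdir()
  write_trace_set(simulate_scenario("prehc_s6l9", 3, seed = 2, duration = 2),
                  dir2)
  expect_identical(readLines(file.path(dir, "trace_0002.tsv")),
                   readLines(file.path(dir2, "trace_0002.tsv")))
})
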