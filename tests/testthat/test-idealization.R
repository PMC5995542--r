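test_that("a clean two-level series is fitted exactly", {
  x <- rep(c(rep(0.5, 10), rep(0.7, 10)), 5)
  fit <- fit_hmm(x, K = 2)
  expect_equal(fit$mean, c(0.5, 0.7), tolerance = 1e-6)
  p <- viterbi_decode(fit, x)
  expect_equal(which(diff(p$state) != 0), seq(10, 90, by = 10))
})

test_that("K = 1 reduces to the sample moments", {
  set.seed(2)
  x <- rnorm(200, 0.6, 0.04)
  fit <- fit_hmm(x, K = 1)
  expect_equal(fit$mean, mean(x))
  expect_equal(fit$sd, sd(x))
})

test_that("EM log-likelihood is non-decreasing on every iteration", {
  set.seed(3)
  for (rep in 1:5) {
    x <- c(rnorm(150, 0.5, 0.05), rnorm(150, 0.7, 0.05))[sample(300)]
    fit <- fit_hmm(x, K = 2, n_restarts = 0)
    expect_true(all(diff(fit$ll_path) > -1e-7))
  }
})

test_that("state means of simulated rotation traces are recovered within 0.02", {
  # two-state exchange at the subunit-rotation FRET levels
  s <- two_state_scheme(k12 = 1, k21 = 1, means = c(0.52, 0.73))
  em <- emission_model(bleach_rate_donor = 0, bleach_rate_acceptor = 0)
  tr <- render_trace(sample_state_path(s, 30, seed = 6), s, em, seed = 7)
  f <- compute_fret(correct_bleedthrough(tr, 0.13), smooth = FALSE)
  fit <- fit_hmm(f, K = 2)
  expect_equal(fit$mean, c(0.52, 0.73), tolerance = 0.02)
})

test_that("BIC selects the generating number of states", {
  set.seed(8)
  one <- rnorm(400, 0.7, 0.05)
  expect_equal(select_K(one, K_max = 3)$K, 1)

  s <- two_state_scheme(k12 = 1.5, k21 = 1.5, means = c(0.5, 0.7))
  em <- emission_model(bleach_rate_donor = 0, bleach_rate_acceptor = 0)
  tr <- render_trace(sample_state_path(s, 20, seed = 9), s, em, seed = 10)
  f <- compute_fret(correct_bleedthrough(tr, 0.13), smooth = FALSE)
  expect_equal(select_K(f, K_max = 3)$K, 2)

  expect_equal(select_K(rep(0.6, 50), K_max = 3)$K, 1)  # constant series
})

test_that("Viterbi equals brute-force enumeration on short traces", {
  set.seed(11)
  for (case in 1:12) {
    K <- sample(2:3, 1)
    T_ <- sample(4:10, 1)
    mu <- sort(runif(K, 0.2, 0.9))
    sd_ <- runif(K, 0.03, 0.10)
    A <- matrix(runif(K * K, 0.05, 1), K, K)
    A <- A / rowSums(A)
    pi0 <- rep(1 / K, K)
    x <- runif(T_, 0.1, 1)
    fit <- structure(
      list(K = K, mean = mu, sd = sd_, transmat = A, init = pi0,
           loglik = NA, n = T_),
      class = "hmm_fit"
    )
    expect_equal(viterbi_decode(fit, x)$state,
                 brute_force_viterbi(x, mu, sd_, A, pi0),
                 info = paste("case", case))
  }
})

test_that("Viterbi ties break toward the lower-mean state", {
  # perfectly symmetric model, every frame equidistant from both means
  fit <- structure(
    list(K = 2L, mean = c(0.4, 0.6), sd = c(0.05, 0.05),
         transmat = matrix(0.5, 2, 2), init = c(0.5, 0.5),
         loglik = NA, n = 6),
    class = "hmm_fit"
  )
  p <- viterbi_decode(fit, rep(0.5, 6))
  expect_equal(p$state, rep(1L, 6))
})

test_that("noiseless decoding reproduces the generating path", {
  s <- two_state_scheme(k12 = 2, k21 = 2, means = c(0.4, 0.8))
  # segment boundaries on exact frame edges so no frame is mixed
  path <- manual_path(c("hi", "lo", "hi", "lo"), c(0, 0.5, 1.5, 2.0, 3.0))
  tr <- render_trace(path, s, noiseless_emission())
  f <- compute_fret(tr, smooth = FALSE)
  fit <- fit_hmm(f, K = 2)
  p <- viterbi_decode(fit, f)
  truth <- c(rep(2L, 15), rep(1L, 30), rep(2L, 15), rep(1L, 30))
  expect_equal(p$state, truth)
})

test_that("sub-0.1 FRET states merge and the merge is idempotent", {
  p <- manual_ipath(c(1, 1, 2, 2, 3, 3, 1), means = c(0.50, 0.65, 0.70))
  m1 <- exclude_for_kinetics(p)
  # 0.65 and 0.70 differ by < 0.1 and fuse into one occupancy-weighted state
  expect_length(m1$state_mean, 2)
  expect_equal(m1$state_mean[2], (0.65 * 2 + 0.70 * 2) / 4)
  expect_equal(m1$state, c(1L, 1L, 2L, 2L, 2L, 2L, 1L))
  m2 <- exclude_for_kinetics(m1)
  expect_equal(m2$state, m1$state)
  expect_equal(m2$state_mean, m1$state_mean)

  # transition counting after merging drives kinetic eligibility
  expect_true(m1$kinetic_eligible)    # lo-hi-lo: 2 transitions
  static <- exclude_for_kinetics(manual_ipath(rep(1, 5), means = 0.7))
  expect_false(static$kinetic_eligible)
  expect_equal(static$n_transitions, 0)
  single <- exclude_for_kinetics(manual_ipath(c(1, 1, 2, 2), means = c(0.5, 0.7)))
  expect_false(single$kinetic_eligible)  # one transition is excluded too
})

test_that("dwell extraction yields durations, censoring and conservation", {
  p <- manual_ipath(c(2, 2, 2, 1, 1, 2), means = c(0.52, 0.73))
  dw <- extract_dwells(p, frame_rate = 30)
  expect_equal(nrow(dw), 3)
  expect_equal(dw$n_frames, c(3, 2, 1))
  expect_equal(dw$duration_s, c(3, 2, 1) / 30, tolerance = 1e-12)
  expect_equal(dw$censored_left, c(TRUE, FALSE, FALSE))
  expect_equal(dw$censored_right, c(FALSE, FALSE, TRUE))
  expect_equal(dw$end_cause, c("transition", "transition", "trace_end"))
  # frame conservation: dwell frames sum to the path length
  expect_equal(sum(dw$n_frames), length(p$state))

  # single-state path: one fully censored dwell
  one <- extract_dwells(manual_ipath(rep(1, 7), means = 0.7,
                                     end_cause = "bleach"), 30)
  expect_equal(nrow(one), 1)
  expect_true(one$censored_left & one$censored_right)
  expect_equal(one$end_cause, "bleach")
})

test_that("decoded transition count approaches truth as noise vanishes", {
  s <- two_state_scheme(k12 = 1.5, k21 = 1.5, means = c(0.45, 0.75))
  path <- sample_state_path(s, 20, seed = 13)
  n_true <- nrow(path$segments) - 1
  counts <- vapply(c(60, 25, 5), function(nsd) {
    em <- emission_model(noise_sd_donor = nsd, noise_sd_acceptor = nsd,
                         bleach_rate_donor = 0, bleach_rate_acceptor = 0)
    tr <- render_trace(path, s, em, seed = 21)
    f <- compute_fret(correct_bleedthrough(tr, 0.13), smooth = FALSE)
    p <- viterbi_decode(fit_hmm(f, K = 2), f)
    p$n_transitions
  }, numeric(1))
  expect_lte(abs(counts[3] - n_true), 1)
  expect_lte(abs(counts[2] - n_true), abs(counts[1] - n_true) + 2)
})
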