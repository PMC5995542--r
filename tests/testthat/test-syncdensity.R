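test_that("synchronization finds the requested kinetic feature", {
  # binding trace: dark (mean ~0) then bound at frame 37
  p <- manual_ipath(c(rep(1, 37), rep(2, 23)), means = c(0.02, 0.62))
  s <- synchronize_traces(list(p), "fret_event_start")
  expect_equal(s$sync_frames, 37L)
  expect_equal(s$n_excluded, 0)

  # trace already starting in the feature is unchanged (t = 0)
  p0 <- manual_ipath(rep(2, 10), means = c(0.02, 0.62))
  expect_equal(synchronize_traces(list(p0), "fret_event_start")$sync_frames, 0L)

  # static low trace lacks the feature and is excluded but tallied
  pstat <- manual_ipath(rep(1, 10), means = c(0.02, 0.62))
  s2 <- synchronize_traces(list(p, pstat), "fret_event_start")
  expect_true(is.na(s2$sync_frames[2]))
  expect_equal(s2$n_excluded, 1)

  # first transition from the high- to the low-FRET state
  rot <- manual_ipath(c(2, 2, 1, 1, 2, 1), means = c(0.52, 0.73))
  expect_equal(synchronize_traces(list(rot), "first_hi_to_lo")$sync_frames, 2L)
  # first transition into the state nearest a target mean
  expect_equal(
    synchronize_traces(list(rot), "first_transition_to",
                       target_mean = 0.73)$sync_frames, 4L)
  expect_error(synchronize_traces(list(rot), "no_such_mode"))
})

test_that("density maps are column-normalized indicator histograms", {
  f <- manual_fret(c(rep(0.3, 5), rep(0.7, 5)))
  dm <- density_map(list(f), sync_frames = 0L, frame_rate = 30,
                    t_max = 10 / 30)
  expect_equal(dim(dm$density), c(60, 10))
  cs <- colSums(dm$density)
  expect_true(all(abs(cs - 1) < 1e-9))  # every populated column sums to 1
  # single noiseless trace: each column is an indicator
  expect_true(all(apply(dm$density, 2, max) == 1))
  expect_error(density_map(list(f), sync_frames = NA_integer_), "no synchronized")
})

test_that("density mapping has no directional bias (time reversal)", {
  set.seed(31)
  fs <- lapply(1:6, function(i) manual_fret(runif(40, 0, 1)))
  rev_fs <- lapply(fs, function(f) manual_fret(rev(f$fret)))
  dm <- density_map(fs, sync_frames = rep(0L, 6), frame_rate = 30,
                    t_max = 40 / 30)
  dmr <- density_map(rev_fs, sync_frames = rep(0L, 6), frame_rate = 30,
                     t_max = 40 / 30)
  expect_equal(dmr$counts, dm$counts[, ncol(dm$counts):1])
})

test_that("post-sync histogram equals the pooled post-sync samples", {
  set.seed(32)
  fs <- lapply(1:8, function(i) manual_fret(runif(60, 0, 1)))
  sync <- c(3L, 10L, 0L, NA, 25L, 7L, 40L, 12L)
  M <- 20
  dm <- density_map(fs, sync_frames = sync, frame_rate = 30,
                    t_max = M / 30)
  pooled <- collect_fret_samples(fs, "post_sync", M = M, sync_frames = sync)
  h <- hist(pooled, breaks = dm$fret_breaks, plot = FALSE)
  expect_equal(rowSums(dm$counts), h$counts)
})

test_that("column-mean FRET decays at the dissociation rate", {
  # synchronized binding traces lose FRET signal at k_off + k_bleach; the
  # fraction of traces still bound at t after sync decays exponentially
  res <- NULL
  fx <- scenario_fixture("l11_rf3_rf1gaq")
  ts <- simulate_scenario(fx, 150, seed = 33)
  sel <- select_traces(ts, beta = 0.13, check_acceptor_steps = FALSE)
  frets <- list(); paths <- list()
  for (i in sel$accepted) {
    tr <- correct_bleedthrough(ts$traces[[i]], 0.13)
    f <- compute_fret(tr, mask = sel$masks[[i]], smooth = FALSE)
    if (sum(f$valid) < 6) next
    fit <- tryCatch(fit_hmm(f, K = 2), error = function(e) NULL)
    if (is.null(fit)) next
    frets[[length(frets) + 1]] <- f
    paths[[length(paths) + 1]] <- viterbi_decode(fit, f)
  }
  sync <- synchronize_traces(paths, "fret_event_start")
  dm <- density_map(frets, sync$sync_frames, frame_rate = 30, t_max = 4)
  cm <- density_column_mean(dm)
  t <- dm$time_mid

  # the column mean starts at the bound FRET level and relaxes toward the
  # dark/equilibrium level with the two-state relaxation rate
  # k_on + k_off = 0.5 + 1.3 1/s (half time log(2)/1.8 = 0.39 s)
  expect_lt(abs(max(cm[1:3]) - 0.51), 0.08)
  lvl_inf <- mean(cm[t > 3])
  expect_lt(lvl_inf, 0.2)
  y <- (cm - lvl_inf) / (max(cm[1:3]) - lvl_inf)
  t_half <- t[which(y < 0.5)[1]]
  expect_gt(t_half, 0.5 * log(2) / 1.8)
  expect_lt(t_half, 1.7 * log(2) / 1.8)
})
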