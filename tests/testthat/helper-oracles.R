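# Shared builders and independent oracles for the test suite.

noiseless_emission <- function(beta = 0, I = 1000, bg_d = 0, bg_a = 0) {
  emission_model(
    total_intensity = I, noise_sd_donor = 0, noise_sd_acceptor = 0,
    background_donor = bg_d, background_acceptor = bg_a,
    bleedthrough_beta = beta, bleach_rate_donor = 0, bleach_rate_acceptor = 0
  )
}

two_state_scheme <- function(k12 = 1, k21 = 1, means = c(0.5, 0.7),
                             dark = character(), initial = NULL) {
  kinetic_scheme(
    state_ids = c("lo", "hi"), fret_mean = means, fret_sd = c(0.05, 0.05),
    rates = matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE),
    dark_states = dark, initial_probs = initial
  )
}

# build a state_path with segment boundaries on exact times
manual_path <- function(states, breaks, bleach_d = Inf, bleach_a = Inf) {
  stopifnot(length(breaks) == length(states) + 1)
  structure(
    list(
      segments = data.frame(
        state = states,
        t_start = breaks[-length(breaks)],
        t_end = breaks[-1],
        stringsAsFactors = FALSE
      ),
      duration = breaks[length(breaks)],
      bleach_time_donor = bleach_d,
      bleach_time_acceptor = bleach_a
    ),
    class = "state_path"
  )
}

manual_ipath <- function(states, means, frame_rate = 30,
                         end_cause = "trace_end", sds = NULL) {
  structure(
    list(
      state = as.integer(states),
      frame = seq_along(states) - 1L,
      state_mean = means,
      state_sd = if (is.null(sds)) rep(0.05, length(means)) else sds,
      frame_rate = frame_rate,
      n_transitions = sum(diff(states) != 0),
      end_cause = end_cause
    ),
    class = "idealized_path"
  )
}

manual_fret <- function(values, valid = NULL, frame_rate = 30,
                        bleach_masked = FALSE) {
  structure(
    list(
      fret = values,
      valid = if (is.null(valid)) rep(TRUE, length(values)) else valid,
      frame_rate = frame_rate,
      bleach_masked = bleach_masked
    ),
    class = "fret_series"
  )
}

# exhaustive maximum a posteriori path: enumerates every K^T state sequence
# and scores it under the HMM; ties broken toward the lexicographically
# smallest path (lowest state indices first)
brute_force_viterbi <- function(x, mean, sd, transmat, init) {
  K <- length(mean)
  T_ <- length(x)
  logB <- vapply(seq_len(K), function(k) dnorm(x, mean[k], sd[k], log = TRUE),
                 numeric(T_))
  dim(logB) <- c(T_, K)
  logA <- log(transmat)
  logpi <- log(init)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  score <- logpi[paths[, 1]] + logB[cbind(1, paths[, 1])]
  if (T_ > 1) {
    for (t in 2:T_) {
      score <- score + logA[cbind(paths[, t - 1], paths[, t])] +
        logB[cbind(t, paths[, t])]
    }
  }
  # lexicographic order among ties: sort paths so the smallest-index path
  # comes first, then take the first maximiser
  ord <- do.call(order, as.data.frame(paths))
  paths <- paths[ord, , drop = FALSE]
  score <- score[ord]
  best <- which(score >= max(score) - 1e-9)[1]
  as.integer(paths[best, ])
}
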