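#' Sample an exact-event continuous-time Markov state path
#'
#' Draws one realisation of the conformational (or binding) dynamics encoded
#' in a [kinetic_scheme()] by the Gillespie algorithm: the sojourn in state
#' `i` is exponential with the state's total exit rate and the next state is
#' chosen with probability proportional to the outgoing rate constants. A
#' state with zero exit rate is absorbing (the path simply stays there until
#' `duration`).
#'
#' @param scheme a [kinetic_scheme()].
#' @param duration trace duration in seconds (> 0).
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `state_path`: a list with `segments` (a
#'   data.frame with columns `state`, `t_start`, `t_end` covering
#'   `[0, duration]` contiguously), `duration`, and bleach times
#'   `bleach_time_donor` / `bleach_time_acceptor` (both `Inf` until an
#'   emission model draws them, see [simulate_scenario()]).
#' @examples
#' fx <- scenario_fixture("posthc_s6l9")
#' p <- sample_state_path(fx$schemes[[1]], duration = 10, seed = 1)
#' head(p$segments)
#' @export
sample_state_path <- function(scheme, duration, seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)

  K <- length(scheme$state_ids)
  exit_rates <- rowSums(scheme$rates)
  state <- sample.int(K, 1, prob = scheme$initial_probs)

  states <- integer(0)
  t_start <- numeric(0)
  t_end <- numeric(0)
  t <- 0
  while (t < duration) {
    lam <- exit_rates[state]
    dwell <- if (lam > 0) rexp(1, lam) else Inf
    tn <- min(t + dwell, duration)
    states <- c(states, state)
    t_start <- c(t_start, t)
    t_end <- c(t_end, tn)
    t <- tn
    if (t >= duration) break
    state <- sample.int(K, 1, prob = scheme$rates[state, ])
  }

  structure(
    list(
      segments = data.frame(
        state = scheme$state_ids[states],
        t_start = t_start,
        t_end = t_end,
        stringsAsFactors = FALSE
      ),
      duration = duration,
      bleach_time_donor = Inf,
      bleach_time_acceptor = Inf
    ),
    class = "state_path"
  )
}

# Exact occupancy-weighted mean FRET per frame. E(t) is piecewise constant
# over the path segments (dark states emit E = 0); each frame's value is the
# time integral of E over the frame divided by the frame length, computed
# from the cumulative integral at frame edges.
frame_mean_fret <- function(path, scheme, n_frames, dt) {
  e_state <- scheme$fret_mean
  e_state[scheme$state_ids %in% scheme$dark_states] <- 0
  seg_state <- match(path$segments$state, scheme$state_ids)
  seg_e <- e_state[seg_state]
  t0 <- path$segments$t_start
  t1 <- path$segments$t_end
  cum <- c(0, cumsum(seg_e * (t1 - t0)))
  edges <- (0:n_frames) * dt
  # integral of E from 0 to each frame edge
  idx <- findInterval(edges, t0, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  idx[idx > length(t0)] <- length(t0)
  integral <- cum[idx] + seg_e[idx] * pmax(pmin(edges, t1[idx]) - t0[idx], 0)
  diff(integral) / dt
}

#' Render a state path into a two-channel fluorescence trace
#'
#' Converts a hidden [sample_state_path()] into donor/acceptor photon counts
#' per frame. Each frame carries the occupancy-weighted mean FRET efficiency
#' of the states visited during the frame (exact time integration, which
#' reproduces the frame-averaging blur of camera-based recordings). Before
#' photobleaching, `donor = I_tot * (1 - E) + bg_D` and
#' `acceptor = I_tot * E + beta * I_tot * (1 - E) + bg_A`, plus Gaussian
#' channel noise. After the acceptor bleaches the full intensity returns to
#' the donor (`donor = I_tot + bg_D`, acceptor shows only background plus
#' donor bleed-through); after the donor bleaches both channels fall to
#' background. Bleaching takes effect from the frame containing the bleach
#' time onwards.
#'
#' @param path a `state_path` (its bleach-time fields are honoured).
#' @param scheme the [kinetic_scheme()] that generated the path.
#' @param emission an [emission_model()].
#' @param frame_rate frames per second (default 30).
#' @param seed optional integer seed for the channel noise.
#' @return An object of class `fret_trace`: list with `frame` (0-based),
#'   `time_s`, `donor`, `acceptor`, `frame_rate`, `meta` and `truth`
#'   (the generating path and scheme).
#' @export
render_trace <- function(path, scheme, emission, frame_rate = 30, seed = NULL) {
  stopifnot(inherits(path, "state_path"), inherits(emission, "emission_model"))
  if (frame_rate <= 0) stop("frame_rate must be positive")
  dt <- 1 / frame_rate
  n_frames <- floor(path$duration * frame_rate + 1e-9)
  if (n_frames < 1) stop("path must cover at least one frame")
  if (!is.null(seed)) set.seed(seed)

  e_bar <- frame_mean_fret(path, scheme, n_frames, dt)
  I <- emission$total_intensity
  beta <- emission$bleedthrough_beta

  donor <- I * (1 - e_bar)
  acceptor <- I * e_bar + beta * donor

  # photobleaching: the frame containing the bleach time and all later
  # frames show the bleached signal
  bf_d <- floor(path$bleach_time_donor * frame_rate + 1e-6)
  bf_a <- floor(path$bleach_time_acceptor * frame_rate + 1e-6)
  idx <- 0:(n_frames - 1)
  a_bleached <- idx >= bf_a
  d_bleached <- idx >= bf_d
  donor[a_bleached & !d_bleached] <- I
  acceptor[a_bleached & !d_bleached] <- beta * I
  donor[d_bleached] <- 0
  acceptor[d_bleached] <- 0

  donor <- donor + emission$background_donor
  acceptor <- acceptor + emission$background_acceptor
  if (emission$noise_sd_donor > 0) {
    donor <- donor + rnorm(n_frames, 0, emission$noise_sd_donor)
  }
  if (emission$noise_sd_acceptor > 0) {
    acceptor <- acceptor + rnorm(n_frames, 0, emission$noise_sd_acceptor)
  }

  structure(
    list(
      frame = idx,
      time_s = idx / frame_rate,
      donor = donor,
      acceptor = acceptor,
      frame_rate = frame_rate,
      meta = list(),
      truth = list(path = path, scheme = scheme, emission = emission,
                   mean_fret = e_bar)
    ),
    class = "fret_trace"
  )
}

#' @export
print.fret_trace <- function(x, ...) {
  cat("fret_trace:", length(x$frame), "frames at", x$frame_rate, "frames/s\n")
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Per-trace seed derivation: one global seed plus a counter, kept < 2^31.
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 1009) %% 2147483629
}

#' Simulate a full set of traces from a named scenario
#'
#' Draws `n_traces` traces from a [scenario_fixture()]: subpopulation
#' membership is sampled from the fixture's mixture weights, a state path is
#' sampled per trace, photobleaching times are drawn for each dye from the
#' emission model, and the trace is rendered with channel noise. The result
#' is fully reproducible from `seed` (per-trace seeds are derived from the
#' global seed via a counter).
#'
#' @param fixture a [scenario_fixture()] object or scenario name.
#' @param n_traces number of traces (`>= 0`).
#' @param seed integer seed.
#' @param duration trace duration in seconds; defaults to the fixture's.
#' @param frame_rate frames per second (default 30).
#' @return An object of class `trace_set`: list with `traces` (list of
#'   `fret_trace`) and `manifest` (scenario name, seed, frame rate, emission
#'   parameters, and per-trace truth: subpopulation, seed, bleach times and
#'   state segments).
#' @examples
#' ts <- simulate_scenario("prehc_s6l9", n_traces = 3, seed = 7, duration = 5)
#' length(ts$traces)
#' @export
simulate_scenario <- function(fixture, n_traces, seed, duration = NULL,
                              frame_rate = 30) {
  if (is.character(fixture)) fixture <- scenario_fixture(fixture)
  stopifnot(inherits(fixture, "scenario_fixture"))
  if (n_traces < 0) stop("n_traces must be >= 0")
  if (is.null(duration)) duration <- fixture$duration

  set.seed(seed)
  subpop <- if (n_traces > 0) {
    sample.int(length(fixture$weights), n_traces,
               replace = TRUE, prob = fixture$weights)
  } else {
    integer(0)
  }

  em <- fixture$emission
  traces <- vector("list", n_traces)
  truth <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    si <- derive_seed(seed, i)
    scheme <- fixture$schemes[[subpop[i]]]
    path <- sample_state_path(scheme, duration, seed = si)
    path$bleach_time_donor <- if (em$bleach_rate_donor > 0) {
      rexp(1, em$bleach_rate_donor)
    } else {
      Inf
    }
    path$bleach_time_acceptor <- if (em$bleach_rate_acceptor > 0) {
      rexp(1, em$bleach_rate_acceptor)
    } else {
      Inf
    }
    tr <- render_trace(path, scheme, em, frame_rate = frame_rate)
    tr$meta <- list(scenario = fixture$name, trace_id = i, seed = si,
                    subpopulation = subpop[i])
    traces[[i]] <- tr
    truth[[i]] <- list(
      trace_id = i, seed = si, subpopulation = subpop[i],
      bleach_time_donor = path$bleach_time_donor,
      bleach_time_acceptor = path$bleach_time_acceptor,
      segments = path$segments
    )
  }

  structure(
    list(
      traces = traces,
      manifest = list(
        scenario = fixture$name,
        seed = seed,
        n_traces = n_traces,
        duration = duration,
        frame_rate = frame_rate,
        weights = fixture$weights,
        emission = unclass(em),
        truth = truth
      )
    ),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat("trace_set: ", length(x$traces), " traces from scenario '",
      x$manifest$scenario, "' (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate a trace set doped with molecular aggregates
#'
#' Builds a quality-control challenge set: a fraction of the traces are
#' "aggregates" formed by summing the channels of two independent molecules
#' and multiplying both channels by a common intensity flicker. Aggregates
#' therefore show roughly doubled total intensity and positively correlated
#' channels, the two signatures the trace selection rules must reject.
#'
#' @param fixture scenario fixture or name.
#' @param n_traces total number of traces.
#' @param frac_aggregate fraction of aggregate traces (default 0.2).
#' @param seed integer seed.
#' @param flicker_sd sd of the shared relative intensity fluctuation.
#' @param ... passed to [simulate_scenario()].
#' @return A `trace_set`; the manifest gains an `is_aggregate` logical.
#' @export
simulate_doped_set <- function(fixture, n_traces, frac_aggregate = 0.2,
                               seed = 1, flicker_sd = 0.15, ...) {
  n_agg <- round(n_traces * frac_aggregate)
  n_single <- n_traces - n_agg
  ts <- simulate_scenario(fixture, n_single + 2 * n_agg, seed = seed, ...)
  set.seed(derive_seed(seed, 999983))
  out <- ts$traces[seq_len(n_single)]
  is_agg <- rep(FALSE, n_single)
  for (j in seq_len(n_agg)) {
    a <- ts$traces[[n_single + 2 * j - 1]]
    b <- ts$traces[[n_single + 2 * j]]
    flick <- 1 + rnorm(length(a$frame), 0, flicker_sd)
    agg <- a
    agg$donor <- (a$donor + b$donor) * flick
    agg$acceptor <- (a$acceptor + b$acceptor) * flick
    agg$meta$aggregate <- TRUE
    out[[n_single + j]] <- agg
    is_agg <- c(is_agg, TRUE)
  }
  ts$traces <- out
  ts$manifest$n_traces <- n_traces
  ts$manifest$truth <- ts$manifest$truth[seq_len(n_single)]
  ts$manifest$is_aggregate <- is_agg
  ts
}
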