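#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, checks threshold ranges and resolves the
#' scenario name before any computation. Units are seconds and 1/s
#' throughout; the recording rate defaults to 30 frames/s.
#'
#' @param config named list; recognised fields (with defaults):
#'   `scenario` (required), `n_traces` (300), `n_replicates` (3), `seed`
#'   (1), `duration` (scenario default), `frame_rate` (30), `beta`
#'   (`"auto"`: estimate from post-acceptor-bleach segments, falling back
#'   to 0.13), `corr_thresh` (0.1), `merge_de` (0.1), `K` (number of states
#'   of the scenario scheme), `t_min` (`"one_frame"`: the minimum
#'   detectable dwell, also used as decoder dead time for
#'   [correct_missed_events()]), `n_exp` (`"auto"`),
#'   `sync_M` (20), `fret_on` (0.25), `detection_limit` (0.2), `k_bleach`
#'   (`"calibrate"` for binding scenarios: estimate from simulated static
#'   calibration traces; or numeric; or `NA` to skip correction),
#'   `n_calibration` (200), `intensity_band` (`c(0.5, 1.5)`),
#'   `min_transitions` (2 for conformational, 1 for binding).
#' @return the completed configuration (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.null(config$scenario)) stop("config$scenario is required")
  fx <- scenario_fixture(config$scenario)  # errors on unknown scenario

  defaults <- list(
    n_traces = 300,
    n_replicates = 3,
    seed = 1,
    duration = fx$duration,
    frame_rate = 30,
    beta = "auto",
    corr_thresh = 0.1,
    merge_de = 0.1,
    K = length(fx$schemes[[1]]$state_ids),
    t_min = "one_frame",
    n_exp = "auto",
    sync_M = 20,
    fret_on = 0.25,
    detection_limit = 0.2,
    k_bleach = if (fx$kind == "binding") "calibrate" else NA_real_,
    n_calibration = 200,
    intensity_band = c(0.5, 1.5),
    min_transitions = if (fx$kind == "binding") 1 else 2
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  unknown <- setdiff(names(config), c("scenario", names(defaults)))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }

  with(config, {
    if (n_traces < 1) stop("n_traces must be >= 1")
    if (n_replicates < 1) stop("n_replicates must be >= 1")
    if (frame_rate <= 0) stop("frame_rate must be positive")
    if (duration <= 0) stop("duration must be positive")
    if (corr_thresh < -1 || corr_thresh > 1) {
      stop("corr_thresh must lie in [-1, 1]")
    }
    if (!identical(beta, "auto") && (beta < 0 || beta >= 1)) {
      stop("beta must be 'auto' or lie in [0, 1)")
    }
    if (merge_de < 0 || merge_de > 1) stop("merge_de must lie in [0, 1]")
    if (sync_M < 1 || sync_M > 100) stop("sync_M must lie in [1, 100]")
    if (!identical(n_exp, "auto") && !n_exp %in% c(1, 2)) {
      stop("n_exp must be 'auto', 1 or 2")
    }
  })
  if (identical(config$t_min, "one_frame")) {
    config$t_min <- 1 / config$frame_rate
  }
  structure(config, class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated scenario
#'
#' Orchestrates simulate -> trace QC -> idealization -> population and
#' kinetic analysis over independent replicate datasets (three by default,
#' each a separately seeded simulation standing in for an independent
#' experimental dataset), and aggregates every reported quantity as mean
#' plus-or-minus sample sd over replicates. Deterministic given the
#' configuration seed.
#'
#' Stages per replicate: [simulate_scenario()];
#' [estimate_bleedthrough()] (if `beta = "auto"`) and [select_traces()];
#' [compute_fret()] with bleach masking; [fit_hmm()] + [viterbi_decode()]
#' + [exclude_for_kinetics()]; [fit_gmm()] on pooled FRET values
#' (steady-state pooling for conformational scenarios, post-synchronization
#' pooling of bound-state frames for binding scenarios);
#' [fit_dwell_exponential()] / [fit_dwell_mixture_traces()] on the dwell
#' tables, with photobleaching correction of binding dissociation rates via
#' [correct_koff()].
#'
#' @param config a list accepted by [validate_config()].
#' @return object of class `pipeline_result`: `rates` (aggregated rate
#'   table), `populations` (aggregated Gaussian components),
#'   `dynamic_fraction`, `qc` (per-replicate acceptance counts),
#'   `replicates` (per-replicate detail), `config`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(scenario = "posthc_s6l9", n_traces = 40,
#'                          n_replicates = 2, duration = 10, seed = 42))
#' res$populations
#' }
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  fx <- scenario_fixture(config$scenario)
  seeds <- vapply(seq_len(config$n_replicates),
                  function(r) derive_seed(config$seed, 7919 * r),
                  numeric(1))

  reps <- lapply(seq_along(seeds), function(r) {
    pipeline_replicate(fx, config, seeds[r], r)
  })

  rates <- aggregate_rate_tables(reps)
  pops <- aggregate_population_tables(reps)
  dyn <- data.frame(
    fraction = mean(vapply(reps, function(x) x$dynamic$fraction, numeric(1))),
    sd = sd(vapply(reps, function(x) x$dynamic$fraction, numeric(1)))
  )
  qc <- do.call(rbind, lapply(seq_along(reps), function(r) {
    data.frame(replicate = r, seed = seeds[r],
               n_traces = config$n_traces,
               n_accepted = reps[[r]]$n_accepted,
               n_kinetic = reps[[r]]$n_kinetic,
               beta_hat = reps[[r]]$beta)
  }))

  structure(
    list(
      scenario = config$scenario,
      rates = rates,
      populations = pops,
      dynamic_fraction = dyn,
      qc = qc,
      replicates = reps,
      config = config
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result for scenario '", x$scenario, "' (",
      length(x$replicates), " replicates x ", x$config$n_traces,
      " traces)\n\n", sep = "")
  cat("FRET populations (mean over replicates):\n")
  print(x$populations, row.names = FALSE)
  cat("\nRate constants:\n")
  print(x$rates, row.names = FALSE)
  cat("\nDynamic traces:", sprintf("%.2f", x$dynamic_fraction$fraction), "\n")
  invisible(x)
}

pipeline_replicate <- function(fx, config, seed_r, rep_id) {
  binding <- fx$kind == "binding"
  ts <- simulate_scenario(fx, config$n_traces, seed = seed_r,
                          duration = config$duration,
                          frame_rate = config$frame_rate)

  beta <- if (identical(config$beta, "auto")) {
    tryCatch(estimate_bleedthrough(ts)$beta_hat, error = function(e) 0.13)
  } else {
    config$beta
  }

  sel <- select_traces(ts, beta = beta, corr_thresh = config$corr_thresh,
                       intensity_band = config$intensity_band,
                       check_acceptor_steps = !binding)

  frets <- list()
  frets_smooth <- list()
  paths <- list()
  used <- integer(0)
  for (i in sel$accepted) {
    tr <- correct_bleedthrough(ts$traces[[i]], beta)
    # idealization runs on unsmoothed FRET: the three-point smoother
    # correlates noise across frames and hides one-frame dwells, biasing
    # dwell times upward; smoothed series are kept for the population
    # histograms, where averaging sharpens the state peaks instead
    f <- compute_fret(tr, mask = sel$masks[[i]], smooth = FALSE)
    if (sum(f$valid) < 2 * config$K + 2) next
    fit <- tryCatch(fit_hmm(f, K = config$K), error = function(e) NULL)
    if (is.null(fit)) next
    p <- viterbi_decode(fit, f)
    p <- exclude_for_kinetics(p, merge_de = config$merge_de,
                              min_transitions = config$min_transitions)
    used <- c(used, i)
    frets[[length(frets) + 1]] <- f
    frets_smooth[[length(frets_smooth) + 1]] <-
      compute_fret(tr, mask = sel$masks[[i]], smooth = TRUE)
    paths[[length(paths) + 1]] <- p
  }
  if (length(paths) == 0) stop("no analyzable traces in replicate ", rep_id)

  dyn <- dynamic_fraction(paths)
  state_names <- fx$schemes[[1]]$state_ids
  nominal <- fx$schemes[[1]]$fret_mean
  nominal[state_names %in% fx$schemes[[1]]$dark_states] <- 0

  # --- populations ---
  if (binding) {
    sync <- synchronize_traces(paths, "fret_event_start",
                               fret_on = config$fret_on)
    bound_frets <- mask_to_bound(frets, paths, config$fret_on)
    values <- collect_fret_samples(bound_frets, "post_sync",
                                   M = config$sync_M,
                                   sync_frames = sync$sync_frames)
    n_comp <- 1
  } else {
    sync <- NULL
    values <- collect_fret_samples(frets_smooth, "steady_state")
    n_comp <- config$K
  }
  # initialize the mixture at the median fitted HMM state means: on
  # fast-exchange data frame averaging adds intermediate density that can
  # otherwise capture a component
  init_means <- if (!binding && n_comp >= 2 && length(paths) >= 5) {
    km <- t(vapply(paths, function(p) {
      m <- sort(p$state_mean)
      c(m, rep(m[length(m)], n_comp - length(m)))[seq_len(n_comp)]
    }, numeric(n_comp)))
    apply(km, 2, stats::median)
  } else {
    NULL
  }
  gmm <- tryCatch(fit_gmm(values, n_comp, init_means = init_means),
                  error = function(e) NULL)
  pop <- if (is.null(gmm)) {
    data.frame(component = integer(0), mean = numeric(0), sd = numeric(0),
               p = numeric(0))
  } else {
    data.frame(component = seq_along(gmm$mean), mean = gmm$mean,
               sd = gmm$sd, p = gmm$weight)
  }

  # --- kinetics ---
  eligible <- Filter(function(p) isTRUE(p$kinetic_eligible), paths)
  rates <- list()
  n_dwells_used <- 0
  if (length(eligible) > 0) {
    dw <- bind_dwells(lapply(seq_along(eligible), function(j) {
      extract_dwells(eligible[[j]], frame_rate = config$frame_rate,
                     trace_id = j)
    }))
    dw$label <- state_names[
      vapply(dw$state_mean, function(m) which.min(abs(nominal - m)),
             integer(1))
    ]
    if (binding) {
      # an apparent FRET-loss event may be dissociation or dye bleaching;
      # only survival to the end of the recording is censored
      dw$censored_right <- dw$censored_right & dw$end_cause == "trace_end"
      rates <- binding_rates(dw, fx, config, seed_r)
    } else {
      rates <- conformational_rates(dw, fx, config, state_names)
    }
    n_dwells_used <- nrow(dw)
  }

  list(
    seed = seed_r,
    beta = beta,
    n_accepted = length(sel$accepted),
    n_used = length(used),
    n_kinetic = length(eligible),
    n_dwells = n_dwells_used,
    population = pop,
    dynamic = dyn,
    rates = rates,
    sync_excluded = if (is.null(sync)) NA_integer_ else sync$n_excluded
  )
}

# restrict each fret series to frames decoded as a signal (non-dark) state;
# frames at segment edges are dropped (camera integration blends the frame
# spanning a binding or release event with the dark level)
mask_to_bound <- function(frets, paths, fret_on) {
  lapply(seq_along(frets), function(i) {
    f <- frets[[i]]
    p <- paths[[i]]
    on <- rep(FALSE, length(f$fret))
    sig <- p$state_mean[p$state] >= fret_on
    interior <- sig
    if (length(sig) > 1) {
      same_prev <- c(FALSE, p$state[-1] == p$state[-length(p$state)])
      same_next <- c(same_prev[-1], FALSE)
      interior <- sig & same_prev & same_next
    }
    on[p$frame + 1] <- interior
    f$valid <- f$valid & on
    f
  })
}

conformational_rates <- function(dw, fx, config, state_names) {
  other_name <- function(s) {
    others <- setdiff(state_names, s)
    if (length(others) == 1) others else "exit"
  }

  # per-state exponential model choice on the pooled dwells
  per_state <- list()
  for (s in unique(dw$label)) {
    rows <- dw$label == s & !dw$censored_left
    if (sum(rows) < 20) next
    durs <- dw$duration_s[rows]
    cens <- dw$censored_right[rows]
    n_exp <- config$n_exp
    if (identical(n_exp, "auto")) {
      sel <- select_exp_model(durations = durs, censored = cens,
                              t_min = config$t_min)
      n_exp <- sel$n_components
    }
    fit <- fit_dwell_exponential(durations = durs, censored = cens,
                                 t_min = config$t_min)
    per_state[[s]] <- list(n_exp = n_exp, raw = fit$rates, se = fit$se,
                           n = fit$n)
  }
  ss <- names(per_state)

  if (length(ss) == 2 &&
      any(vapply(per_state, function(p) p$n_exp, numeric(1)) == 2)) {
    # biphasic dynamics: a molecule's kinetic class (fast or slow) sets the
    # exit rates of both states, so classify whole traces on the joint
    # dwell evidence and report molecule fractions
    dwj <- dw
    dwj$state <- dwj$label
    mix <- fit_dwell_mixture_joint(dwj, ss, t_min = config$t_min)
    out <- list()
    rates <- mix$rates
    for (cls in 1:2) {
      kc <- correct_missed_events(rates[cls, 1], rates[cls, 2], config$t_min)
      rates[cls, ] <- kc
    }
    for (s_i in 1:2) {
      s <- ss[s_i]
      qname <- paste0("k_", s, "_to_", other_name(s))
      out[[paste0(qname, "_fast")]] <-
        rate_estimate(paste0(qname, "_fast"), rates[1, s_i],
                      n = per_state[[s]]$n)
      out[[paste0(qname, "_slow")]] <-
        rate_estimate(paste0(qname, "_slow"), rates[2, s_i],
                      n = per_state[[s]]$n)
    }
    out$fraction_fast <- rate_estimate("fraction_fast", mix$fraction_fast,
                                       n = mix$n_traces)
    return(out)
  }

  # monophasic: joint dead-time correction for alternating two-state
  # dynamics (a missed short sojourn in the partner state merges dwells)
  if (length(ss) == 2) {
    kc <- correct_missed_events(per_state[[ss[1]]]$raw,
                                per_state[[ss[2]]]$raw, config$t_min)
    per_state[[ss[1]]]$raw <- kc[1]
    per_state[[ss[2]]]$raw <- kc[2]
  }
  out <- list()
  for (s in ss) {
    ps <- per_state[[s]]
    qname <- paste0("k_", s, "_to_", other_name(s))
    out[[qname]] <- rate_estimate(qname, ps$raw, sd = ps$se, n = ps$n)
  }
  out
}

binding_rates <- function(dw, fx, config, seed_r) {
  out <- list()
  scheme <- fx$schemes[[1]]
  bound_name <- setdiff(scheme$state_ids, scheme$dark_states)[1]
  dark_name <- scheme$dark_states[1]

  k_bleach <- config$k_bleach
  if (identical(k_bleach, "calibrate")) {
    cal <- simulate_scenario(calibration_fixture(fx), config$n_calibration,
                             seed = derive_seed(seed_r, 333331),
                             frame_rate = config$frame_rate)
    k_bleach <- estimate_photobleach_rate(cal$traces)
  } else if (!is.na(k_bleach)) {
    k_bleach <- rate_estimate("k_bleach", k_bleach)
  } else {
    k_bleach <- NULL
  }

  rows_d <- dw$label == dark_name & !dw$censored_left
  fit_on <- NULL
  if (sum(rows_d) >= 20) {
    fit_on <- fit_dwell_exponential(
      durations = dw$duration_s[rows_d],
      censored = dw$censored_right[rows_d] | dw$end_cause[rows_d] == "bleach",
      t_min = config$t_min
    )
    out$k_on <- rate_estimate("k_on", fit_on$rates, sd = fit_on$se,
                              n = fit_on$n)
  }

  rows <- dw$label == bound_name & !dw$censored_left
  if (sum(rows) >= 20) {
    fit <- fit_dwell_exponential(durations = dw$duration_s[rows],
                                 censored = dw$censored_right[rows],
                                 t_min = config$t_min)
    k_obs <- fit$rates
    if (!is.null(fit_on)) {
      # missed short dark excursions merge consecutive binding events
      k_obs <- correct_missed_events(k_obs, fit_on$rates, config$t_min)[1]
    }
    out$k_off_obs <- rate_estimate("k_off_obs", k_obs, sd = fit$se,
                                   n = fit$n)
    if (!is.null(k_bleach)) {
      out$k_bleach <- k_bleach
      corr <- correct_koff(out$k_off_obs, k_bleach,
                           detection_limit = config$detection_limit)
      corr$n <- fit$n
      out$k_off <- corr
    }
  }
  out
}

# static single-state calibration scenario matched to a binding fixture's
# emission model and bound FRET level
calibration_fixture <- function(fx) {
  scheme <- fx$schemes[[1]]
  bound <- setdiff(scheme$state_ids, scheme$dark_states)[1]
  e <- scheme$fret_mean[match(bound, scheme$state_ids)]
  make_fixture(
    paste0(fx$name, "_bleach_cal"),
    list(kinetic_scheme(state_ids = "bound", fret_mean = e,
                        fret_sd = 0.05, rates = matrix(0, 1, 1))),
    1, "conformational", emission = fx$emission, duration = 30
  )
}

aggregate_rate_tables <- function(reps) {
  qnames <- unique(unlist(lapply(reps, function(r) names(r$rates))))
  if (length(qnames) == 0) {
    return(data.frame(quantity = character(0), mean = numeric(0),
                      sd = numeric(0), corrected = logical(0),
                      bound = logical(0), limit = numeric(0),
                      n_replicates = integer(0)))
  }
  rows <- lapply(qnames, function(q) {
    ests <- Filter(Negate(is.null), lapply(reps, function(r) r$rates[[q]]))
    agg <- aggregate_replicates(ests)
    data.frame(
      quantity = q, mean = agg$mean, sd = agg$sd,
      corrected = agg$corrected, bound = agg$bound, limit = agg$limit,
      n_replicates = length(ests)
    )
  })
  do.call(rbind, rows)
}

aggregate_population_tables <- function(reps) {
  pops <- lapply(reps, function(r) r$population)
  ncomp <- max(vapply(pops, nrow, integer(1)))
  if (ncomp == 0) {
    return(data.frame(component = integer(0), mean = numeric(0),
                      mean_sd = numeric(0), width = numeric(0),
                      p = numeric(0), p_sd = numeric(0)))
  }
  rows <- lapply(seq_len(ncomp), function(k) {
    ms <- vapply(pops, function(p) if (nrow(p) >= k) p$mean[k] else NA_real_,
                 numeric(1))
    ws <- vapply(pops, function(p) if (nrow(p) >= k) p$p[k] else NA_real_,
                 numeric(1))
    ss <- vapply(pops, function(p) if (nrow(p) >= k) p$sd[k] else NA_real_,
                 numeric(1))
    data.frame(
      component = k,
      mean = mean(ms, na.rm = TRUE),
      mean_sd = sd(ms[!is.na(ms)]),
      width = mean(ss, na.rm = TRUE),
      p = mean(ws, na.rm = TRUE),
      p_sd = sd(ws[!is.na(ws)])
    )
  })
  do.call(rbind, rows)
}
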