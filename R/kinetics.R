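#' Maximum-likelihood exponential fit of state dwell times
#'
#' Fits a one- or two-component exponential to the dwell times of one state,
#' the step that converts idealized traces into rate constants (`k` is the
#' inverse of the mean dwell). Right-censored dwells (ended by
#' photobleaching or the end of the recording) contribute survival terms,
#' and a minimum-detectable-dwell truncation correction (`t_min`) accounts
#' for sojourns too short to appear in a frame-sampled idealized trace:
#' all likelihood contributions are conditioned on the dwell exceeding
#' `t_min`.
#'
#' For a single component with censoring and truncation the MLE is the
#' closed form `k = n_uncensored / sum(d - t_min)`. The two-component
#' mixture is fitted numerically with seeded restarts; component rates are
#' reported fast-first with their amplitude fractions (fractions of dwells).
#'
#' @param dwells a `dwell_table` (see [extract_dwells()]).
#' @param state state to fit: integer label or `"all"`; alternatively a
#'   numeric vector of durations via `durations`/`censored`.
#' @param n_components 1 or 2.
#' @param t_min truncation threshold in seconds (minimum detectable dwell;
#'   use one frame for frame-sampled idealized dwells, 0 for continuous
#'   data).
#' @param durations,censored optional raw inputs overriding `dwells`:
#'   durations in seconds and a logical right-censoring flag.
#' @param drop_left_censored drop left-censored dwells (default `TRUE`;
#'   their start is unobserved so their length is not exponential).
#' @param min_n2 minimum number of dwells required for a two-component fit;
#'   below it the fit falls back to one component with a warning.
#' @return An object of class `exp_fit`: `rates` (1/s, fast first),
#'   `fractions`, `se` (per-rate standard errors), `loglik`, `bic`, `n`,
#'   `n_censored`, `n_components`, `forced_single`.
#' @examples
#' set.seed(1)
#' d <- rexp(500, 2)
#' fit <- fit_dwell_exponential(durations = d, censored = rep(FALSE, 500))
#' fit$rates
#' @export
fit_dwell_exponential <- function(dwells = NULL, state = "all",
                                  n_components = 1, t_min = 0,
                                  durations = NULL, censored = NULL,
                                  drop_left_censored = TRUE, min_n2 = 50) {
  if (is.null(durations)) {
    stopifnot(inherits(dwells, "dwell_table"))
    rows <- if (identical(state, "all")) rep(TRUE, nrow(dwells)) else dwells$state == state
    if (drop_left_censored) rows <- rows & !dwells$censored_left
    durations <- dwells$duration_s[rows]
    censored <- dwells$censored_right[rows]
  }
  if (is.null(censored)) censored <- rep(FALSE, length(durations))
  stopifnot(length(censored) == length(durations))
  keep <- is.finite(durations) & durations > 0
  durations <- durations[keep]
  censored <- censored[keep]
  n <- length(durations)
  if (n < 2) stop("insufficient dwells for an exponential fit (n = ", n, ")")
  n_unc <- sum(!censored)
  if (n_unc == 0) stop("all dwells are censored; no rate is identifiable")
  if (!n_components %in% c(1, 2)) stop("n_components must be 1 or 2")

  d <- pmax(durations - t_min, 1e-12)

  forced_single <- FALSE
  if (n_components == 2 && n < min_n2) {
    warning("fewer than ", min_n2,
            " dwells; falling back to a single exponential")
    n_components <- 1
    forced_single <- TRUE
  }

  if (n_components == 1) {
    k <- n_unc / sum(d)
    ll <- n_unc * log(k) - k * sum(d)
    return(structure(
      list(rates = k, fractions = 1, se = k / sqrt(n_unc),
           loglik = ll, bic = -2 * ll + 1 * log(n),
           n = n, n_censored = n - n_unc, n_components = 1L,
           forced_single = forced_single, t_min = t_min),
      class = "exp_fit"
    ))
  }

  nll <- function(par) {
    a <- plogis(par[1])
    k1 <- exp(par[2])
    k2 <- exp(par[3])
    # truncated mixture: all terms conditioned on d > 0 after shifting by
    # t_min, which for the shifted variable is just the plain mixture
    f <- a * k1 * exp(-k1 * d) + (1 - a) * k2 * exp(-k2 * d)
    S <- a * exp(-k1 * d) + (1 - a) * exp(-k2 * d)
    ll <- sum(log(pmax(ifelse(censored, S, f), 1e-300)))
    -ll
  }

  # frame-quantized dwells shifted by t_min pile up at zero; an unbounded
  # rate component would collapse onto that lattice point, so rates are
  # capped just below the sampling limit
  k_cap <- if (t_min > 0) 0.8 / t_min else 1e5
  km <- n_unc / sum(d)
  inits <- list(
    c(qlogis(0.5), log(km * 3), log(km / 3)),
    c(qlogis(0.7), log(km * 5), log(km / 2)),
    c(qlogis(0.3), log(km * 2), log(km / 5))
  )
  lower <- c(-6, log(1e-4), log(1e-4))
  upper <- c(6, log(k_cap), log(k_cap))
  best <- NULL
  for (p0 in inits) {
    p0 <- pmin(pmax(p0, lower + 1e-3), upper - 1e-3)
    opt <- tryCatch(
      optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("two-exponential fit failed to converge")
  a <- plogis(best$par[1])
  k <- exp(best$par[2:3])
  fr <- c(a, 1 - a)
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]
  fr <- fr[ord]
  ll <- -best$value
  # rough per-rate standard errors from effective counts per component
  se <- k / sqrt(pmax(fr * n_unc, 1))
  structure(
    list(rates = k, fractions = fr, se = se,
         loglik = ll, bic = -2 * ll + 3 * log(n),
         n = n, n_censored = n - n_unc, n_components = 2L,
         forced_single = FALSE, t_min = t_min),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(x$n_components, "-exponential dwell fit: n = ", x$n,
      " (", x$n_censored, " censored)\n", sep = "")
  print(data.frame(rate = round(x$rates, 4), fraction = round(x$fractions, 4),
                   se = round(x$se, 4)), row.names = FALSE)
  invisible(x)
}

#' Choose one vs two exponential dwell components by BIC
#'
#' Dwell-time distributions of mixed complexes are biphasic; this selects
#' the number of exponential components by comparing BIC of the one- and
#' two-component maximum-likelihood fits. With fewer than `min_n2` dwells a
#' single component is forced (flagged).
#'
#' @inheritParams fit_dwell_exponential
#' @return list with `n_components`, `fit`, `bic` (named vector), `forced`.
#' @export
select_exp_model <- function(dwells = NULL, state = "all", t_min = 0,
                             durations = NULL, censored = NULL,
                             min_n2 = 50, ...) {
  f1 <- fit_dwell_exponential(dwells, state, 1, t_min,
                              durations = durations, censored = censored, ...)
  if (f1$n < min_n2) {
    return(list(n_components = 1L, fit = f1,
                bic = c(`1` = f1$bic, `2` = NA_real_), forced = TRUE))
  }
  f2 <- fit_dwell_exponential(dwells, state, 2, t_min,
                              durations = durations, censored = censored,
                              min_n2 = min_n2, ...)
  # a biphasic call requires a non-degenerate mixture: both components
  # carry real weight, are kinetically distinct, and the fast rate stays
  # clear of the sampling-rate cap
  k_cap <- if (t_min > 0) 0.8 / t_min else 1e5
  degenerate <- min(f2$fractions) < 0.05 ||
    f2$rates[1] > 0.9 * k_cap ||
    f2$rates[1] / f2$rates[2] < 2
  if (!degenerate && f2$bic < f1$bic) {
    list(n_components = 2L, fit = f2, bic = c(`1` = f1$bic, `2` = f2$bic),
         forced = FALSE)
  } else {
    list(n_components = 1L, fit = f1, bic = c(`1` = f1$bic, `2` = f2$bic),
         forced = FALSE)
  }
}

#' Resolve kinetic subpopulations at the trace level
#'
#' When two kinetic subpopulations coexist, pooled dwell amplitudes
#' over-weight the fast population (fast molecules contribute more dwells
#' per trace). This two-level mixture EM assigns whole traces to a fast or
#' slow class -- dwells within a trace share one rate -- and therefore
#' reports the *fraction of molecules* in each class, the quantity quoted
#' for biphasic complexes.
#'
#' @param dwells a `dwell_table` with a `trace_id` column.
#' @param state state label to analyse.
#' @param t_min truncation threshold (s), as in [fit_dwell_exponential()].
#' @param max_iter,tol EM iteration cap and relative tolerance.
#' @return list with `rates` (fast, slow), `fraction_fast` (of molecules),
#'   `responsibilities` (per trace), `loglik`, `n_traces`.
#' @export
fit_dwell_mixture_traces <- function(dwells, state, t_min = 0,
                                     max_iter = 500, tol = 1e-8) {
  stopifnot(inherits(dwells, "dwell_table"))
  rows <- dwells$state == state & !dwells$censored_left
  d <- pmax(dwells$duration_s[rows] - t_min, 1e-12)
  cens <- dwells$censored_right[rows]
  id <- dwells$trace_id[rows]
  if (length(d) < 4) stop("too few dwells for a trace-level mixture")

  ids <- unique(id)
  # per-trace sufficient statistics for an exponential likelihood
  nunc <- vapply(ids, function(j) sum(id == j & !cens), numeric(1))
  S <- vapply(ids, function(j) sum(d[id == j]), numeric(1))

  pooled <- fit_dwell_exponential(durations = dwells$duration_s[rows],
                                  censored = cens,
                                  n_components = 2, t_min = t_min,
                                  min_n2 = 4)
  k <- pooled$rates
  phi <- 0.5
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    l1 <- log(phi) + nunc * log(k[1]) - k[1] * S
    l2 <- log(1 - phi) + nunc * log(k[2]) - k[2] * S
    m <- pmax(l1, l2)
    den <- m + log(exp(l1 - m) + exp(l2 - m))
    r <- exp(l1 - den)
    ll <- sum(den)
    if (!is.finite(ll)) break
    phi <- mean(r)
    phi <- min(max(phi, 1e-6), 1 - 1e-6)
    k1 <- sum(r * nunc) / sum(r * S)
    k2 <- sum((1 - r) * nunc) / sum((1 - r) * S)
    if (is.finite(k1) && k1 > 0) k[1] <- k1
    if (is.finite(k2) && k2 > 0) k[2] <- k2
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) break
    ll_prev <- ll
  }
  if (k[1] < k[2]) {
    k <- rev(k)
    r <- 1 - r
    phi <- 1 - phi
  }
  list(rates = k, fraction_fast = phi, responsibilities = r,
       loglik = ll, n_traces = length(ids))
}

#' Joint trace-level mixture over the dwells of both states
#'
#' Like [fit_dwell_mixture_traces()], but a trace's kinetic class (fast or
#' slow molecule) governs the exit rates of *both* states simultaneously, so
#' every dwell of the trace contributes classification evidence. This is
#' the appropriate model when two subpopulations differ in their entire
#' transition kinetics (e.g. fast ribosomes with k_N_to_R = 5.9 and
#' k_R_to_N = 2.9 1/s versus slow ones at 1.30 and 0.80 1/s), and it
#' sharply reduces the misclassification of slow molecules that happen to
#' show few dwells of one state.
#'
#' @param dwells a `dwell_table` whose `state` column holds the (merged,
#'   labelled) states; left-censored dwells are ignored.
#' @param states character or integer vector of the two states to use.
#' @param t_min truncation threshold (s).
#' @param max_iter,tol EM iteration cap and relative tolerance.
#' @return list with `rates` (2 x 2 matrix: rows fast/slow class, columns
#'   the two states), `fraction_fast` (of molecules), `responsibilities`
#'   (per trace), `loglik`, `n_traces`.
#' @export
fit_dwell_mixture_joint <- function(dwells, states, t_min = 0,
                                    max_iter = 500, tol = 1e-8) {
  stopifnot(inherits(dwells, "dwell_table"), length(states) == 2)
  rows <- dwells$state %in% states & !dwells$censored_left
  dd <- dwells[rows, ]
  d <- pmax(dd$duration_s - t_min, 1e-12)
  ids <- unique(dd$trace_id)
  nunc <- matrix(0, length(ids), 2)
  S <- matrix(0, length(ids), 2)
  for (s in 1:2) {
    for (j in seq_along(ids)) {
      sel <- dd$trace_id == ids[j] & dd$state == states[s]
      nunc[j, s] <- sum(sel & !dd$censored_right)
      S[j, s] <- sum(d[sel])
    }
  }

  # initialize from per-state pooled two-exponential fits (fast with fast)
  k <- matrix(0, 2, 2)
  for (s in 1:2) {
    f2 <- tryCatch(
      fit_dwell_exponential(durations = dd$duration_s[dd$state == states[s]],
                            censored = dd$censored_right[dd$state == states[s]],
                            n_components = 2, t_min = t_min, min_n2 = 4),
      error = function(e) NULL
    )
    if (is.null(f2)) {
      f1 <- fit_dwell_exponential(durations = dd$duration_s[dd$state == states[s]],
                                  censored = dd$censored_right[dd$state == states[s]],
                                  t_min = t_min)
      k[, s] <- c(f1$rates * 2, f1$rates / 2)
    } else {
      k[, s] <- f2$rates
    }
  }

  phi <- 0.5
  ll_prev <- -Inf
  r <- rep(0.5, length(ids))
  for (it in seq_len(max_iter)) {
    l1 <- log(phi) + nunc %*% log(k[1, ]) - S %*% k[1, ]
    l2 <- log(1 - phi) + nunc %*% log(k[2, ]) - S %*% k[2, ]
    m <- pmax(l1, l2)
    den <- m + log(exp(l1 - m) + exp(l2 - m))
    r <- as.numeric(exp(l1 - den))
    ll <- sum(den)
    if (!is.finite(ll)) break
    phi <- min(max(mean(r), 1e-6), 1 - 1e-6)
    for (s in 1:2) {
      k1 <- sum(r * nunc[, s]) / sum(r * S[, s])
      k2 <- sum((1 - r) * nunc[, s]) / sum((1 - r) * S[, s])
      if (is.finite(k1) && k1 > 0) k[1, s] <- k1
      if (is.finite(k2) && k2 > 0) k[2, s] <- k2
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) break
    ll_prev <- ll
  }
  # canonical order: the class with the larger mean exit rate is "fast"
  if (mean(k[1, ]) < mean(k[2, ])) {
    k <- k[2:1, ]
    r <- 1 - r
    phi <- 1 - phi
  }
  colnames(k) <- as.character(states)
  rownames(k) <- c("fast", "slow")
  list(rates = k, fraction_fast = phi, responsibilities = r,
       loglik = ll, n_traces = length(ids))
}

#' First-order missed-event correction for alternating dwell rates
#'
#' Frame-sampled idealization cannot resolve sojourns shorter than the
#' decoder dead time (about one frame): a missed excursion to the other
#' state merges the two flanking dwells, so raw truncated-MLE exit rates are
#' biased low, most strongly when the partner state is fast. This applies
#' the standard first-order dead-time correction for a two-state alternating
#' process: with dead time `theta`, a sojourn in the partner state is missed
#' with probability `q = 1 - exp(-k_partner * theta)`; the expected number
#' of missed interruptions per observed dwell is `m = q / (1 - q)`, each
#' contributing one extra dwell of the state plus the short partner sojourn,
#' so `1/k_raw = (1 + m)/k + m * E[tau_partner | tau < theta]`. The pair of
#' equations is solved by fixed-point iteration.
#'
#' @param k_a_raw,k_b_raw raw exit rates (1/s) of the two states from a
#'   truncated MLE with `t_min = theta` (see [fit_dwell_exponential()]).
#' @param theta decoder dead time in seconds (typically one frame).
#' @param max_iter,tol iteration controls.
#' @return numeric vector `c(k_a, k_b)` of corrected exit rates.
#' @examples
#' correct_missed_events(5.5, 1.7, theta = 1 / 30)
#' @export
correct_missed_events <- function(k_a_raw, k_b_raw, theta,
                                  max_iter = 50, tol = 1e-10) {
  stopifnot(k_a_raw > 0, k_b_raw > 0, theta >= 0)
  if (theta == 0) return(c(k_a_raw, k_b_raw))
  ka <- k_a_raw
  kb <- k_b_raw
  for (it in seq_len(max_iter)) {
    qb <- 1 - exp(-kb * theta)
    ma <- qb / (1 - qb)
    etb <- if (qb > 0) 1 / kb - theta * exp(-kb * theta) / qb else 0
    qa <- 1 - exp(-ka * theta)
    mb <- qa / (1 - qa)
    eta <- if (qa > 0) 1 / ka - theta * exp(-ka * theta) / qa else 0
    inv_a <- (1 / k_a_raw - ma * etb) / (1 + ma)
    inv_b <- (1 / k_b_raw - mb * eta) / (1 + mb)
    if (inv_a <= 0 || inv_b <= 0) break  # correction out of first-order range
    ka_new <- 1 / inv_a
    kb_new <- 1 / inv_b
    if (abs(ka_new - ka) + abs(kb_new - kb) < tol) {
      ka <- ka_new
      kb <- kb_new
      break
    }
    ka <- ka_new
    kb <- kb_new
  }
  c(ka, kb)
}

#' Estimate the dye-pair photobleaching rate from static traces
#'
#' Fits a single exponential to the durations of uninterrupted FRET signal
#' in non-fluctuating traces: the signal ends at the first photobleaching
#' step of either dye (uncensored) or survives to the end of the recording
#' (right-censored). This is the photobleaching calibration that sets the
#' detection ceiling for slow dissociation rates.
#'
#' @param ts a `trace_set` or list of `fret_trace` (non-fluctuating traces).
#' @param min_traces minimum number of traces required (default 20).
#' @param bg_donor,bg_acceptor channel backgrounds.
#' @return A `rate_estimate` (see [rate_estimate()]) named `k_bleach`; if
#'   every trace survives unbleached only an upper bound is reported.
#' @export
estimate_photobleach_rate <- function(ts, min_traces = 20,
                                      bg_donor = 0, bg_acceptor = 0) {
  traces <- if (inherits(ts, "trace_set")) ts$traces else ts
  if (length(traces) < min_traces) {
    stop("need at least ", min_traces, " static traces (have ",
         length(traces), ")")
  }
  dur <- numeric(length(traces))
  cens <- logical(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    keep <- mask_after_bleach(tr, channels = "both",
                              bg_donor = bg_donor, bg_acceptor = bg_acceptor)
    bf <- attr(keep, "bleach_frame")
    if (is.na(bf)) {
      dur[i] <- length(tr$frame) / tr$frame_rate
      cens[i] <- TRUE
    } else {
      dur[i] <- bf / tr$frame_rate
      cens[i] <- FALSE
    }
  }
  ok <- dur > 0
  dur <- dur[ok]
  cens <- cens[ok]
  if (all(cens)) {
    # nothing bleached inside the window: report an upper bound
    limit <- 1 / mean(dur)
    return(rate_estimate("k_bleach", mean = NA_real_, sd = NA_real_,
                         bound = TRUE, limit = limit,
                         n = length(dur)))
  }
  fit <- fit_dwell_exponential(durations = dur, censored = cens)
  rate_estimate("k_bleach", mean = fit$rates, sd = fit$se,
                n = fit$n)
}

#' Construct a rate estimate
#'
#' The container for reported rate constants: a point estimate with
#' standard deviation, or -- when the process is slower than the
#' photobleaching detection ceiling -- an upper bound.
#'
#' @param quantity name of the rate (e.g. `"k_off"`, `"k_R_to_N"`).
#' @param mean point estimate (1/s); `NA` for pure bounds.
#' @param sd standard deviation; `NA` if undefined (single replicate).
#' @param corrected was a photobleaching correction applied.
#' @param bound is this a detection-limit bound rather than an estimate.
#' @param limit the bound value (1/s) when `bound` is `TRUE`.
#' @param n number of observations behind the estimate.
#' @return object of class `rate_estimate`.
#' @export
rate_estimate <- function(quantity, mean, sd = NA_real_, corrected = FALSE,
                          bound = FALSE, limit = NA_real_, n = NA_integer_) {
  if (!bound && !is.na(sd) && sd < 0) stop("sd must be >= 0")
  structure(
    list(quantity = quantity, mean = mean, sd = sd, corrected = corrected,
         bound = bound, limit = limit, n = n),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  if (x$bound) {
    cat(x$quantity, "<=", sprintf("%.3g", x$limit), "1/s (detection limit",
        if (x$corrected) ", bleach-corrected" else "", ")\n", sep = "")
  } else {
    cat(x$quantity, " = ", sprintf("%.3g", x$mean),
        if (!is.na(x$sd)) sprintf(" ± %.3g", x$sd) else "",
        " 1/s", if (x$corrected) " (bleach-corrected)" else "", "\n", sep = "")
  }
  invisible(x)
}

#' Photobleaching correction of an observed dissociation rate
#'
#' In binding experiments the loss of the acceptor-labelled factor's FRET
#' signal by dye photobleaching is indistinguishable from dissociation, so
#' the observed decay rate is `k_obs = k_off + k_bleach`. This subtracts the
#' calibrated photobleaching rate with propagated uncertainty. When the
#' observed rate is within two bleach-rate standard deviations of the bleach
#' rate itself, no point estimate is resolvable and an upper bound at the
#' detection limit is reported instead (default 0.2 1/s, the ceiling set by
#' photobleaching at typical imaging conditions).
#'
#' @param k_obs observed decay rate: a `rate_estimate` or numeric.
#' @param k_bleach photobleaching rate: a `rate_estimate` or numeric.
#' @param sd_obs,sd_bleach standard deviations when numerics are given.
#' @param detection_limit reported bound when the rate is unresolvable
#'   (1/s).
#' @param quantity name of the corrected rate.
#' @return a `rate_estimate`, either corrected (`corrected = TRUE`) or a
#'   detection-limit bound.
#' @examples
#' correct_koff(6.0, 0.1, sd_obs = 0.3, sd_bleach = 0.05)
#' correct_koff(0.15, 0.12, sd_obs = 0.02, sd_bleach = 0.02)
#' @export
correct_koff <- function(k_obs, k_bleach, sd_obs = NA_real_,
                         sd_bleach = NA_real_, detection_limit = 0.2,
                         quantity = "k_off") {
  if (inherits(k_obs, "rate_estimate")) {
    sd_obs <- k_obs$sd
    k_obs <- k_obs$mean
  }
  if (inherits(k_bleach, "rate_estimate")) {
    sd_bleach <- k_bleach$sd
    k_bleach <- k_bleach$mean
  }
  sd_prop <- sqrt(sum(c(sd_obs, sd_bleach)^2, na.rm = TRUE))
  guard <- if (is.na(sd_bleach)) 0 else 2 * sd_bleach
  if (k_obs <= k_bleach + guard) {
    return(rate_estimate(quantity, mean = NA_real_, sd = NA_real_,
                         corrected = TRUE, bound = TRUE,
                         limit = detection_limit))
  }
  rate_estimate(quantity, mean = k_obs - k_bleach, sd = sd_prop,
                corrected = TRUE)
}

#' Aggregate replicate rate estimates
#'
#' Rate constants are reported as unweighted mean plus-or-minus sample
#' standard deviation over independent replicate datasets (three by
#' default in the pipeline). A single replicate yields a mean with
#' undefined sd (flagged); if any replicate is a detection-limit bound the
#' aggregate is a bound.
#'
#' @param estimates list of `rate_estimate` of the same quantity.
#' @return a `rate_estimate`.
#' @examples
#' aggregate_replicates(list(
#'   rate_estimate("k_off", 2.0), rate_estimate("k_off", 2.2),
#'   rate_estimate("k_off", 2.4)
#' ))
#' @export
aggregate_replicates <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "rate_estimate")))
  qs <- vapply(estimates, function(e) e$quantity, character(1))
  if (length(unique(qs)) != 1) {
    stop("cannot aggregate estimates of different quantities: ",
         paste(unique(qs), collapse = ", "))
  }
  if (any(vapply(estimates, function(e) e$bound, logical(1)))) {
    # the aggregate must be an upper bound valid for every replicate
    lim <- suppressWarnings(
      max(vapply(estimates, function(e) {
        if (e$bound) e$limit else e$mean
      }, numeric(1)), na.rm = TRUE)
    )
    return(rate_estimate(qs[1], mean = NA_real_, sd = NA_real_,
                         corrected = any(vapply(estimates, function(e) e$corrected, logical(1))),
                         bound = TRUE, limit = lim))
  }
  m <- vapply(estimates, function(e) e$mean, numeric(1))
  rate_estimate(
    qs[1],
    mean = mean(m),
    sd = if (length(m) >= 2) sd(m) else NA_real_,
    corrected = any(vapply(estimates, function(e) e$corrected, logical(1))),
    n = length(m)
  )
}
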