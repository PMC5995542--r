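#' Fit a Gaussian-emission hidden Markov model to a FRET series
#'
#' Maximum-likelihood fit by expectation-maximization (Baum-Welch) with
#' Gaussian state emissions. Initialization is deterministic from emission
#' quantiles, plus `n_restarts` seeded restarts with perturbed means; the
#' best-likelihood fit is returned with states sorted by ascending mean.
#' EM stops when the relative log-likelihood change falls below `tol` or
#' after `max_iter` iterations (non-convergence is flagged, the best iterate
#' is still returned).
#'
#' @param fret a `fret_series` from [compute_fret()] or a numeric vector.
#' @param K number of states (>= 1).
#' @param n_restarts number of additional randomized restarts.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed seed for the restart perturbations.
#' @param sd_floor lower bound on emission sds (guards degenerate states).
#' @return An object of class `hmm_fit`: `K`, `mean`, `sd`, `transmat`
#'   (rows sum to 1), `init`, `loglik`, `ll_path` (per-iteration
#'   log-likelihood of the winning restart), `bic`, `converged`, `n`.
#' @examples
#' x <- c(rnorm(50, 0.3, 0.03), rnorm(50, 0.7, 0.03))
#' f <- fit_hmm(x, K = 2)
#' round(f$mean, 2)
#' @export
fit_hmm <- function(fret, K, n_restarts = 3, max_iter = 200, tol = 1e-6,
                    seed = 1, sd_floor = 1e-3) {
  x <- fret_values(fret)
  n <- length(x)
  if (K < 1) stop("K must be >= 1")
  if (n < 2 * K) stop("need at least 2*K unmasked frames to fit ", K, " states")

  if (K == 1) {
    mu <- mean(x)
    s <- max(sd(x), sd_floor)
    if (!is.finite(s)) s <- sd_floor
    ll <- sum(dnorm(x, mu, s, log = TRUE))
    return(structure(
      list(K = 1L, mean = mu, sd = s,
           transmat = matrix(1, 1, 1), init = 1,
           loglik = ll, ll_path = ll,
           bic = -2 * ll + hmm_n_par(1) * log(n),
           converged = TRUE, n = n),
      class = "hmm_fit"
    ))
  }

  base_means <- quantile(x, probs = (seq_len(K)) / (K + 1), names = FALSE)
  spread <- max(sd(x), sd_floor)
  best <- NULL
  for (r in 0:n_restarts) {
    mu0 <- base_means
    if (r > 0) {
      set.seed(seed + r)
      mu0 <- base_means + rnorm(K, 0, spread / 2)
    }
    fit <- hmm_em(x, mu0, rep(spread / 2, K), max_iter, tol, sd_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$mean)
  best$mean <- best$mean[ord]
  best$sd <- best$sd[ord]
  best$transmat <- best$transmat[ord, ord, drop = FALSE]
  best$init <- best$init[ord]
  best$K <- as.integer(K)
  best$n <- n
  best$bic <- -2 * best$loglik + hmm_n_par(K) * log(n)
  class(best) <- "hmm_fit"
  best
}

hmm_n_par <- function(K) K * K + 2 * K - 1  # transitions + init + means + sds

fret_values <- function(fret) {
  if (inherits(fret, "fret_series")) fret$fret[fret$valid] else as.numeric(fret)
}

hmm_em <- function(x, mu, s, max_iter, tol, sd_floor) {
  K <- length(mu)
  n <- length(x)
  A <- matrix(0.1 / (K - 1), K, K)
  diag(A) <- 0.9
  pi0 <- rep(1 / K, K)
  s <- pmax(s, sd_floor)

  ll_prev <- -Inf
  ll_path <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    B <- vapply(seq_len(K), function(k) dnorm(x, mu[k], s[k]), numeric(n))
    B <- pmax(B, 1e-300)
    dim(B) <- c(n, K)
    fb <- hmm_forward_backward(B, A, pi0)
    ll <- fb$loglik
    ll_path <- c(ll_path, ll)
    g <- fb$gamma
    xi <- fb$xi
    pi0 <- g[1, ]
    pi0 <- pi0 / sum(pi0)
    rs <- rowSums(xi)
    A <- xi / ifelse(rs > 0, rs, 1)
    A[rs == 0, ] <- 1 / K
    wk <- colSums(g)
    mu <- colSums(g * x) / wk
    s <- sqrt(colSums(g * (x - rep(mu, each = n))^2) / wk)
    s <- pmax(s, sd_floor)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(mean = mu, sd = s, transmat = A, init = pi0,
       loglik = ll_path[length(ll_path)], ll_path = ll_path,
       converged = converged)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Gaussian HMM fit:", x$K, "state(s),", x$n, "frames, logLik",
      sprintf("%.2f", x$loglik),
      if (!x$converged) "(not converged)" else "", "\n")
  print(data.frame(state = seq_len(x$K), mean = round(x$mean, 4),
                   sd = round(x$sd, 4)), row.names = FALSE)
  invisible(x)
}

#' Select the number of FRET states by BIC
#'
#' Fits HMMs with `K = 1..K_max` states and returns the K minimizing the
#' Bayesian information criterion.
#'
#' @param fret a `fret_series` or numeric vector.
#' @param K_max maximum number of states considered (default 4).
#' @param ... passed to [fit_hmm()].
#' @return list with `K` (best), `bic` (vector over K) and `fits`.
#' @export
select_K <- function(fret, K_max = 4, ...) {
  x <- fret_values(fret)
  ks <- seq_len(K_max)
  ks <- ks[2 * ks <= length(x)]
  if (length(ks) == 0) stop("series too short for any model")
  fits <- lapply(ks, function(k) {
    tryCatch(fit_hmm(x, k, ...), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  ks <- ks[ok]
  fits <- fits[ok]
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  list(K = ks[which.min(bics)], bic = setNames(bics, ks), fits = fits)
}

#' Decode the maximum a posteriori state path (Viterbi)
#'
#' @param fit an `hmm_fit`.
#' @param fret the `fret_series` the fit was obtained from (or a numeric
#'   vector).
#' @return An object of class `idealized_path`: `state` (integer labels
#'   into `state_mean`, one per unmasked frame), `frame` (0-based frame
#'   indices of the unmasked frames), `state_mean`, `state_sd`,
#'   `frame_rate`, `n_transitions` and `end_cause` (`"bleach"` if the
#'   series was masked by bleach detection, else `"trace_end"`).
#' @export
viterbi_decode <- function(fit, fret) {
  stopifnot(inherits(fit, "hmm_fit"))
  x <- fret_values(fret)
  n <- length(x)
  K <- fit$K
  if (K == 1) {
    st <- rep(1L, n)
  } else {
    logB <- vapply(seq_len(K), function(k) {
      dnorm(x, fit$mean[k], fit$sd[k], log = TRUE)
    }, numeric(n))
    dim(logB) <- c(n, K)
    st <- hmm_viterbi(logB, log(pmax(fit$transmat, 1e-300)),
                      log(pmax(fit$init, 1e-300)))
  }
  frames <- if (inherits(fret, "fret_series")) {
    which(fret$valid) - 1L
  } else {
    seq_len(n) - 1L
  }
  fr <- if (inherits(fret, "fret_series")) fret$frame_rate else NA_real_
  end_cause <- if (inherits(fret, "fret_series") && isTRUE(fret$bleach_masked)) {
    "bleach"
  } else {
    "trace_end"
  }
  structure(
    list(
      state = as.integer(st),
      frame = frames,
      state_mean = fit$mean,
      state_sd = fit$sd,
      frame_rate = fr,
      n_transitions = sum(diff(st) != 0),
      end_cause = end_cause
    ),
    class = "idealized_path"
  )
}

#' @export
print.idealized_path <- function(x, ...) {
  cat("idealized_path:", length(x$state), "frames,",
      length(x$state_mean), "state(s),", x$n_transitions, "transition(s)\n")
  invisible(x)
}

#' Merge close FRET states and flag traces usable for kinetics
#'
#' Applies the two exclusion rules used before dwell-time analysis:
#' (i) fitted states whose means differ by less than `merge_de` FRET units
#' are merged (closest pair first, occupancy-weighted mean, repeated until
#' all surviving means are at least `merge_de` apart) -- such transitions
#' are not resolvable FRET changes; (ii) traces with at most
#' `min_transitions - 1` surviving transitions are flagged ineligible for
#' kinetic analysis (they are retained for population histograms). The
#' operation is idempotent.
#'
#' @param paths an `idealized_path` or list of them.
#' @param merge_de minimum resolvable FRET difference (default 0.1).
#' @param min_transitions minimum surviving transitions for kinetic
#'   eligibility (default 2, i.e. traces with 0 or 1 transitions are
#'   excluded).
#' @return Path(s) of class `idealized_path` with merged states and an
#'   added `kinetic_eligible` flag.
#' @export
exclude_for_kinetics <- function(paths, merge_de = 0.1, min_transitions = 2) {
  single <- inherits(paths, "idealized_path")
  plist <- if (single) list(paths) else paths
  out <- lapply(plist, merge_close_states, merge_de = merge_de,
                min_transitions = min_transitions)
  if (single) out[[1]] else out
}

merge_close_states <- function(path, merge_de, min_transitions) {
  means <- path$state_mean
  sds <- path$state_sd
  labels <- path$state
  repeat {
    if (length(means) < 2) break
    ord <- order(means)
    d <- diff(means[ord])
    j <- which.min(d)
    if (d[j] >= merge_de) break
    a <- ord[j]; b <- ord[j + 1]
    na <- sum(labels == a); nb <- sum(labels == b)
    w <- if (na + nb > 0) c(na, nb) / (na + nb) else c(0.5, 0.5)
    new_mean <- w[1] * means[a] + w[2] * means[b]
    new_sd <- w[1] * sds[a] + w[2] * sds[b]
    means[a] <- new_mean
    sds[a] <- new_sd
    labels[labels == b] <- a
    keep <- setdiff(seq_along(means), b)
    relabel <- match(labels, keep)
    means <- means[keep]
    sds <- sds[keep]
    labels <- relabel
  }
  # canonical ascending-mean labelling
  ord <- order(means)
  labels <- match(labels, ord)
  path$state_mean <- means[ord]
  path$state_sd <- sds[ord]
  path$state <- as.integer(labels)
  path$n_transitions <- sum(diff(labels) != 0)
  path$kinetic_eligible <- path$n_transitions >= min_transitions
  path
}

#' Extract state dwell times from an idealized path
#'
#' One row per sojourn in a state. The first dwell of a trace is
#' left-censored (its beginning is unobserved) and the last dwell is
#' right-censored, ended either by photobleaching or by the end of the
#' recording; interior dwells end in a genuine state transition.
#'
#' @param path an `idealized_path` (after [exclude_for_kinetics()]).
#' @param frame_rate frames per second; defaults to the path's.
#' @param trace_id identifier copied into the table.
#' @return A data.frame (class `dwell_table`) with columns `trace_id`,
#'   `state`, `state_mean`, `start_frame`, `n_frames`, `duration_s`,
#'   `censored_left`, `censored_right`, `end_cause`.
#' @export
extract_dwells <- function(path, frame_rate = NULL, trace_id = 1L) {
  stopifnot(inherits(path, "idealized_path"))
  if (is.null(frame_rate)) frame_rate <- path$frame_rate
  if (is.null(frame_rate) || is.na(frame_rate)) {
    stop("frame_rate must be supplied when the path carries none")
  }
  r <- rle(path$state)
  k <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  df <- data.frame(
    trace_id = trace_id,
    state = r$values,
    state_mean = path$state_mean[r$values],
    start_frame = path$frame[starts],
    n_frames = r$lengths,
    duration_s = r$lengths / frame_rate,
    censored_left = seq_len(k) == 1,
    censored_right = seq_len(k) == k,
    end_cause = c(rep("transition", max(k - 1, 0)), path$end_cause),
    stringsAsFactors = FALSE
  )
  class(df) <- c("dwell_table", "data.frame")
  df
}

#' Bind dwell tables from many traces
#'
#' @param dwell_list list of `dwell_table` objects.
#' @return a single `dwell_table`.
#' @export
bind_dwells <- function(dwell_list) {
  df <- do.call(rbind, dwell_list)
  class(df) <- c("dwell_table", "data.frame")
  df
}
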