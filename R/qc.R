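#' Three-point moving average
#'
#' Centered smoothing over three data points, the standard pre-processing
#' applied to every trajectory before FRET computation and display. At the
#' series edges the window shrinks to the available points, so a length-1
#' series is returned unchanged and the output never leaves the range of the
#' input.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  left <- c(x[1], x[-n])
  right <- c(x[-1], x[n])
  counts <- c(2, rep(3, n - 2), 2)
  sums <- left + x + right
  sums[1] <- x[1] + x[2]
  sums[n] <- x[n - 1] + x[n]
  sums / counts
}

#' Correct donor bleed-through in the acceptor channel
#'
#' Subtracts the fraction `beta` of the (background-corrected) donor signal
#' that leaks into the acceptor detection channel:
#' `acceptor' = acceptor - beta * (donor - bg_D)`. The donor channel is
#' unchanged.
#'
#' @param trace a `fret_trace`.
#' @param beta bleed-through coefficient in `[0, 1)`.
#' @param bg_donor donor background (counts/frame).
#' @return the trace with corrected acceptor channel.
#' @export
correct_bleedthrough <- function(trace, beta, bg_donor = 0) {
  if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
  trace$acceptor <- trace$acceptor - beta * (trace$donor - bg_donor)
  trace$meta$bleedthrough_corrected <- beta
  trace
}

#' Detect photobleaching steps in a single fluorescence channel
#'
#' Finds downward intensity steps by penalized least-squares piecewise
#' constant segmentation (binary segmentation with an SIC-type penalty
#' proportional to the noise variance times `log(T)`). A changepoint counts
#' as a photobleaching step when (a) the level drops by at least
#' `min_drop_frac` of the pre-step level above background, (b) the signal
#' never recovers after the step (no later segment rises above the post
#' level by more than a quarter of the drop), (c) the trace ultimately
#' decays: the final segment sits below `bg + floor_frac * (pre - bg)`, and
#' (d) the pre-step level itself stands clear of the bleached floor
#' (`bg + floor_frac * (peak - bg)`), so that residual bleed-through
#' vanishing with a later donor bleach is not counted twice. Reversible
#' intensity changes caused by FRET state transitions fail (b) or (c) and
#' do not count; sequential partial steps of a multi-fluorophore aggregate
#' (e.g. 1000 to 500 to 0) count once each.
#'
#' @param x numeric intensity series (length >= 4).
#' @param bg channel background (counts/frame).
#' @param min_drop_frac minimum drop as a fraction of the pre-step level.
#' @param floor_frac fraction of the pre-bleach level that defines the
#'   "bleached" floor.
#' @param penalty segmentation penalty; defaults to
#'   `10 * sigma^2 * log(length(x))` with `sigma` estimated robustly from
#'   first differences.
#' @param max_segments maximum number of segments considered.
#' @return list with `n_steps`, `step_frames` (0-based frame index of the
#'   first bleached frame of each step) and the fitted `segment` table.
#' @export
detect_bleach_steps <- function(x, bg = 0, min_drop_frac = 0.4,
                                floor_frac = 0.25, penalty = NULL,
                                max_segments = 6) {
  n <- length(x)
  if (n < 4) stop("series too short for step detection (need >= 4 frames)")
  sigma <- mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- max(sd(x) / 10, 1e-12)
  if (is.null(penalty)) penalty <- 10 * sigma^2 * log(n)

  cps <- binseg_changepoints(x, penalty, max_segments)
  bounds <- c(0, sort(cps), n)
  means <- vapply(seq_len(length(bounds) - 1), function(i) {
    mean(x[(bounds[i] + 1):bounds[i + 1]])
  }, numeric(1))

  step_frames <- integer(0)
  if (length(means) > 1) {
    peak <- max(means)
    global_floor <- bg + floor_frac * (peak - bg)
    final <- means[length(means)]
    for (i in seq_len(length(means) - 1)) {
      pre <- means[i]
      post <- means[i + 1]
      drop <- pre - post
      later <- if (i + 2 <= length(means)) means[(i + 2):length(means)] else numeric(0)
      if (pre > global_floor &&
          drop >= min_drop_frac * (pre - bg) &&
          all(later <= post + 0.25 * drop) &&
          final <= bg + floor_frac * (pre - bg)) {
        step_frames <- c(step_frames, bounds[i + 1])
      }
    }
  }
  list(
    n_steps = length(step_frames),
    step_frames = step_frames,
    segments = data.frame(
      start = bounds[-length(bounds)],
      end = bounds[-1] - 1,
      mean = means
    )
  )
}

# Binary segmentation for piecewise-constant mean with penalty on each
# accepted split. Returns split positions k meaning a boundary between
# x[k] and x[k+1] (1-based count of frames before the split).
binseg_changepoints <- function(x, penalty, max_segments) {
  splits <- integer(0)
  queue <- list(c(1L, length(x)))
  while (length(queue) > 0 && length(splits) + 1 < max_segments) {
    seg <- queue[[1]]
    queue <- queue[-1]
    a <- seg[1]; b <- seg[2]
    if (b - a < 3) next
    y <- x[a:b]
    m <- length(y)
    cs <- cumsum(y)
    tot <- cs[m]
    k <- seq_len(m - 1)
    # SSE reduction of splitting after position k
    gain <- (cs[k] - tot * k / m)^2 * m / (k * (m - k))
    kbest <- which.max(gain)
    if (gain[kbest] > penalty) {
      pos <- a - 1L + kbest
      splits <- c(splits, pos)
      queue <- c(queue, list(c(a, pos)), list(c(pos + 1L, b)))
    }
  }
  sort(splits)
}

#' Compute the FRET efficiency series of a corrected trace
#'
#' FRET efficiency per frame is the acceptor fraction of total emission,
#' `E = acceptor / (donor + acceptor)`, computed on the bleed-through
#' corrected channels. Frames whose total intensity falls below a small
#' positive floor (including everything after photobleaching) are masked
#' rather than producing unstable ratios.
#'
#' @param trace a `fret_trace` (bleed-through corrected).
#' @param mask optional logical vector of frames to keep (e.g. pre-bleach
#'   frames from [mask_after_bleach()]); defaults to all frames.
#' @param smooth apply the three-point smoother to both channels first
#'   (default `TRUE`, matching the standard trajectory pre-processing).
#' @param total_floor minimum total intensity for a frame to be valid.
#' @param bg_donor,bg_acceptor channel backgrounds subtracted before the
#'   ratio.
#' @return An object of class `fret_series`: list with `fret`, `valid`
#'   (logical mask), `frame_rate` and `bleach_masked` (TRUE if the mask was
#'   produced by bleach detection).
#' @export
compute_fret <- function(trace, mask = NULL, smooth = TRUE,
                         total_floor = NULL, bg_donor = 0, bg_acceptor = 0) {
  d <- trace$donor - bg_donor
  a <- trace$acceptor - bg_acceptor
  if (smooth) {
    d <- smooth3(d)
    a <- smooth3(a)
  }
  tot <- d + a
  if (is.null(total_floor)) {
    total_floor <- 0.2 * max(stats::median(tot), 0)
  }
  valid <- tot > pmax(total_floor, .Machine$double.eps)
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(valid))
    valid <- valid & mask
  }
  fret <- rep(NA_real_, length(tot))
  fret[valid] <- a[valid] / tot[valid]
  structure(
    list(
      fret = fret, valid = valid, frame_rate = trace$frame_rate,
      bleach_masked = isTRUE(attr(mask, "bleach_masked"))
    ),
    class = "fret_series"
  )
}

#' Mask frames from the first photobleaching event onwards
#'
#' Runs [detect_bleach_steps()] on the requested channels and returns a
#' logical keep-mask that is `FALSE` from the first detected bleach frame to
#' the end of the trace. For conformational (always-FRET) dye pairs both
#' channels are informative; for binding experiments only the donor bleach
#' is detectable (loss of the acceptor dye on a bound factor is
#' indistinguishable from dissociation), so use `channels = "donor"`.
#'
#' @param trace a `fret_trace` (raw or corrected).
#' @param channels which channels to scan: `"both"` or `"donor"`.
#' @param bg_donor,bg_acceptor channel backgrounds.
#' @param ... passed to [detect_bleach_steps()].
#' @return logical vector (`TRUE` = keep) with attributes `bleach_masked`
#'   (was any step found) and `bleach_frame` (first bleached frame or `NA`).
#' @export
mask_after_bleach <- function(trace, channels = c("both", "donor"),
                              bg_donor = 0, bg_acceptor = 0, ...) {
  channels <- match.arg(channels)
  first <- Inf
  sd_ <- detect_bleach_steps(trace$donor, bg = bg_donor, ...)
  if (sd_$n_steps > 0) first <- min(first, sd_$step_frames[1])
  if (channels == "both") {
    sa <- detect_bleach_steps(trace$acceptor, bg = bg_acceptor, ...)
    if (sa$n_steps > 0) first <- min(first, sa$step_frames[1])
  }
  keep <- rep(TRUE, length(trace$frame))
  if (is.finite(first)) keep[trace$frame >= first] <- FALSE
  attr(keep, "bleach_masked") <- is.finite(first)
  attr(keep, "bleach_frame") <- if (is.finite(first)) first else NA_integer_
  keep
}

#' Estimate the donor bleed-through coefficient
#'
#' Uses trace segments where the acceptor dye has photobleached while the
#' donor is still alive: in such donor-only frames the acceptor channel
#' carries nothing but background and donor bleed-through, so the
#' coefficient is the robust central estimate (median) of
#' `(acceptor - bg_A) / (donor - bg_D)` over all qualifying frames.
#'
#' @param ts a `trace_set` (or list of `fret_trace`).
#' @param bg_donor,bg_acceptor channel backgrounds.
#' @param ... passed to [detect_bleach_steps()].
#' @return list with `beta_hat`, `n_frames` and `n_traces` used.
#' @export
estimate_bleedthrough <- function(ts, bg_donor = 0, bg_acceptor = 0, ...) {
  traces <- if (inherits(ts, "trace_set")) ts$traces else ts
  ratios <- numeric(0)
  n_traces_used <- 0
  for (tr in traces) {
    sa <- detect_bleach_steps(tr$acceptor, bg = bg_acceptor, ...)
    if (sa$n_steps == 0) next
    a_bleach <- sa$step_frames[1]
    sd_ <- detect_bleach_steps(tr$donor, bg = bg_donor, ...)
    d_bleach <- if (sd_$n_steps > 0) sd_$step_frames[1] else length(tr$frame)
    if (d_bleach <= a_bleach + 2) next
    win <- (a_bleach + 2):(d_bleach - 1)  # skip the transition frame itself
    d <- tr$donor[win + 1] - bg_donor
    a <- tr$acceptor[win + 1] - bg_acceptor
    ok <- d > 0.2 * stats::median(d)
    if (!any(ok)) next
    ratios <- c(ratios, a[ok] / d[ok])
    n_traces_used <- n_traces_used + 1
  }
  if (length(ratios) == 0) {
    stop(
      "no post-acceptor-bleach donor-only segments found; ",
      "supply donor-only calibration traces to estimate bleed-through"
    )
  }
  list(
    beta_hat = stats::median(ratios),
    n_frames = length(ratios),
    n_traces = n_traces_used
  )
}

#' Select analyzable single-molecule traces
#'
#' Applies the standard semi-automated trace selection rules to a simulated
#' or recorded trace set:
#'
#' 1. **Anti-correlation** - the Pearson correlation between the smoothed
#'    donor and the smoothed, bleed-through corrected acceptor over the
#'    pre-first-bleach window must be below `corr_thresh` (default 0.1).
#'    Static traces have correlation near 0 and pass, which is intended.
#' 2. **Single photobleaching step per channel** - exactly one detected
#'    bleach step (or none if the trace ends unbleached). For binding
#'    experiments set `check_acceptor_steps = FALSE`.
#' 3. **Characteristic single-fluorophore intensity** - the pre-bleach
#'    total corrected intensity must fall within `intensity_band` times the
#'    set median, which rejects aggregates with multiple fluorophores.
#' 4. **Acceptor signal present** (conformational dye pairs only) - the
#'    median corrected FRET over the analyzable window must exceed
#'    `min_fret`; a molecule whose acceptor photobleached before the
#'    recording shows a flat near-zero ratio and carries no FRET
#'    information. Skipped when `check_acceptor_steps = FALSE` (binding
#'    experiments are legitimately dark most of the time).
#'
#' @param ts a `trace_set` or list of traces.
#' @param beta bleed-through coefficient used for correction.
#' @param corr_thresh correlation threshold (default 0.1).
#' @param intensity_band allowed band around the set median total intensity.
#' @param check_acceptor_steps require a single acceptor bleach step
#'   (disable for binding experiments where the acceptor comes and goes
#'   with the factor).
#' @param bg_donor,bg_acceptor channel backgrounds.
#' @param min_prebleach_frames minimum analyzable window length.
#' @param min_fret minimum median FRET for rule 4 (conformational mode).
#' @return list with `accepted` (integer indices), `report` (one row per
#'   trace: correlation, step counts, intensity, accept flag and reason) and
#'   `masks` (per-trace keep-masks from [mask_after_bleach()]).
#' @export
select_traces <- function(ts, beta = 0.13, corr_thresh = 0.1,
                          intensity_band = c(0.5, 1.5),
                          check_acceptor_steps = TRUE,
                          bg_donor = 0, bg_acceptor = 0,
                          min_prebleach_frames = 10, min_fret = 0.15) {
  traces <- if (inherits(ts, "trace_set")) ts$traces else ts
  n <- length(traces)
  if (n == 0) {
    return(list(
      accepted = integer(0),
      report = data.frame(
        trace_id = integer(0), correlation = numeric(0),
        donor_steps = integer(0), acceptor_steps = integer(0),
        total_intensity = numeric(0), median_fret = numeric(0),
        accepted = logical(0), reason = character(0)
      ),
      masks = list()
    ))
  }

  channels <- if (check_acceptor_steps) "both" else "donor"
  corr <- numeric(n)
  d_steps <- integer(n)
  a_steps <- integer(n)
  intens <- numeric(n)
  med_fret <- rep(NA_real_, n)
  masks <- vector("list", n)
  too_short <- logical(n)

  for (i in seq_len(n)) {
    tr <- correct_bleedthrough(traces[[i]], beta, bg_donor = bg_donor)
    sd_ <- detect_bleach_steps(tr$donor, bg = bg_donor)
    d_steps[i] <- sd_$n_steps
    if (check_acceptor_steps) {
      sa <- detect_bleach_steps(tr$acceptor, bg = bg_acceptor)
      a_steps[i] <- sa$n_steps
    }
    keep <- mask_after_bleach(tr, channels = channels,
                              bg_donor = bg_donor, bg_acceptor = bg_acceptor)
    masks[[i]] <- keep
    win <- which(keep)
    if (length(win) < min_prebleach_frames) {
      too_short[i] <- TRUE
      corr[i] <- NA_real_
      intens[i] <- NA_real_
      next
    }
    ds <- smooth3(tr$donor)[win]
    as <- smooth3(tr$acceptor)[win]
    corr[i] <- if (sd(ds) > 0 && sd(as) > 0) cor(ds, as) else 0
    intens[i] <- stats::median(tr$donor[win] + tr$acceptor[win]) -
      bg_donor - bg_acceptor
    tot <- ds + as
    med_fret[i] <- stats::median(as[tot > 0] / tot[tot > 0])
  }

  med_int <- stats::median(intens, na.rm = TRUE)
  reason <- character(n)
  accepted <- logical(n)
  for (i in seq_len(n)) {
    if (too_short[i]) {
      reason[i] <- "short_window"
    } else if (!is.na(corr[i]) && corr[i] >= corr_thresh) {
      reason[i] <- "correlation"
    } else if (d_steps[i] > 1) {
      reason[i] <- "multistep_donor"
    } else if (check_acceptor_steps && a_steps[i] > 1) {
      reason[i] <- "multistep_acceptor"
    } else if (is.na(intens[i]) ||
               intens[i] < intensity_band[1] * med_int ||
               intens[i] > intensity_band[2] * med_int) {
      reason[i] <- "intensity"
    } else if (check_acceptor_steps &&
               (is.na(med_fret[i]) || med_fret[i] < min_fret)) {
      reason[i] <- "no_acceptor"
    } else {
      reason[i] <- "ok"
      accepted[i] <- TRUE
    }
  }

  list(
    accepted = which(accepted),
    report = data.frame(
      trace_id = seq_len(n),
      correlation = corr,
      donor_steps = d_steps,
      acceptor_steps = a_steps,
      total_intensity = intens,
      median_fret = med_fret,
      accepted = accepted,
      reason = reason
    ),
    masks = masks
  )
}
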