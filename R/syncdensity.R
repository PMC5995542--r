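#' Synchronize traces at a kinetic feature
#'
#' Time-shifts each trace so that a chosen feature of its idealized path
#' sits at t = 0, the alignment used before compiling post-synchronized
#' FRET probability density (contour) plots. Supported modes:
#'
#' * `"fret_event_start"` - the first frame assigned to a state with mean
#'   above `fret_on` (the appearance of the FRET signal when a labelled
#'   factor binds);
#' * `"first_transition_to"` - the first transition *into* the state whose
#'   fitted mean is closest to `target_mean`;
#' * `"first_hi_to_lo"` - the first transition from the highest-mean state
#'   to a lower-mean state (e.g. the first transition from the non-rotated
#'   to the rotated ribosome conformation).
#'
#' Traces lacking the feature are excluded and tallied.
#'
#' @param paths list of `idealized_path`.
#' @param mode synchronization mode, see above.
#' @param fret_on FRET threshold defining "signal present" for
#'   `"fret_event_start"`.
#' @param target_mean target state mean for `"first_transition_to"`.
#' @return list with `sync_frames` (0-based frame of the feature per trace,
#'   `NA` when absent) and `n_excluded`.
#' @export
synchronize_traces <- function(paths,
                               mode = c("fret_event_start",
                                        "first_transition_to",
                                        "first_hi_to_lo"),
                               fret_on = 0.25, target_mean = NULL) {
  mode <- match.arg(mode)
  sync <- vapply(paths, function(p) {
    st <- p$state
    if (length(st) == 0) return(NA_integer_)
    means <- p$state_mean
    if (mode == "fret_event_start") {
      on <- means[st] >= fret_on
      i <- which(on)[1]
      if (is.na(i)) NA_integer_ else p$frame[i]
    } else if (mode == "first_transition_to") {
      if (is.null(target_mean)) stop("target_mean required for this mode")
      tgt <- which.min(abs(means - target_mean))
      i <- which(st[-1] == tgt & st[-length(st)] != tgt)[1]
      if (is.na(i)) NA_integer_ else p$frame[i + 1]
    } else {
      hi <- which.max(means)
      i <- which(st[-length(st)] == hi & means[st[-1]] < means[hi])[1]
      if (is.na(i)) NA_integer_ else p$frame[i + 1]
    }
  }, integer(1))
  list(sync_frames = sync, n_excluded = sum(is.na(sync)))
}

#' Compile aligned traces into a FRET probability density map
#'
#' The 2-D histogram of (time since synchronization, FRET) across a set of
#' aligned traces, the data behind single-molecule contour plots. Each time
#' column is normalized over the traces still contributing at that time
#' (survivor normalization), so every populated column sums to 1.
#'
#' @param fret_list list of `fret_series`.
#' @param sync_frames 0-based synchronization frame per trace (`NA` drops
#'   the trace); use `rep(0L, n)` for unsynchronized maps.
#' @param frame_rate frames per second.
#' @param t_max map extent in seconds after the synchronization point.
#' @param fret_breaks FRET bin edges (default 0.02-unit bins on
#'   `[-0.1, 1.1]`).
#' @param frames_per_bin time-bin width in frames (default 1).
#' @return object of class `density_map`: `density` (FRET bins x time
#'   bins), `counts`, `n_contributing` per column, `time_mid`, `fret_mid`,
#'   bin edges and `n_traces`.
#' @export
density_map <- function(fret_list, sync_frames, frame_rate = 30,
                        t_max = 10, fret_breaks = seq(-0.1, 1.1, by = 0.02),
                        frames_per_bin = 1) {
  stopifnot(length(sync_frames) == length(fret_list))
  use <- which(!is.na(sync_frames))
  if (length(use) == 0) stop("no synchronized traces to compile")
  n_tbins <- ceiling(t_max * frame_rate / frames_per_bin)
  nf <- length(fret_breaks) - 1
  counts <- matrix(0, nrow = nf, ncol = n_tbins)
  contrib <- integer(n_tbins)

  for (i in use) {
    f <- fret_list[[i]]
    rel <- which_frames(f) - sync_frames[i]
    ok <- f$valid & rel >= 0 & rel < n_tbins * frames_per_bin
    if (!any(ok)) next
    tb <- rel[ok] %/% frames_per_bin + 1
    fb <- findInterval(f$fret[ok], fret_breaks,
                       rightmost.closed = TRUE, all.inside = TRUE)
    for (j in seq_along(tb)) counts[fb[j], tb[j]] <- counts[fb[j], tb[j]] + 1
    contrib[unique(tb)] <- contrib[unique(tb)] + 1L
  }

  csum <- colSums(counts)
  dens <- counts
  nz <- csum > 0
  dens[, nz] <- sweep(counts[, nz, drop = FALSE], 2, csum[nz], "/")

  structure(
    list(
      density = dens, counts = counts, n_contributing = contrib,
      time_mid = ((seq_len(n_tbins) - 0.5) * frames_per_bin) / frame_rate,
      fret_mid = (fret_breaks[-1] + fret_breaks[-length(fret_breaks)]) / 2,
      time_breaks = (0:n_tbins) * frames_per_bin / frame_rate,
      fret_breaks = fret_breaks,
      n_traces = length(use)
    ),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map:", nrow(x$density), "FRET bins x", ncol(x$density),
      "time bins,", x$n_traces, "traces\n")
  invisible(x)
}

#' Column-mean FRET of a density map
#'
#' The mean FRET value in each time column, a convenient 1-D summary of a
#' contour plot (e.g. the decay of the bound-state FRET level after
#' synchronization to the binding event).
#'
#' @param dm a `density_map`.
#' @return numeric vector (NA for empty columns).
#' @export
density_column_mean <- function(dm) {
  stopifnot(inherits(dm, "density_map"))
  csum <- colSums(dm$counts)
  out <- rep(NA_real_, ncol(dm$counts))
  nz <- csum > 0
  out[nz] <- colSums(dm$counts[, nz, drop = FALSE] * dm$fret_mid) / csum[nz]
  out
}

#' Write a density map as CSV plus JSON axis metadata
#'
#' @param dm a `density_map`.
#' @param path base path; writes `<path>.csv` (matrix, FRET rows x time
#'   columns) and `<path>.json` (axes).
#' @return invisibly, the two file paths.
#' @export
write_density_map <- function(dm, path) {
  stopifnot(inherits(dm, "density_map"))
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  write.table(dm$density, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(time_breaks = dm$time_breaks, fret_breaks = dm$fret_breaks,
         n_contributing = dm$n_contributing, n_traces = dm$n_traces),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, js))
}
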