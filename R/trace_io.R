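#' Write and read trace sets as TSV files plus a JSON manifest
#'
#' One tab-separated file per trace with header columns `frame`, `time_s`,
#' `donor`, `acceptor`, and a `manifest.json` recording the scenario name,
#' seed, frame rate, emission parameters and per-trace ground truth
#' (subpopulation, bleach times, hidden state segments).
#'
#' @param ts a `trace_set` from [simulate_scenario()].
#' @param dir output directory (created if missing).
#' @param digits significant digits written for the intensities.
#' @return `write_trace_set()` invisibly returns the directory;
#'   `read_trace_set()` returns a `trace_set` (traces carry no `truth`
#'   component beyond what the manifest stores).
#' @export
write_trace_set <- function(ts, dir, digits = 6) {
  stopifnot(inherits(ts, "trace_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ts$traces)) {
    tr <- ts$traces[[i]]
    df <- data.frame(
      frame = tr$frame,
      time_s = signif(tr$time_s, digits),
      donor = signif(tr$donor, digits),
      acceptor = signif(tr$acceptor, digits)
    )
    write.table(df, file.path(dir, sprintf("trace_%04d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  man <- ts$manifest
  man$truth <- lapply(man$truth, function(tt) {
    tt$segments <- as.list(tt$segments)
    tt$bleach_time_donor <- finite_or_string(tt$bleach_time_donor)
    tt$bleach_time_acceptor <- finite_or_string(tt$bleach_time_acceptor)
    tt
  })
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

finite_or_string <- function(x) if (is.finite(x)) x else "Inf"

#' @rdname write_trace_set
#' @export
read_trace_set <- function(dir) {
  man_file <- file.path(dir, "manifest.json")
  if (!file.exists(man_file)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(man_file, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^trace_\\d+\\.tsv$",
                           full.names = TRUE))
  traces <- lapply(seq_along(files), function(i) {
    df <- read.table(files[i], header = TRUE, sep = "\t")
    structure(
      list(
        frame = df$frame, time_s = df$time_s,
        donor = df$donor, acceptor = df$acceptor,
        frame_rate = man$frame_rate,
        meta = list(scenario = man$scenario, trace_id = i),
        truth = NULL
      ),
      class = "fret_trace"
    )
  })
  structure(list(traces = traces, manifest = man), class = "trace_set")
}
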