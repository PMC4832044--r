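#' Sampling design for an around-the-clock time course
#'
#' Describes the Zeitgeber times (ZT, hours after lights-on) and replicate
#' labels of every sample in one assay. The default grid matches a
#' liver-style circadian design: samples every 2 h over one 24-h cycle with
#' two replicate series, i.e. ZT0, ZT2, ..., ZT22 x \{r1, r2\} = 24 samples.
#'
#' @param times numeric vector of Zeitgeber times in hours; each must lie in
#'   `[0, period)`. One entry per time point (replicates are expanded via
#'   `n_replicates`).
#' @param n_replicates integer, replicate series per time point.
#' @param period rhythm period in hours (fixed at 24 for an entrained
#'   light/dark design).
#' @return A `ts_design` object: a data.frame with columns `sample_id`
#'   (e.g. "ZT02_r1"), `time` (hours) and `replicate`, plus a `period`
#'   attribute.
#' @examples
#' d <- ts_design()
#' nrow(d)            # 24
#' unique(d$time)     # 0, 2, ..., 22
#' @export
ts_design <- function(times = seq(0, 22, by = 2), n_replicates = 2,
                      period = 24) {
  stopifnot(is.numeric(times), length(times) >= 1,
            n_replicates >= 1, period > 0)
  if (any(times < 0 | times >= period))
    stop("all times must lie in [0, period)")
  if (anyDuplicated(times))
    stop("'times' must be distinct; replicates are set via 'n_replicates'")
  reps <- rep(seq_len(n_replicates), each = length(times))
  tt <- rep(times, times = n_replicates)
  d <- data.frame(
    sample_id = sprintf("ZT%02d_r%d", round(tt), reps),
    time = tt,
    replicate = reps,
    stringsAsFactors = FALSE
  )
  attr(d, "period") <- period
  class(d) <- c("ts_design", "data.frame")
  d
}

#' @export
print.ts_design <- function(x, ...) {
  cat(sprintf("Time-course design: %d samples, %d distinct times, period %g h\n",
              nrow(x), length(unique(x$time)), design_period(x)))
  NextMethod()
}

#' Period of a time-course design
#' @param design a `ts_design`.
#' @return period in hours.
#' @export
design_period <- function(design) {
  p <- attr(design, "period")
  if (is.null(p)) 24 else p
}

validate_design <- function(design, min_times = 4) {
  stopifnot(is.data.frame(design),
            all(c("sample_id", "time", "replicate") %in% names(design)))
  if (length(unique(design$time)) < min_times)
    stop("at least ", min_times, " distinct times are required")
  invisible(design)
}
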