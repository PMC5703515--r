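# Running maximum of x over a trailing window of `width` samples (the
# current sample included). The moving-max tracks the recent resting
# saturation and serves as the desaturation baseline.
moving_max <- function(x, width) {
  n <- length(x)
  out <- numeric(n)
  # monotonic deque of indices with decreasing values
  q <- integer(0)
  for (i in seq_len(n)) {
    while (length(q) && x[q[length(q)]] <= x[i]) q <- q[-length(q)]
    q <- c(q, i)
    if (q[1L] <= i - width) q <- q[-1L]
    out[i] <- x[q[1L]]
  }
  out
}

# Trailing moving average over `width` samples (shorter at the start).
moving_avg <- function(x, width) {
  cs <- cumsum(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - width, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

#' Detect oxygen desaturation events
#'
#' Events are falls of at least `drop_threshold` percentage points below a
#' running baseline. The baseline is the moving maximum, over the
#' preceding `baseline_window` seconds, of a `smooth_s`-second moving
#' average of the signal; smoothing keeps measurement noise from inflating
#' the baseline or fragmenting events. Candidate episodes are delimited
#' independently of the threshold: maximal runs where the smoothed signal
#' sits at least `onset_margin` below the baseline, with runs closer than
#' `min_separation` seconds merged and depth scanning capped at
#' `max_duration` seconds. An episode counts as an event at a given
#' threshold iff its maximum raw drop below the baseline reaches the
#' threshold. Because episode boundaries do not depend on the threshold,
#' the event count is monotone non-increasing in the threshold (so the 4%
#' index can never exceed the 3% index on the same recording).
#'
#' @param samples Preprocessed 1-Hz numeric series.
#' @param drop_threshold Minimum fall in % points (3 for ODI3, 4 for ODI4).
#' @param baseline_window Baseline moving-max window in s (default 120).
#' @param smooth_s Moving-average width in s for baseline/episode
#'   delimitation (default 10; depth is always measured on the raw series).
#' @param onset_margin Drop in % points that opens/closes a candidate
#'   episode (default 1).
#' @param min_separation Episodes closer than this (s) are merged
#'   (default 10).
#' @param max_duration Longest single episode in s (default 300); longer
#'   runs still count once.
#' @return data.frame with one row per event: `start`, `nadir_time`,
#'   `end` (sample indices), `nadir` (% saturation) and `depth` (max drop).
#' @export
detect_desaturations <- function(samples, drop_threshold = 3,
                                 baseline_window = 120L, smooth_s = 10L,
                                 onset_margin = 1,
                                 min_separation = 10L, max_duration = 300L) {
  x <- as.numeric(samples)
  n <- length(x)
  empty <- data.frame(start = integer(0), nadir_time = integer(0),
                      end = integer(0), nadir = numeric(0), depth = numeric(0))
  if (n < 2L) return(empty)
  sm <- moving_avg(x, smooth_s)
  base <- moving_max(sm, baseline_window)
  drop <- base - x
  below <- (base - sm) >= onset_margin
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by short recoveries
  if (nrow(runs) > 1L) {
    keep <- list(runs[1L, ])
    for (k in 2L:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs[k, 1L] - last[2L] - 1L < min_separation) {
        keep[[length(keep)]] <- c(last[1L], runs[k, 2L])
      } else keep[[length(keep) + 1L]] <- runs[k, ]
    }
    runs <- do.call(rbind, keep)
  }
  ev <- lapply(seq_len(nrow(runs)), function(k) {
    i1 <- runs[k, 1L]; i2 <- runs[k, 2L]
    seg_drop <- drop[i1:i2]
    # a very long run (sustained hypoxemia) is scanned only up to the cap
    lim <- min(length(seg_drop), max_duration)
    depth <- max(seg_drop[seq_len(lim)])
    if (depth < drop_threshold) return(NULL)
    nt <- i1 + which.max(seg_drop[seq_len(lim)]) - 1L
    data.frame(start = i1, nadir_time = nt, end = i2,
               nadir = x[nt], depth = depth)
  })
  ev <- ev[!vapply(ev, is.null, logical(1))]
  if (length(ev) == 0L) return(empty)
  do.call(rbind, ev)
}

#' Oxygen desaturation index
#'
#' Number of desaturation events of at least `threshold` % points per hour
#' of recording.
#'
#' @param samples Preprocessed 1-Hz series.
#' @param threshold Drop threshold in % points (3 for ODI3, 4 for ODI4).
#' @param duration_hours Recording duration in hours; computed from the
#'   series length at 1 Hz when omitted.
#' @param ... Passed to [detect_desaturations()].
#' @return Events per hour.
#' @export
odi <- function(samples, threshold = 3, duration_hours = NULL, ...) {
  if (is.null(duration_hours)) duration_hours <- (length(samples) - 1L) / 3600
  if (duration_hours <= 0) stop("recording duration must be positive")
  nrow(detect_desaturations(samples, drop_threshold = threshold, ...)) / duration_hours
}

#' CT90 and summary saturation statistics
#'
#' CT90 is the percentage of recording time spent below 90% saturation.
#' The basal saturation is the modal integer value (the most common
#' saturation level, a standard oximetry-report convention; switch
#' `basal = "median"` for the median instead).
#'
#' @param samples Preprocessed numeric series.
#' @param basal `"mode"` (default) or `"median"`.
#' @return Named vector `ct90, spo2_basal, spo2_min, spo2_mean`.
#' @export
ct90_and_stats <- function(samples, basal = c("mode", "median")) {
  basal <- match.arg(basal)
  x <- as.numeric(samples)
  if (length(x) == 0L) stop("empty signal")
  b <- if (basal == "mode") {
    tab <- table(round(x))
    as.numeric(names(tab)[which.max(tab)])
  } else stats::median(x)
  c(ct90 = 100 * mean(x < 90), spo2_basal = b,
    spo2_min = min(x), spo2_mean = mean(x))
}

#' All conventional oximetry indices for one recording
#'
#' @param rec A preprocessed [spo2_recording()] or numeric vector.
#' @param ... Passed to [detect_desaturations()].
#' @return Named vector `odi3, odi4, ct90, spo2_basal, spo2_min, spo2_mean`.
#' @export
oximetry_indices <- function(rec, ...) {
  x <- if (inherits(rec, "spo2_recording")) rec$samples else as.numeric(rec)
  hrs <- (length(x) - 1L) / 3600
  c(odi3 = odi(x, 3, hrs, ...), odi4 = odi(x, 4, hrs, ...), ct90_and_stats(x))
}
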