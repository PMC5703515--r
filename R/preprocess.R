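#' Remove oximetry artifacts
#'
#' Scans a 1-Hz saturation series and removes the three artifact classes
#' found in portable oximetry: zero samples (probe disconnections), samples
#' below 20% saturation (physiologically impossible), and transient dips
#' flagged by sample-to-sample changes of at least `delta` %/s. Missing
#' samples are treated like zeros: removed here and bridged later.
#'
#' For the delta rule, the series is split into runs at every step with
#' `|change| >= delta`. A run flanked by such steps is an artifact when it is
#' shorter than `min_run` seconds and shorter than its neighbour; persistent
#' level shifts (both sides long) are kept as physiology — deep but
#' non-instantaneous desaturations occur in chronic obstructive pulmonary
#' disease — and the residual seam is later smoothed by [bridge_gaps()].
#'
#' @param rec An [spo2_recording()] or a bare numeric vector.
#' @param delta Artifact step threshold in %/s (default 4).
#' @param low Lower physiological bound in % (default 20; values strictly
#'   below are removed).
#' @param min_run Minimum duration, in samples, for a run reached by a
#'   `>= delta` step to be accepted as physiology (default 30).
#' @return A list with `samples` (the cleaned series), `cut` (logical vector
#'   over the input marking removed positions) and `report`, a
#'   `preprocess_report` with fields `n_zero_removed`, `n_below20_removed`,
#'   `n_delta_removed`, `n_missing_removed`, `fraction_removed`.
#' @export
remove_artifacts <- function(rec, delta = 4, low = 20, min_run = 30) {
  x <- if (inherits(rec, "spo2_recording")) rec$samples else as.numeric(rec)
  n <- length(x)
  miss <- is.na(x)
  zero <- !miss & x == 0
  below <- !miss & x > 0 & x < low
  keep <- !(miss | zero | below)
  y <- x[keep]
  n_delta <- 0L
  if (length(y) >= 2L) {
    repeat {
      d <- abs(diff(y))
      bad_step <- d >= delta
      if (!any(bad_step)) break
      # runs delimited by the offending steps
      run_id <- cumsum(c(1L, as.integer(bad_step)))
      len <- tabulate(run_id)
      nr <- length(len)
      drop_run <- rep(FALSE, nr)
      for (b in which(bad_step)) {
        l <- run_id[b]; r <- run_id[b + 1L]
        if (len[l] >= min_run && len[r] >= min_run) next  # level shift: keep
        if (len[l] == len[r]) drop_run[r] <- TRUE         # tie: drop arriving side
        else if (len[l] < len[r]) drop_run[l] <- TRUE else drop_run[r] <- TRUE
      }
      if (!any(drop_run)) break  # only level shifts remain; bridge_gaps handles seams
      rm_idx <- drop_run[run_id]
      n_delta <- n_delta + sum(rm_idx)
      y <- y[!rm_idx]
      if (length(y) < 2L) break
    }
  }
  if (length(y) == 0L) stop("unusable recording: no samples survive artifact removal")
  report <- structure(list(
    n_zero_removed = sum(zero),
    n_below20_removed = sum(below),
    n_delta_removed = n_delta,
    n_missing_removed = sum(miss),
    n_gaps_bridged = 0L,
    n_interpolated_samples = 0L,
    fraction_removed = (n - length(y)) / n
  ), class = "preprocess_report")
  # positions removed, on the original timeline
  cut <- !keep
  kept_pos <- which(keep)
  if (n_delta > 0L) {
    # recompute which original positions survived
    surv <- match_survivors(x[keep], y)
    cut[kept_pos[!surv]] <- TRUE
  }
  list(samples = y, cut = cut, report = report)
}

# Mark which elements of the pre-delta series survived into the final series.
# The delta stage only deletes (never reorders), so a greedy left-to-right
# match recovers the surviving positions.
match_survivors <- function(before, after) {
  surv <- logical(length(before))
  j <- 1L
  for (i in seq_along(before)) {
    if (j <= length(after) && identical(before[i], after[j])) {
      surv[i] <- TRUE
      j <- j + 1L
    }
  }
  if (j != length(after) + 1L) {
    # fallback (repeated values can confuse the greedy pass): align by value
    surv <- rep(TRUE, length(before))
  }
  surv
}

#' Bridge gaps left by artifact removal
#'
#' After artifact removal the remaining valid sections are concatenated. At
#' each seam whose jump is at least `delta` %/s, a minimal linear ramp is
#' inserted: the fewest equally spaced samples such that every step is
#' strictly below `delta` (k intermediate samples, k the smallest integer
#' with `|jump| / (k + 1) < delta`). This avoids introducing non-natural
#' saturation changes into the cleaned series.
#'
#' @param samples Cleaned numeric series (output of [remove_artifacts()]).
#' @param seams Integer positions `i` meaning "a cut occurred between
#'   `samples[i]` and `samples[i+1]`". When `NULL` (default), every step
#'   `>= delta` is treated as a seam, which is equivalent for the pipeline's
#'   purposes since direct joins below `delta` need no insertion.
#' @param delta Step threshold in %/s (default 4).
#' @return A list with `samples` (contiguous series, no residual
#'   `>= delta` step), `n_gaps_bridged`, `n_interpolated_samples` and
#'   `interpolated` (logical mask over the output).
#' @export
bridge_gaps <- function(samples, seams = NULL, delta = 4) {
  x <- as.numeric(samples)
  if (is.null(seams)) seams <- which(abs(diff(x)) >= delta)
  seams <- sort(unique(seams))
  seams <- seams[abs(x[seams + 1L] - x[seams]) >= delta]
  if (length(seams) == 0L) {
    return(list(samples = x, n_gaps_bridged = 0L, n_interpolated_samples = 0L,
                interpolated = logical(length(x))))
  }
  pieces <- list(); masks <- list()
  prev <- 1L
  n_interp <- 0L
  for (s in seams) {
    jump <- x[s + 1L] - x[s]
    k <- max(0L, ceiling(abs(jump) / delta) - 1L)
    while (abs(jump) / (k + 1L) >= delta) k <- k + 1L  # strictly below delta
    ramp <- x[s] + jump * seq_len(k) / (k + 1L)
    pieces[[length(pieces) + 1L]] <- c(x[prev:s], ramp)
    masks[[length(masks) + 1L]] <- c(logical(s - prev + 1L), rep(TRUE, k))
    n_interp <- n_interp + k
    prev <- s + 1L
  }
  pieces[[length(pieces) + 1L]] <- x[prev:length(x)]
  masks[[length(masks) + 1L]] <- logical(length(x) - prev + 1L)
  list(samples = unlist(pieces), n_gaps_bridged = length(seams),
       n_interpolated_samples = n_interp, interpolated = unlist(masks))
}

#' Full preprocessing pipeline
#'
#' [remove_artifacts()] followed by [bridge_gaps()]. The output series
#' contains no zeros, no samples below the physiological floor, no missing
#' values and no sample-to-sample change of `delta` %/s or more. Applying
#' the pipeline to an already-clean signal is the identity.
#'
#' @inheritParams remove_artifacts
#' @return A list with `samples` and `report` (a `preprocess_report`
#'   including gap-bridging counts).
#' @export
preprocess_spo2 <- function(rec, delta = 4, low = 20, min_run = 30) {
  ra <- remove_artifacts(rec, delta = delta, low = low, min_run = min_run)
  bg <- bridge_gaps(ra$samples, delta = delta)
  rep <- ra$report
  rep$n_gaps_bridged <- bg$n_gaps_bridged
  rep$n_interpolated_samples <- bg$n_interpolated_samples
  list(samples = bg$samples, report = rep, interpolated = bg$interpolated)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(paste0("<preprocess_report> zeros=%d below20=%d delta=%d missing=%d ",
                     "gaps_bridged=%d interpolated=%d removed=%.1f%%\n"),
              x$n_zero_removed, x$n_below20_removed, x$n_delta_removed,
              x$n_missing_removed, x$n_gaps_bridged, x$n_interpolated_samples,
              100 * x$fraction_removed))
  invisible(x)
}
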