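#' Feature matrix for a set of recordings
#'
#' Preprocesses each recording and extracts the 16 oximetric features,
#' returning one row per recording.
#'
#' @param recordings List of [spo2_recording()]s (raw; preprocessing is
#'   applied here).
#' @param ... Passed to [extract_features()].
#' @return Numeric matrix, `length(recordings)` x 16, named columns.
#' @export
cohort_features <- function(recordings, ...) {
  rows <- lapply(recordings, function(r) {
    clean <- preprocess_spo2(r)
    as.numeric(extract_features(clean$samples, ...))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- feature_names()
  rownames(m) <- vapply(recordings, function(r) r$subject_id, "")
  m
}

#' End-to-end screening pipeline on a labelled cohort
#'
#' Runs the complete method on a set of recordings with known reference
#' AHI: feature extraction, FCBF selection against the reference, and
#' leave-one-out cross-validated MLP estimation, returning held-out AHI
#' estimates together with the selection result.
#'
#' @param recordings List of raw [spo2_recording()]s.
#' @param ahi_ref Reference AHI per recording.
#' @param n_hidden,nu Network architecture (defaults: the published in-lab
#'   preset, N_H = 12, nu = 1).
#' @param seed Seed controlling weight initializations.
#' @param features Optional precomputed feature matrix (skips extraction).
#' @return List with `features`, `fcbf`, `pred` (held-out estimates) and
#'   `icc` (agreement of the estimates with `ahi_ref`).
#' @export
screen_cohort <- function(recordings, ahi_ref, n_hidden = 12L, nu = 1,
                          seed = 1L, features = NULL) {
  X <- if (is.null(features)) cohort_features(recordings) else features
  sel <- fcbf_select(X, ahi_ref)
  Xs <- X[, sel$selected, drop = FALSE]
  pred <- mlp_loocv(Xs, ahi_ref, n_hidden = n_hidden, nu = nu, seed = seed)
  list(features = X, fcbf = sel, pred = pred,
       icc = icc(ahi_ref, pred))
}
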