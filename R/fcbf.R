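#' Equal-frequency discretization
#'
#' Bins a continuous variable into `n_bins` labels of (near-)equal
#' occupancy. Ties are broken stably by original position, which makes the
#' labelling invariant to strictly monotone transformations of the values.
#' A constant vector collapses to a single label.
#'
#' @param values Numeric vector.
#' @param n_bins Number of bins (default 4).
#' @return Integer labels in `1:n_bins` (fewer for degenerate inputs).
#' @export
discretize <- function(values, n_bins = 4L) {
  x <- as.numeric(values)
  n <- length(x)
  if (n == 0L) stop("empty vector")
  if (length(unique(x)) == 1L) return(rep(1L, n))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / n))
}

#' Shannon entropy of a discrete label vector
#'
#' @param labels Vector of discrete labels.
#' @return Entropy in bits, `-sum(p * log2(p))`.
#' @export
shannon_entropy <- function(labels) {
  if (length(labels) == 0L) stop("empty vector")
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Symmetrical uncertainty between two discrete variables
#'
#' SU(X, Y) = 2 IG(X, Y) / (H(X) + H(Y)), where IG = H(X) - H(X|Y) is the
#' information gain (mutual information) and H is Shannon entropy. SU
#' normalizes IG to \[0, 1\], is symmetric in its arguments, equals 1 for
#' deterministically related non-constant variables and 0 for independent
#' ones. When both variables are constant SU is defined as 0.
#'
#' @param x_labels,y_labels Equal-length discrete label vectors.
#' @return SU in \[0, 1\].
#' @export
symmetrical_uncertainty <- function(x_labels, y_labels) {
  if (length(x_labels) != length(y_labels)) stop("label vectors differ in length")
  hx <- shannon_entropy(x_labels)
  hy <- shannon_entropy(y_labels)
  if (hx + hy == 0) return(0)
  hxy <- shannon_entropy(paste(x_labels, y_labels, sep = "\r"))
  ig <- hx + hy - hxy
  max(0, min(1, 2 * ig / (hx + hy)))
}

#' Fast correlation-based filter (FCBF)
#'
#' Two-stage filter selection by symmetrical uncertainty: (i) relevance —
#' every feature is ranked by its SU with the (discretized) target; (ii)
#' redundancy — scanning the ranking from the most relevant feature i
#' downward, any lower-ranked feature j with `SU(i, j) >= SU(j, target)` is
#' removed as redundant. The surviving features form the optimum subset.
#'
#' Continuous features and the continuous target (here the AHI) are
#' discretized by equal-frequency binning before entropies are computed.
#' No relevance threshold is applied beyond `SU > 0` (ranking plus the
#' redundancy stage does the pruning); ranking ties are broken stably by
#' original column order.
#'
#' @param X Numeric matrix or data.frame, one row per subject, one column
#'   per feature (named).
#' @param y Numeric target vector (reference AHI), length `nrow(X)`.
#' @param n_bins Equal-frequency bins for discretization (default 4).
#' @return An `fcbf_result`: list with `su_with_target` (named, input
#'   order), `ranking` (names by decreasing SU), `selected` (surviving
#'   names, decreasing SU), `removed` (named character vector: removed
#'   feature -> remover) and `n_input`.
#' @export
fcbf_select <- function(X, y, n_bins = 4L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two subjects")
  if (nrow(X) != length(y)) stop("feature matrix and target differ in length")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  lab <- apply(X, 2L, discretize, n_bins = n_bins)
  ylab <- discretize(y, n_bins = n_bins)
  su_y <- apply(lab, 2L, symmetrical_uncertainty, y_labels = ylab)
  ord <- order(-su_y, seq_along(su_y))  # stable: ties by column index
  ranking <- colnames(X)[ord]
  alive <- su_y[ord] > 0
  names(alive) <- ranking
  removed <- character(0)
  for (i in seq_along(ranking)) {
    if (!alive[i]) next
    fi <- ranking[i]
    js <- which(alive & seq_along(ranking) > i)
    for (j in js) {
      fj <- ranking[j]
      su_ij <- symmetrical_uncertainty(lab[, fi], lab[, fj])
      if (su_ij >= su_y[fj]) {
        alive[j] <- FALSE
        removed[fj] <- fi
      }
    }
  }
  structure(list(su_with_target = su_y,
                 ranking = ranking,
                 selected = ranking[alive],
                 removed = removed,
                 n_input = ncol(X)),
            class = "fcbf_result")
}

#' @export
print.fcbf_result <- function(x, ...) {
  cat(sprintf("<fcbf_result> %d/%d features selected: %s\n",
              length(x$selected), x$n_input, paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Serialize an FCBF result to JSON
#' @param x An `fcbf_result`.
#' @param path Output path.
#' @export
write_fcbf_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
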