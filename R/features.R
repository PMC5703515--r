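#' Split a signal into non-overlapping segments
#'
#' Time-domain and nonlinear measures are applied to non-overlapping
#' 512-sample segments of the cleaned series; a trailing remainder shorter
#' than the segment length is discarded.
#'
#' @param samples Numeric vector.
#' @param length Segment length in samples (default 512).
#' @return List of numeric segments (`floor(n / length)` of them).
#' @export
segment_signal <- function(samples, length = 512L) {
  n <- base::length(samples)
  k <- n %/% length
  if (k < 1L) stop("recording too short for segmental features (need >= ",
                   length, " samples, got ", n, ")")
  lapply(seq_len(k), function(i) samples[((i - 1L) * length + 1L):(i * length)])
}

# Population central moments with the usual standardization: mean, variance,
# skewness, kurtosis (Gaussian -> 3). Skewness/kurtosis of a constant are
# defined as 0.
moments4 <- function(x) {
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 <= .Machine$double.eps * max(1, mu^2)) {
    return(c(mu, 0, 0, 0))
  }
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  c(mu, m2, m3 / m2^1.5, m4 / m2^2)
}

#' First- to fourth-order time-domain moments
#'
#' Mean (M1t), variance (M2t), skewness (M3t) and kurtosis (M4t) of the
#' saturation amplitude histogram, computed per 512-sample segment and
#' averaged across segments (arithmetic mean). Kurtosis uses the
#' standardized fourth moment (Gaussian = 3); skewness and kurtosis of a
#' constant segment are 0.
#'
#' @param samples Preprocessed numeric series.
#' @param segment_length Segment length (default 512); set `NULL` to compute
#'   on the whole series without segmentation.
#' @return Named vector `M1t, M2t, M3t, M4t`.
#' @export
time_moments <- function(samples, segment_length = 512L) {
  segs <- if (is.null(segment_length)) list(samples)
          else segment_signal(samples, segment_length)
  m <- rowMeans(vapply(segs, moments4, numeric(4)))
  stats::setNames(m, c("M1t", "M2t", "M3t", "M4t"))
}

#' Welch power spectral density estimate
#'
#' Welch's averaged-periodogram method with a 512-sample Hann window, 50%
#' overlap and a 1024-point FFT. Each window is mean-detrended before
#' windowing so the estimate reflects saturation fluctuations, not the DC
#' level. The one-sided PSD uses density scaling, so
#' `sum(psd) * resolution` approximates the variance of the detrended
#' signal (Parseval).
#'
#' @param samples Numeric series (at least one window long).
#' @param fs Sampling rate in Hz (default 1).
#' @param window Window length (default 512).
#' @param nfft FFT length (default 1024).
#' @param overlap Fractional window overlap (default 0.5).
#' @return A `spectral_estimate`: list with `frequencies` (0 to Nyquist,
#'   `nfft/2 + 1` bins), `psd` and `resolution` (Hz).
#' @export
welch_psd <- function(samples, fs = 1, window = 512L, nfft = 1024L, overlap = 0.5) {
  x <- as.numeric(samples)
  n <- length(x)
  if (n < window) stop("recording too short for spectral estimation (need >= ",
                       window, " samples)")
  step <- max(1L, floor(window * (1 - overlap)))
  starts <- seq(1L, n - window + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(window) / (window + 1)))  # Hann
  u <- sum(w^2)
  nb <- nfft %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + window - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - window)))
    p <- Mod(X[seq_len(nb)])^2 / (fs * u)
    p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]   # one-sided: double interior bins
    acc <- acc + p
  }
  structure(list(frequencies = (seq_len(nb) - 1L) * fs / nfft,
                 psd = acc / length(starts),
                 resolution = fs / nfft),
            class = "spectral_estimate")
}

#' First- to fourth-order frequency-domain moments
#'
#' The PSD is normalized to unit sum and the histogram of its amplitude
#' values across bins is summarized by mean (M1f), variance (M2f), skewness
#' (M3f) and kurtosis (M4f), mirroring the time-domain moments. For a flat
#' normalized spectrum over N bins, M1f = 1/N and M2f = 0.
#'
#' @param psd A `spectral_estimate` from [welch_psd()].
#' @return Named vector `M1f, M2f, M3f, M4f`.
#' @export
freq_moments <- function(psd) {
  p <- psd$psd
  tot <- sum(p)
  if (tot <= 0) stop("empty spectrum")
  stats::setNames(moments4(p / tot), c("M1f", "M2f", "M3f", "M4f"))
}

#' Median frequency
#'
#' The smallest frequency at which cumulative spectral power reaches 50% of
#' the total.
#'
#' @param psd A `spectral_estimate`.
#' @return MF in Hz.
#' @export
median_frequency <- function(psd) {
  tot <- sum(psd$psd)
  if (tot <= 0) stop("empty spectrum")
  psd$frequencies[which(cumsum(psd$psd) >= 0.5 * tot)[1L]]
}

#' Spectral entropy
#'
#' Shannon entropy of the sum-normalized PSD divided by `log(N_bins)`, so a
#' flat spectrum scores 1 and a single-bin spectrum scores 0.
#'
#' @param psd A `spectral_estimate`.
#' @return SE in \[0, 1\].
#' @export
spectral_entropy <- function(psd) {
  tot <- sum(psd$psd)
  if (tot <= 0) stop("empty spectrum")
  q <- psd$psd / tot
  q <- q[q > 0]
  -sum(q * log(q)) / log(length(psd$psd))
}

#' Total, peak and relative spectral power in the apnea band
#'
#' Recurrent apneic desaturations concentrate spectral power in the
#' 0.014–0.033 Hz band (periods of roughly 30–70 s). Returns the total
#' integrated power PT (`sum(psd) * resolution`), the peak PSD amplitude PA
#' within the band (inclusive bounds), and the relative power PR = band
#' power / total power.
#'
#' @param psd A `spectral_estimate`.
#' @param band Numeric length-2 band in Hz (default `c(0.014, 0.033)`).
#' @return Named vector `PT, PA, PR`.
#' @export
band_powers <- function(psd, band = c(0.014, 0.033)) {
  tot <- sum(psd$psd)
  if (tot <= 0) stop("empty spectrum")
  inb <- psd$frequencies >= band[1L] & psd$frequencies <= band[2L]
  c(PT = tot * psd$resolution,
    PA = if (any(inb)) max(psd$psd[inb]) else 0,
    PR = sum(psd$psd[inb]) / tot)
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B and A count pairs of m- and
#' (m+1)-length templates matching within Chebyshev tolerance `r`
#' (self-matches excluded). Quantifies the irregularity of the series:
#' recurrent, self-similar desaturation patterns lower it. If no template
#' pair matches at length m (B = 0) the measure is undefined and is
#' returned as 0 with a warning (over-regular or constant signal).
#'
#' @param samples Numeric series of length > m + 1.
#' @param m Template length (default 1).
#' @param r Tolerance; interpreted as `r_frac * sd_ref` when `sd_ref` is
#'   supplied, else as an absolute tolerance.
#' @return SampEn in nats.
#' @export
sample_entropy <- function(samples, m = 1L, r = 0.25) {
  x <- as.numeric(samples)
  n <- length(x)
  if (n <= m + 1L) stop("series too short for sample entropy")
  if (r <= 0) { warning("non-positive tolerance; returning 0"); return(0) }
  # n - m template starts for both lengths (standard convention); matches
  # counted as unordered pairs with self-matches excluded
  nv <- n - m
  ok <- abs(outer(x[1:nv], x[1:nv], "-")) <= r
  if (m > 1L) for (k in 1L:(m - 1L)) {
    ok <- ok & (abs(outer(x[(1 + k):(nv + k)], x[(1 + k):(nv + k)], "-")) <= r)
  }
  B <- (sum(ok) - nv) / 2
  ok <- ok & (abs(outer(x[(1 + m):(nv + m)], x[(1 + m):(nv + m)], "-")) <= r)
  A <- (sum(ok) - nv) / 2
  if (B == 0) { warning("no template matches (B = 0); SampEn undefined, returning 0"); return(0) }
  if (A == 0) return(-log(1 / B))  # conventional cap when no (m+1)-matches
  -log(A / B)
}

#' Central tendency measure
#'
#' Fraction of second-order difference points
#' `(x[t+1] - x[t], x[t+2] - x[t+1])` that fall strictly inside the circle
#' of radius `rho` centred at the origin. A low-variability signal keeps its
#' consecutive changes small, so CTM is near 1; large swings push it to 0.
#'
#' @param samples Numeric series of length >= 3.
#' @param rho Radius in saturation percentage points (default 0.25).
#' @return CTM in \[0, 1\].
#' @export
central_tendency_measure <- function(samples, rho = 0.25) {
  x <- as.numeric(samples)
  if (length(x) < 3L) stop("series too short for CTM")
  d <- diff(x)
  n <- length(d) - 1L
  mean(sqrt(d[1:n]^2 + d[2:(n + 1L)]^2) < rho)
}

# LZ76 phrase count of a binary (0/1 integer) sequence, by the classic
# exhaustive-history parsing. Returns c(n), the number of phrases.
lz76_count <- function(s) {
  n <- length(s)
  if (n == 0L) return(0L)
  c_n <- 1L; i <- 0L; u <- 1L; v <- 1L; vmax <- 1L
  while (u + v <= n) {
    if (s[i + v] == s[u + v]) {
      v <- v + 1L
    } else {
      vmax <- max(v, vmax)
      i <- i + 1L
      if (i == u) {        # all positions tried: new phrase ends here
        c_n <- c_n + 1L
        u <- u + vmax
        i <- 0L; v <- 1L; vmax <- 1L
      } else {
        v <- 1L
      }
    }
  }
  if (v != 1L) c_n <- c_n + 1L
  c_n
}

#' Lempel-Ziv complexity
#'
#' The series is binarized at its median (values above the median map to 1)
#' and parsed by the LZ76 exhaustive-history scheme; the phrase count c(n)
#' is normalized by its asymptotic bound `n / log2(n)`, so a random binary
#' sequence approaches 1 while a constant or strictly periodic one tends to
#' 0 as n grows.
#'
#' @param samples Numeric series of length >= 2.
#' @param threshold Binarization threshold; default the median of `samples`.
#' @return Normalized LZC (>= 0).
#' @export
lempel_ziv_complexity <- function(samples, threshold = NULL) {
  x <- as.numeric(samples)
  n <- length(x)
  if (n < 2L) stop("series too short for LZC")
  if (is.null(threshold)) threshold <- stats::median(x)
  s <- as.integer(x > threshold)
  lz76_count(s) * log2(n) / n
}

#' Extract the 16 oximetric features
#'
#' Computes the full feature vector used to characterize one overnight
#' recording: time-domain moments M1t–M4t and nonlinear measures (SampEn,
#' CTM, LZC) per non-overlapping 512-sample segment, averaged across
#' segments; frequency-domain moments M1f–M4f, median frequency MF,
#' spectral entropy SE and the spectral measures PT, PA, PR from a single
#' whole-recording Welch PSD. The SampEn tolerance is `sampen_r` times the
#' standard deviation of the whole preprocessed recording.
#'
#' @param rec A preprocessed [spo2_recording()] or numeric vector (no
#'   missing values; at least 512 samples).
#' @param segment_length Segment length for segmental features (default 512).
#' @param sampen_m,sampen_r Sample-entropy template length and tolerance
#'   fraction of the recording SD (defaults 1 and 0.25).
#' @param ctm_rho CTM radius in percentage points (default 0.25).
#' @param band Spectral band of interest in Hz (default `c(0.014, 0.033)`).
#' @return Named numeric vector of the 16 features, class `feature_vector`.
#' @export
extract_features <- function(rec, segment_length = 512L, sampen_m = 1L,
                             sampen_r = 0.25, ctm_rho = 0.25,
                             band = c(0.014, 0.033)) {
  x <- if (inherits(rec, "spo2_recording")) rec$samples else as.numeric(rec)
  if (anyNA(x)) stop("recording contains missing samples; preprocess first")
  segs <- segment_signal(x, segment_length)
  tm <- time_moments(x, segment_length)
  sd_ref <- stats::sd(x)
  r_abs <- sampen_r * sd_ref
  se_vals <- vapply(segs, function(s) {
    if (r_abs <= 0) 0 else suppressWarnings(sample_entropy(s, m = sampen_m, r = r_abs))
  }, numeric(1))
  ctm_vals <- vapply(segs, central_tendency_measure, numeric(1), rho = ctm_rho)
  lzc_vals <- vapply(segs, lempel_ziv_complexity, numeric(1))
  psd <- welch_psd(x)
  fm <- freq_moments(psd)
  bp <- band_powers(psd, band)
  out <- c(tm, fm,
           MF = median_frequency(psd), SE = spectral_entropy(psd),
           PT = unname(bp["PT"]), PA = unname(bp["PA"]), PR = unname(bp["PR"]),
           SampEn = mean(se_vals), CTM = mean(ctm_vals), LZC = mean(lzc_vals))
  structure(out, class = c("feature_vector", "numeric"))
}

#' Feature names in canonical order
#' @return Character vector of the 16 feature names.
#' @export
feature_names <- function() {
  c("M1t", "M2t", "M3t", "M4t", "M1f", "M2f", "M3f", "M4f",
    "MF", "SE", "PT", "PA", "PR", "SampEn", "CTM", "LZC")
}

#' Write a feature matrix to CSV
#'
#' One row per recording, 16 named feature columns plus `subject_id`.
#'
#' @param features Matrix or data.frame with the 16 feature columns.
#' @param path Output path.
#' @param subject_ids Optional identifiers (row names used otherwise).
#' @export
write_features_csv <- function(features, path, subject_ids = NULL) {
  df <- as.data.frame(features)
  if (is.null(subject_ids)) subject_ids <- rownames(df)
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(df)))
  utils::write.csv(cbind(subject_id = subject_ids, df), path, row.names = FALSE)
  invisible(path)
}
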