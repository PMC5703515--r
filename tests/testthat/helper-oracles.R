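# Independent brute-force oracles and tiny fixture builders used across the
# suite. Each oracle is written as the most literal possible transcription
# of the definition, independent of the package's implementation path.

# SampEn by explicit O(N^2) template matching, plain loops.
brute_sampen <- function(x, m, r) {
  n <- length(x)
  count <- function(len) {
    tot <- 0L
    for (i in 1:(n - m)) {
      for (j in 1:(n - m)) {
        if (i == j) next
        if (i + len - 1 > n || j + len - 1 > n) next
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r) tot <- tot + 1L
      }
    }
    tot / 2
  }
  B <- count(m); A <- count(m + 1)
  if (B == 0) return(0)
  if (A == 0) return(-log(1 / B))
  -log(A / B)
}

# CTM by explicit point counting.
brute_ctm <- function(x, rho) {
  inside <- 0L
  for (t in 1:(length(x) - 2L)) {
    d1 <- x[t + 1L] - x[t]
    d2 <- x[t + 2L] - x[t + 1L]
    if (sqrt(d1^2 + d2^2) < rho) inside <- inside + 1L
  }
  inside / (length(x) - 2L)
}

# LZ76 phrase count by the alternative "longest reproducible extension"
# formulation: each new phrase is the shortest prefix of the remainder that
# is NOT a substring of the extended history.
brute_lz76 <- function(s) {
  str <- paste(s, collapse = "")
  n <- nchar(str)
  i <- 1L; cnt <- 0L
  while (i <= n) {
    l <- 1L
    while (i + l - 1L <= n) {
      phrase <- substr(str, i, i + l - 1L)
      hist <- substr(str, 1L, i + l - 2L)
      if (!grepl(phrase, hist, fixed = TRUE)) break
      l <- l + 1L
    }
    cnt <- cnt + 1L
    i <- i + l
  }
  cnt
}

# Symmetrical uncertainty from an explicit joint contingency table.
brute_su <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  ig <- H(px) + H(py) - H(as.vector(p))
  2 * ig / (H(px) + H(py))
}

# AUC by exhaustive positive-negative pair comparison.
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Folded empirical CDF by direct counting.
brute_mountain <- function(d) {
  n <- length(d)
  sapply(sort(d), function(v) {
    p <- 100 * sum(d <= v) / (n + 1)
    min(p, 100 - p)
  })
}

# Trapezoidal desaturation dip embedded in a constant-baseline signal.
make_dip <- function(baseline = 95, depth = 4, fall = 5, hold = 5, rise = 5,
                     pad = 150) {
  c(rep(baseline, pad),
    seq(baseline, baseline - depth, length.out = fall + 1L)[-1L],
    rep(baseline - depth, hold),
    seq(baseline - depth, baseline, length.out = rise + 1L)[-1L],
    rep(baseline, pad))
}

# Minimal EDF writer (16-bit, one data record per second block) used to
# exercise the package's reader round-trip; written at test time only.
write_edf_fixture <- function(path, samples, label = "SpO2",
                              extra_channel = FALSE) {
  n <- length(samples)
  ns <- if (extra_channel) 2L else 1L
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("sim subject", 80), pad("sim recording", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(as.character(256 * (1 + ns)), 8), pad("", 44),
                pad(as.character(n), 8), pad("1", 8), pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  labs <- c(label, if (extra_channel) "Pulse")
  f <- function(vals, w) for (v in vals) writeChar(pad(v, w), con, eos = NULL)
  f(labs, 16); f(rep("", ns), 80); f(rep("%", ns), 8)
  f(rep("0", ns), 8); f(rep("100", ns), 8)        # phys min/max
  f(rep("0", ns), 8); f(rep("1000", ns), 8)       # dig min/max
  f(rep("", ns), 80); f(rep("1", ns), 8); f(rep("", ns), 32)
  dig <- as.integer(round(samples * 10))
  pulse <- rep(600L, n)
  for (r in seq_len(n)) {
    writeBin(dig[r], con, size = 2, endian = "little")
    if (extra_channel) writeBin(pulse[r], con, size = 2, endian = "little")
  }
  invisible(path)
}
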