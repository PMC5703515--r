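#' Intraclass correlation coefficient
#'
#' Agreement between two continuous measurements of the same subjects
#' (here the reference AHI from polysomnography and an oximetric estimate).
#' The default is the single-measure, absolute-agreement, two-way
#' random-effects coefficient; `variant = "consistency"` gives the
#' two-way consistency coefficient instead. Confidence intervals use the
#' standard F-distribution method for each variant.
#'
#' @param a,b Equal-length numeric vectors (length >= 3).
#' @param variant `"agreement"` (default) or `"consistency"`.
#' @param conf Confidence level (default 0.95).
#' @return List with `icc`, `ci` (length-2), `variant` and the ANOVA mean
#'   squares.
#' @export
icc <- function(a, b, variant = c("agreement", "consistency"), conf = 0.95) {
  variant <- match.arg(variant)
  if (length(a) != length(b)) stop("vectors differ in length")
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired observations")
  Y <- cbind(a, b)
  if (stats::var(a) == 0 && stats::var(b) == 0) stop("zero variance in both measurements: ICC undefined")
  k <- 2
  row_m <- rowMeans(Y); col_m <- colMeans(Y); g <- mean(Y)
  ss_total <- sum((Y - g)^2)
  ss_rows <- k * sum((row_m - g)^2)
  ss_cols <- n * sum((col_m - g)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  alpha <- 1 - conf
  if (variant == "agreement") {
    val <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    aa <- (k * val) / (n * (1 - val))
    bb <- 1 + (k * val * (n - 1)) / (n * (1 - val))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else {
    val <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    df2 <- (n - 1) * (k - 1)
    f_l <- f_obs / stats::qf(1 - alpha / 2, n - 1, df2)
    f_u <- f_obs * stats::qf(1 - alpha / 2, df2, n - 1)
    lo <- (f_l - 1) / (f_l + k - 1)
    hi <- (f_u - 1) / (f_u + k - 1)
  }
  list(icc = val, ci = c(lo, hi), variant = variant,
       msr = msr, msc = msc, mse = mse, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean difference `mean(b - a)` (positive when method `b`
#' overestimates the reference `a`); the 95% limits of agreement are
#' `bias +/- 1.96 * sd(b - a)` and their width is `2 * 1.96 * sd`.
#'
#' @param a Reference measurements.
#' @param b Test measurements, same length (>= 2).
#' @return List with `bias`, `loa_low`, `loa_high`, `loa_width`, `sd_diff`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- b - a
  s <- stats::sd(d)
  bias <- mean(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       loa_width = 2 * 1.96 * s, sd_diff = s, mean_level = (a + b) / 2,
       differences = d)
}

#' Mountain (folded empirical CDF) plot data
#'
#' For each sorted difference the empirical percentile `p = 100 r / (n+1)`
#' (ties share the maximal rank) is folded as `min(p, 100 - p)`, producing
#' a curve that peaks at the median difference; a narrow, zero-centred
#' mountain indicates good agreement.
#'
#' @param differences Numeric vector of method differences (length >= 2).
#' @return data.frame with `difference`, `percentile`, `folded`, sorted by
#'   difference.
#' @export
mountain_plot <- function(differences) {
  d <- sort(as.numeric(differences))
  if (length(d) < 2L) stop("need at least 2 differences")
  n <- length(d)
  p <- 100 * rank(d, ties.method = "max") / (n + 1)
  data.frame(difference = d, percentile = p, folded = pmin(p, 100 - p))
}

ci_proportion <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  if (min(x, n - x) < 5) {                     # Wilson for sparse cells
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, ctr - hw), min(1, ctr + hw))
  } else {                                      # Wald
    hw <- z * sqrt(p * (1 - p) / n)
    c(max(0, p - hw), min(1, p + hw))
  }
}

#' Diagnostic metrics at a severity cutoff
#'
#' Dichotomizes both the estimated and the reference AHI at `cutoff`
#' (positive iff AHI >= cutoff) and reports sensitivity, specificity,
#' predictive values, likelihood ratios and accuracy, in percent with 95%
#' confidence intervals (Wald, switching to Wilson when a cell count is
#' below 5; likelihood-ratio CIs by the log method). When specificity is
#' 100% the positive likelihood ratio is undefined and flagged `NA`.
#'
#' @param pred_ahi Estimated AHI values.
#' @param true_ahi Reference AHI values, same length.
#' @param cutoff Severity cutoff in events/h (15 = moderate, 30 = severe).
#' @param conf Confidence level (default 0.95).
#' @return List with the confusion counts (`tp`, `fp`, `tn`, `fn`) and for
#'   each metric a value (%) and CI; `lr_pos`/`lr_neg` are ratios.
#' @export
confusion_metrics <- function(pred_ahi, true_ahi, cutoff, conf = 0.95) {
  if (length(pred_ahi) != length(true_ahi)) stop("vectors differ in length")
  if (cutoff <= 0) stop("cutoff must be positive")
  pp <- pred_ahi >= cutoff
  tt <- true_ahi >= cutoff
  tp <- sum(pp & tt); fp <- sum(pp & !tt)
  tn <- sum(!pp & !tt); fn <- sum(!pp & tt)
  n <- length(true_ahi)
  pct <- function(x, m) if (m == 0L) NA_real_ else 100 * x / m
  se <- pct(tp, tp + fn); sp <- pct(tn, tn + fp)
  ppv <- pct(tp, tp + fp); npv <- pct(tn, tn + fn)
  acc <- 100 * (tp + tn) / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lr_pos <- lr_pos_ci <- NA_real_
  lr_pos_defined <- FALSE
  if (!is.na(sp) && sp < 100 && !is.na(se)) {
    lr_pos <- (se / 100) / (1 - sp / 100)
    lr_pos_defined <- TRUE
    if (tp > 0 && fp > 0) {
      s <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
      lr_pos_ci <- c(lr_pos * exp(-z * s), lr_pos * exp(z * s))
    } else lr_pos_ci <- c(NA_real_, NA_real_)
  } else lr_pos_ci <- c(NA_real_, NA_real_)
  lr_neg <- if (!is.na(sp) && sp > 0 && !is.na(se)) (1 - se / 100) / (sp / 100) else NA_real_
  lr_neg_ci <- if (!is.na(lr_neg) && fn > 0 && tn > 0) {
    s <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
    c(lr_neg * exp(-z * s), lr_neg * exp(z * s))
  } else c(NA_real_, NA_real_)
  list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn, n = n,
       se = se, se_ci = 100 * ci_proportion(tp, tp + fn, conf),
       sp = sp, sp_ci = 100 * ci_proportion(tn, tn + fp, conf),
       ppv = ppv, ppv_ci = 100 * ci_proportion(tp, tp + fp, conf),
       npv = npv, npv_ci = 100 * ci_proportion(tn, tn + fn, conf),
       acc = acc, acc_ci = 100 * ci_proportion(tp + tn, n, conf),
       lr_pos = lr_pos, lr_pos_ci = lr_pos_ci, lr_pos_defined = lr_pos_defined,
       lr_neg = lr_neg, lr_neg_ci = lr_neg_ci)
}

#' Empirical ROC area under the curve
#'
#' AUC by the Mann-Whitney rank identity (equivalent to the trapezoidal
#' area of the empirical ROC curve sweeping all thresholds; ties handled by
#' rank averaging), with a Hanley-McNeil standard-error 95% CI. Also
#' returns the ROC curve points.
#'
#' @param scores Continuous scores (higher = more likely positive).
#' @param labels Logical or 0/1 class labels (both classes present).
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `ci` and `curve` (data.frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("vectors differ in length")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- t(vapply(th, function(t) {
    c(fpr = sum(scores[!labels] >= t) / n0, tpr = sum(scores[labels] >= t) / n1)
  }, numeric(2)))
  list(auc = auc, ci = c(max(0, auc - z * se), min(1, auc + z * se)),
       curve = as.data.frame(curve))
}

#' Sleep-apnea severity class from the AHI
#'
#' Standard categories: AHI < 5 normal, 5-15 mild, 15-30 moderate, >= 30
#' severe (lower bounds inclusive).
#'
#' @param ahi Nonnegative AHI value(s) in events/h.
#' @return Factor with levels `normal`, `mild`, `moderate`, `severe`.
#' @export
severity_class <- function(ahi) {
  if (any(ahi < 0)) stop("AHI must be nonnegative")
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Full agreement + diagnostic evaluation of an AHI estimator
#'
#' Convenience wrapper producing everything reported for one test group and
#' setting: ICC, Bland-Altman, mountain-plot data, and diagnostic metrics
#' plus AUC at each cutoff.
#'
#' @param true_ahi Reference AHI (polysomnography).
#' @param est_ahi Estimated AHI (oximetry).
#' @param cutoffs Severity cutoffs in events/h (default `c(15, 30)`).
#' @param icc_variant Passed to [icc()].
#' @return List with `icc`, `bland_altman`, `mountain` and `diagnostic`
#'   (one entry per cutoff, each with `metrics` and `auc`).
#' @export
evaluate_agreement <- function(true_ahi, est_ahi, cutoffs = c(15, 30),
                               icc_variant = "agreement") {
  diag <- lapply(cutoffs, function(cf) {
    list(metrics = confusion_metrics(est_ahi, true_ahi, cf),
         auc = roc_auc(est_ahi, true_ahi >= cf))
  })
  names(diag) <- paste0("cutoff", cutoffs)
  list(icc = icc(true_ahi, est_ahi, variant = icc_variant),
       bland_altman = bland_altman(true_ahi, est_ahi),
       mountain = mountain_plot(est_ahi - true_ahi),
       diagnostic = diag)
}
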