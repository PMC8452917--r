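# Validation statistics: Pearson correlation, Bland-Altman agreement,
# diagnostic accuracy at a binary threshold, and reproducibility indices
# (two-way mixed-effects absolute-agreement single-measure ICC; coefficient
# of variation of paired differences with a seeded bootstrap CI).

#' Pearson correlation of paired measurements
#'
#' @param x,y Numeric vectors of equal length (n >= 3) with non-zero
#'   variance.
#' @return A list with `r`, `p_value` (two-sided) and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop_coroflow("degenerate_input_error", "x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop_coroflow("insufficient_data_error", "need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_coroflow("degenerate_input_error", "zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `x - y`; the bias is their mean and the limits of
#' agreement are `bias +/- k * SD` (k = 1.96 for 95 % limits).
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @param k Limits-of-agreement multiplier.
#' @return An object of class `bland_altman` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n` and a `data` frame of pair means and
#'   differences for plotting.
#' @export
bland_altman <- function(x, y, k = 1.96) {
  if (length(x) != length(y))
    stop_coroflow("insufficient_data_error", "x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    stop_coroflow("insufficient_data_error", "need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - k * sd_diff, loa_high = bias + k * sd_diff,
                 k = k, n = length(d),
                 data = data.frame(mean = (x + y) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("mean difference %.3f, 95%% limits of agreement: %.3f, %.3f (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Diagnostic accuracy metrics against a reference standard
#'
#' @param predicted_positive Logical vector of test-positive calls.
#' @param truth_positive Logical vector of reference-positive states.
#' @return An object of class `diagnostic_metrics` with the 2x2 counts and
#'   sensitivity, specificity, PPV, NPV and accuracy in percent (full
#'   precision; rounding is presentation-only).
#' @export
diagnostic_metrics <- function(predicted_positive, truth_positive) {
  if (length(predicted_positive) != length(truth_positive) ||
      length(truth_positive) < 1L)
    stop_coroflow("insufficient_data_error",
                  "need equal-length non-empty flag vectors")
  p <- as.logical(predicted_positive); t <- as.logical(truth_positive)
  if (anyNA(p) || anyNA(t))
    stop_coroflow("degenerate_input_error", "flags must not contain NA")
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  if (tp + fn == 0L)
    stop_coroflow("undefined_metric_error",
                  "no reference positives: sensitivity undefined")
  if (tn + fp == 0L)
    stop_coroflow("undefined_metric_error",
                  "no reference negatives: specificity undefined")
  if (tp + fp == 0L)
    stop_coroflow("undefined_metric_error",
                  "no predicted positives: PPV undefined")
  if (tn + fn == 0L)
    stop_coroflow("undefined_metric_error",
                  "no predicted negatives: NPV undefined")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 ppv = 100 * tp / (tp + fp),
                 npv = 100 * tn / (tn + fn),
                 accuracy = 100 * (tp + tn) / length(p)),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.0f%%, sensitivity %.0f%%, specificity %.0f%%, PPV %.0f%%, NPV %.0f%% (TP %d FP %d FN %d TN %d)\n",
    x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv,
    x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Reproducibility of repeated measurements
#'
#' Computes the two-way mixed-effects, absolute-agreement, single-measure
#' intraclass correlation with its 95 % confidence interval (F-based),
#' the coefficient of variation defined as the SD of the paired
#' differences over the grand mean of all measurements (in percent) with a
#' seeded bootstrap CI, and the Bland-Altman analysis of the pairs.
#'
#' @param measurements_a,measurements_b Paired repeated measurements
#'   (n >= 3).
#' @param conf Confidence level.
#' @param n_boot Bootstrap resamples for the COV interval.
#' @param seed Seed for the bootstrap.
#' @return An object of class `repro_result` with `icc`, `icc_ci`,
#'   `cov_percent`, `cov_ci` and `bland_altman`.
#' @export
reproducibility_stats <- function(measurements_a, measurements_b,
                                  conf = 0.95, n_boot = 2000, seed = 1) {
  a <- measurements_a; b <- measurements_b
  if (length(a) != length(b) || length(a) < 3L)
    stop_coroflow("insufficient_data_error", "need at least 3 pairs")
  n <- length(a); k <- 2
  y <- cbind(a, b)
  gm <- mean(y)
  row_m <- rowMeans(y); col_m <- colMeans(y)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (denom <= 0) 1 else (msr - mse) / denom
  alpha <- 1 - conf
  icc_ci <- c(NA_real_, NA_real_)
  if (mse > 0 && icc < 1) {
    aa <- (k * icc) / (n * (1 - icc))
    bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    icc_ci <- c(
      n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
      n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr))
  } else if (icc == 1) {
    icc_ci <- c(1, 1)
  }
  cov_fun <- function(ai, bi) 100 * stats::sd(ai - bi) / mean(c(ai, bi))
  cov_pct <- cov_fun(a, b)
  cov_ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      cov_fun(a[idx], b[idx])
    }, numeric(1))
    stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                    na.rm = TRUE)
  })
  structure(list(icc = icc, icc_ci = icc_ci,
                 cov_percent = cov_pct, cov_ci = cov_ci,
                 bland_altman = bland_altman(a, b), n = n, conf = conf),
            class = "repro_result")
}

#' @export
print.repro_result <- function(x, ...) {
  cat(sprintf("ICC %.3f (95%% CI: %.3f, %.3f); COV %.2f%% (95%% CI: %.2f%%, %.2f%%)\n",
              x$icc, x$icc_ci[1], x$icc_ci[2],
              x$cov_percent, x$cov_ci[1], x$cov_ci[2]))
  print(x$bland_altman)
  invisible(x)
}

#' Read a paired-FFR table
#'
#' Expects columns `vessel_id`, `phase`, `ffr_invasive`, `ffr_b`, one row
#' per measurement.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_paired_ffr <- function(path) {
  if (!file.exists(path))
    stop_coroflow("parse_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "phase", "ffr_invasive", "ffr_b")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_coroflow("parse_error", "%s: missing column(s) %s", path,
                  paste(miss, collapse = ", "))
  df
}

#' Full agreement report for a paired-FFR table
#'
#' Per phase: Pearson correlation, Bland-Altman of model minus invasive
#' FFR, and diagnostic metrics of the model's ischemia call (FFR <=
#' `threshold`) against the invasive reference. Diagnostic metrics are
#' omitted (with a note) for phases where a 2x2 cell denominator is empty.
#'
#' @param paired A data.frame as returned by [read_paired_ffr()] or
#'   [generate_validation_cohort()].
#' @param threshold Ischemia threshold.
#' @return A named list of per-phase statistics.
#' @export
agreement_report <- function(paired, threshold = 0.80) {
  phases <- unique(paired$phase)
  out <- lapply(phases, function(ph) {
    d <- paired[paired$phase == ph, , drop = FALSE]
    diag <- tryCatch(
      diagnostic_metrics(d$ffr_b <= threshold, d$ffr_invasive <= threshold),
      coroflow_error = function(e) conditionMessage(e))
    list(n = nrow(d),
         pearson = tryCatch(pearson_r(d$ffr_b, d$ffr_invasive),
                            coroflow_error = function(e) conditionMessage(e)),
         bland_altman = bland_altman(d$ffr_b, d$ffr_invasive),
         diagnostics = diag)
  })
  stats::setNames(out, phases)
}
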