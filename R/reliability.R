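#' Dice similarity coefficient for one bone label
#'
#' \code{2|A∩B| / (|A|+|B|)} over the pixels carrying the given label in
#' each mask; defined as 1 when the label is absent from both.
#'
#' @param maskA,maskB Integer label masks of identical shape.
#' @param label Bone label.
#' @return Proportion in [0, 1].
#' @export
dice <- function(maskA, maskB, label) {
  if (!all(dim(maskA) == dim(maskB))) stop("mask shapes differ")
  a <- maskA == label; b <- maskB == label
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Two-way crossed mean squares (rows = subjects, cols = raters).
#' @keywords internal
anova_ms <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("ratings table contains missing values")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("ratings table must be at least 2 x 2")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm_ - gm)^2)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + gm)^2)
  ssw <- sum((x - rm_)^2)
  list(n = n, k = k,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), msw = ssw / (n * (k - 1)))
}

#' @keywords internal
icc_result <- function(estimate, ci, model, n, k, degenerate = FALSE) {
  structure(list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
                 model = model, n = n, k = k, degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s: %.3f (95%% CI %.3f-%.3f), n=%d k=%d [%s]\n",
              x$model, x$estimate, x$ci_low, x$ci_high, x$n, x$k,
              altman_band(x$estimate)))
  invisible(x)
}

#' One-way random single-measures ICC, ICC(1,1)
#'
#' Estimate \code{(MSB - MSW) / (MSB + (k-1) MSW)} from the one-way ANOVA
#' decomposition (subjects as the random grouping factor), the standard
#' model for intra-observer repeatability where sessions are not
#' identifiable levels. The 95% CI is the exact F interval: with
#' \code{F = MSB/MSW}, \code{FL = F / qf(.975, n-1, n(k-1))} and
#' \code{FU = F * qf(.975, n(k-1), n-1)}, the bounds are
#' \code{(FL-1)/(FL+k-1)} and \code{(FU-1)/(FU+k-1)}.
#'
#' A zero-variance table (all values equal) returns estimate 1 with a
#' degenerate CI and a warning: perfect agreement is the semantically
#' correct limit.
#'
#' @param x Numeric matrix, subjects x measurements (k >= 2 columns).
#' @param conf_level Confidence level.
#' @return \code{icc_result}.
#' @export
icc_oneway_single <- function(x, conf_level = 0.95) {
  ms <- anova_ms(x)
  n <- ms$n; k <- ms$k
  if (ms$msw < 1e-30 && ms$msr < 1e-30) {
    warning("zero-variance ratings table; returning degenerate ICC of 1")
    return(icc_result(1, c(1, 1), "oneway_random_single", n, k,
                      degenerate = TRUE))
  }
  msb <- ms$msr
  est <- (msb - ms$msw) / (msb + (k - 1) * ms$msw)
  alpha <- 1 - conf_level
  if (ms$msw < 1e-30) {
    warning("zero within-subject variance; returning degenerate ICC of 1")
    return(icc_result(1, c(1, 1), "oneway_random_single", n, k,
                      degenerate = TRUE))
  }
  F0 <- msb / ms$msw
  FL <- F0 / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  FU <- F0 * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  icc_result(est, c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1)),
             "oneway_random_single", n, k)
}

#' Two-way random single-measures absolute-agreement ICC, ICC(A,1)
#'
#' Estimate \code{(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))} from
#' the two-way crossed decomposition (rows = subjects, columns = raters,
#' both random), the standard model for inter-observer agreement where
#' systematic rater offsets count as disagreement. The 95% CI uses the
#' Satterthwaite-degrees-of-freedom F approximation of McGraw and Wong.
#'
#' @inheritParams icc_oneway_single
#' @return \code{icc_result}.
#' @export
icc_twoway_random_single <- function(x, conf_level = 0.95) {
  ms <- anova_ms(x)
  n <- ms$n; k <- ms$k
  denom <- ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse)
  if (abs(denom) < 1e-30) {
    warning("zero-variance ratings table; returning degenerate ICC of 1")
    return(icc_result(1, c(1, 1), "twoway_random_single_agreement", n, k,
                      degenerate = TRUE))
  }
  est <- (ms$msr - ms$mse) / denom
  alpha <- 1 - conf_level
  if (ms$mse < 1e-30 && ms$msc < 1e-30) {
    warning("zero rater and residual variance; degenerate CI")
    return(icc_result(est, c(est, est), "twoway_random_single_agreement",
                      n, k, degenerate = TRUE))
  }
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  F1 <- stats::qf(1 - alpha / 2, n - 1, v)
  lo <- n * (ms$msr - F1 * ms$mse) /
    (F1 * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  F2 <- stats::qf(1 - alpha / 2, v, n - 1)
  hi <- n * (F2 * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * F2 * ms$msr)
  icc_result(est, c(lo, hi), "twoway_random_single_agreement", n, k)
}

#' Paired bootstrap inference on an ICC difference
#'
#' Difference \code{ICC(B) - ICC(A)} between two ratings tables over the
#' same subjects (e.g. without vs with an assistance tool), with a
#' subject-level paired bootstrap: subjects are resampled with replacement
#' and both ICCs recomputed on each resample, which preserves the
#' within-subject correlation between the two conditions. The 95% CI is the
#' percentile interval and the two-sided p-value is
#' \code{2 min(P(diff <= 0), P(diff >= 0))} with the (b+1)/(B+1)
#' correction.
#'
#' @param tableA,tableB Numeric matrices, same subjects (rows) in the same
#'   order.
#' @param model "twoway" (default, \code{\link{icc_twoway_random_single}})
#'   or "oneway".
#' @param n_boot Bootstrap replications (>= 100).
#' @param rng_seed Integer seed; results are reproducible given it.
#' @return List with \code{difference}, \code{ci_low}, \code{ci_high},
#'   \code{p_value}, \code{icc_a}, \code{icc_b}, \code{n_boot},
#'   \code{n_failed} (resamples where an ICC was degenerate).
#' @export
icc_difference <- function(tableA, tableB, model = c("twoway", "oneway"),
                           n_boot = 2000, rng_seed = 1L) {
  model <- match.arg(model)
  tableA <- as.matrix(tableA); tableB <- as.matrix(tableB)
  if (nrow(tableA) != nrow(tableB)) {
    stop("tables must cover the same subjects (row counts differ)")
  }
  if (n_boot < 100) stop("n_boot must be >= 100")
  fn <- if (model == "twoway") icc_twoway_random_single else icc_oneway_single
  est <- function(a, b) {
    suppressWarnings(fn(b)$estimate - fn(a)$estimate)
  }
  d0 <- est(tableA, tableB)
  n <- nrow(tableA)
  with_seed(rng_seed, {
    diffs <- rep(NA_real_, n_boot)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      diffs[i] <- tryCatch(est(tableA[idx, , drop = FALSE],
                               tableB[idx, , drop = FALSE]),
                           error = function(e) NA_real_)
    }
    ok <- diffs[is.finite(diffs)]
    B <- length(ok)
    if (B < 100) stop("too many degenerate bootstrap resamples")
    ci <- unname(stats::quantile(ok, c(0.025, 0.975), type = 7))
    p <- 2 * min((sum(ok <= 0) + 1) / (B + 1), (sum(ok >= 0) + 1) / (B + 1))
    list(difference = d0, ci_low = ci[1], ci_high = ci[2],
         p_value = min(1, p),
         icc_a = suppressWarnings(fn(tableA)$estimate),
         icc_b = suppressWarnings(fn(tableB)$estimate),
         n_boot = n_boot, n_failed = n_boot - B)
  })
}

#' Altman agreement band for an ICC
#'
#' Half-open bands: (0.80, 1] "very good", (0.60, 0.80] "good",
#' (0.40, 0.60] "moderate"; values at or below 0.40 are labelled
#' "fair/poor", an extrapolation beyond the three named bands.
#'
#' @param icc ICC estimate.
#' @return Character label.
#' @export
altman_band <- function(icc) {
  stopifnot(is.finite(icc), icc <= 1)
  if (icc > 0.80) "very good"
  else if (icc > 0.60) "good"
  else if (icc > 0.40) "moderate"
  else "fair/poor"
}

#' @keywords internal
wald_ci_pct <- function(successes, m, conf_level = 0.95) {
  if (m == 0) return(c(NA_real_, NA_real_))
  p <- successes / m
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(p * (1 - p) / m)
  100 * c(max(0, p - half), min(1, p + half))
}

#' Diagnostic metrics with Wald confidence intervals
#'
#' Sensitivity, specificity and accuracy (percent) of a binary prediction
#' against truth, each with a 95% Wald normal-approximation interval
#' \code{p ± 1.96 sqrt(p(1-p)/m)} clipped to [0, 100]. A metric whose
#' denominator is empty (truth lacks that class) is reported as NA.
#'
#' @param predicted,truth Logical vectors of equal length (TRUE = pes
#'   planus).
#' @return Object of class \code{diagnostic_summary}: counts \code{tp},
#'   \code{fn}, \code{tn}, \code{fp} and rows \code{sensitivity},
#'   \code{specificity}, \code{accuracy} each with \code{estimate},
#'   \code{ci_low}, \code{ci_high}.
#' @export
diagnostic_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  if (any(is.na(predicted)) || any(is.na(truth))) stop("NA labels")
  diagnostic_from_counts(tp = sum(predicted & truth),
                         fn = sum(!predicted & truth),
                         tn = sum(!predicted & !truth),
                         fp = sum(predicted & !truth))
}

#' Diagnostic metrics from confusion-matrix counts
#'
#' @param tp,fn,tn,fp Non-negative counts.
#' @return \code{diagnostic_summary}; see \code{\link{diagnostic_metrics}}.
#' @export
diagnostic_from_counts <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  pos <- tp + fn; neg <- tn + fp; tot <- pos + neg
  if (tot == 0) stop("no observations")
  metric <- function(s, m) {
    if (m == 0) {
      return(c(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    }
    ci <- wald_ci_pct(s, m)
    c(estimate = 100 * s / m, ci_low = ci[1], ci_high = ci[2])
  }
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = metric(tp, pos),
                 specificity = metric(tn, neg),
                 accuracy = metric(tp + tn, tot)),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("<diagnostic_summary> tp=%d fn=%d tn=%d fp=%d\n",
              x$tp, x$fn, x$tn, x$fp))
  for (nm in c("sensitivity", "specificity", "accuracy")) {
    v <- x[[nm]]
    if (is.na(v["estimate"])) {
      cat(sprintf("  %-12s undefined (empty class)\n", nm))
    } else {
      cat(sprintf("  %-12s %6.2f%% (%.2f-%.2f)\n", nm, v["estimate"],
                  v["ci_low"], v["ci_high"]))
    }
  }
  invisible(x)
}

#' Pool diagnostic summaries across readers (micro-average)
#'
#' Sums the confusion-matrix counts across readers and recomputes the
#' metrics and Wald intervals on the pooled counts — the combined-readers
#' row of a multi-reader validation table.
#'
#' @param summaries Non-empty list of \code{diagnostic_summary} objects.
#' @return Pooled \code{diagnostic_summary}.
#' @export
pool_readers <- function(summaries) {
  if (length(summaries) == 0) stop("empty summary list")
  stopifnot(all(vapply(summaries, inherits, logical(1),
                       "diagnostic_summary")))
  tot <- function(f) sum(vapply(summaries, `[[`, numeric(1), f))
  diagnostic_from_counts(tot("tp"), tot("fn"), tot("tn"), tot("fp"))
}

#' Paired bootstrap comparison of a diagnostic metric between two readings
#'
#' Resamples subjects with replacement, recomputes the chosen metric under
#' both prediction sets on each resample, and derives a two-sided p-value
#' from the bootstrap distribution of the difference (as in
#' \code{\link{icc_difference}}). Resamples where the metric is undefined
#' (a class absent from the resampled truth) are skipped and counted.
#'
#' @param predictedA,predictedB,truth Logical vectors on the same subjects.
#' @param metric "sensitivity", "specificity" or "accuracy".
#' @param n_boot Bootstrap replications.
#' @param rng_seed Integer seed.
#' @return List with \code{difference} (B - A, percentage points),
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{n_boot},
#'   \code{n_skipped}.
#' @export
compare_paired_bootstrap <- function(predictedA, predictedB, truth,
                                     metric = c("sensitivity", "specificity",
                                                "accuracy"),
                                     n_boot = 1000, rng_seed = 1L) {
  metric <- match.arg(metric)
  nA <- length(predictedA)
  if (length(predictedB) != nA || length(truth) != nA) {
    stop("vectors must have equal length")
  }
  predictedA <- as.logical(predictedA)
  predictedB <- as.logical(predictedB)
  truth <- as.logical(truth)
  mfun <- function(pred, tr) {
    s <- diagnostic_metrics(pred, tr)[[metric]]
    unname(s["estimate"])
  }
  d0 <- mfun(predictedB, truth) - mfun(predictedA, truth)
  with_seed(rng_seed, {
    diffs <- rep(NA_real_, n_boot)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(nA, nA, replace = TRUE)
      a <- mfun(predictedA[idx], truth[idx])
      b <- mfun(predictedB[idx], truth[idx])
      diffs[i] <- b - a
    }
    ok <- diffs[is.finite(diffs)]
    B <- length(ok)
    if (B == 0) stop("metric undefined in every bootstrap resample")
    ci <- unname(stats::quantile(ok, c(0.025, 0.975), type = 7))
    p <- 2 * min((sum(ok <= 0) + 1) / (B + 1), (sum(ok >= 0) + 1) / (B + 1))
    list(difference = d0, ci_low = ci[1], ci_high = ci[2],
         p_value = min(1, p), n_boot = n_boot, n_skipped = n_boot - B)
  })
}
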