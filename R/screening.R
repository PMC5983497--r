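# Screening statistics: Pearson correlation, population outlier exclusion,
# discrimination-limit classification, threshold scan, stepwise regression.

#' Single-pass population outlier exclusion
#'
#' Drops values deviating more than `k` standard deviations from the
#' population mean. One pass only: the mean and SD are computed once over all
#' values (SD with denominator n) and never re-estimated after removal.
#' A zero-SD (all-equal) input retains every index.
#'
#' @param values numeric vector of per-subject mean intensities (length >= 3).
#' @param k SD multiplier (> 0, default 3).
#' @return integer vector of retained indices.
#' @examples
#' exclude_outliers(c(100, 101, 99, 100, 300))  # SD ~ 80: all retained
#' @export
exclude_outliers <- function(values, k = 3) {
  if (length(values) < 3) stopf("exclude_outliers: need at least 3 values")
  if (!is.numeric(k) || k <= 0) stopf("exclude_outliers: 'k' must be > 0")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))  # population SD, denominator n
  if (s == 0) return(seq_along(values))
  which(abs(values - m) <= k * s)
}

#' Pearson correlation with two-sided t-test
#'
#' Sample Pearson correlation between channel intensities and TsB, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` against
#' Student's t with n - 2 degrees of freedom. Exact |r| = 1 gives p = 0.
#'
#' @param x,y equal-length numeric vectors (n >= 3), neither constant.
#' @param channel optional channel label carried into the result.
#' @return object of class `correlation_result`: list with `channel`, `r`,
#'   `p_value`, `n`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))$r  # 0.6
#' @export
pearson <- function(x, y, channel = NA_character_) {
  n <- length(x)
  if (length(y) != n) stopf("pearson: 'x' and 'y' must have equal length")
  if (n < 3) stopf("pearson: need at least 3 observations")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stopf("pearson: correlation undefined for a constant input")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(min(r, 1), -1)
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(channel = channel, r = r, p_value = p, n = n),
            class = "correlation_result")
}

#' Per-channel intensity/TsB correlations
#'
#' Joins extracted channel summaries to the subject table on `subject_id` and
#' computes [pearson()] per channel between the mean intensity and TsB.
#' Subjects without a TsB value are dropped.
#'
#' @param summaries stacked [extract_intensity()] rows.
#' @param subjects cohort data.frame with `subject_id` and `tsb_umol_l`.
#' @param statistic which summary column to correlate (default `"mean"`).
#' @return data.frame with columns `channel`, `r`, `p_value`, `n`.
#' @export
correlate_channels <- function(summaries, subjects, statistic = "mean") {
  out <- lapply(c("red", "green", "blue"), function(ch) {
    s <- summaries[summaries$channel == ch, c("subject_id", statistic)]
    d <- merge(s, subjects[, c("subject_id", "tsb_umol_l")], by = "subject_id")
    d <- d[!is.na(d$tsb_umol_l), ]
    cr <- pearson(d[[statistic]], d$tsb_umol_l, channel = ch)
    data.frame(channel = ch, r = cr$r, p_value = cr$p_value, n = cr$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify subjects at a discrimination limit and score the screen
#'
#' A subject screens positive when the channel intensity is strictly above
#' `limit`; the condition is positive when TsB is strictly above
#' `clinical_threshold` (boundary subjects are negative on both sides).
#' Sensitivity is `100 * tp / (tp + fn)` and specificity
#' `100 * tn / (tn + fp)`, in percent. With no condition-positive subjects
#' sensitivity is undefined and returned as `NA` with
#' `sensitivity_defined = FALSE` -- never 0 or 100; likewise for specificity.
#'
#' @param intensities per-subject mean channel intensities (0-255).
#' @param tsb per-subject TsB, umol/L.
#' @param limit intensity discrimination limit in [0, 255].
#' @param clinical_threshold TsB threshold defining the condition, umol/L
#'   (default 205, a conventional warning level for a term newborn).
#' @return object of class `screening_result`: `confusion` (tp, fp, tn, fn,
#'   discrimination_limit, clinical_threshold), `sensitivity`, `specificity`,
#'   `sensitivity_defined`, `specificity_defined`.
#' @examples
#' # 26 subjects above limit 212 (11 with TsB > 205), 25 below all <= 205:
#' ints <- c(rep(220, 26), rep(200, 25))
#' tsb <- c(rep(250, 11), rep(150, 15), rep(150, 25))
#' classify_and_score(ints, tsb, limit = 212)
#' @export
classify_and_score <- function(intensities, tsb, limit,
                               clinical_threshold = 205) {
  if (length(intensities) != length(tsb))
    stopf("classify_and_score: input lengths differ")
  if (limit < 0 || limit > 255)
    stopf("classify_and_score: 'limit' must lie in [0, 255]")
  test_pos <- intensities > limit
  cond_pos <- tsb > clinical_threshold
  tp <- sum(test_pos & cond_pos); fp <- sum(test_pos & !cond_pos)
  tn <- sum(!test_pos & !cond_pos); fn <- sum(!test_pos & cond_pos)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  structure(list(
    confusion = list(tp = tp, fp = fp, tn = tn, fn = fn,
                     discrimination_limit = limit,
                     clinical_threshold = clinical_threshold),
    sensitivity = sens, specificity = spec,
    sensitivity_defined = tp + fn > 0,
    specificity_defined = tn + fp > 0), class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cf <- x$confusion
  cat(sprintf("<screening_result> limit %s, TsB threshold %s umol/L\n",
              format(cf$discrimination_limit), format(cf$clinical_threshold)))
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d\n", cf$tp, cf$fp, cf$tn, cf$fn))
  cat(sprintf("  sensitivity %s%%  specificity %s%%\n",
              if (x$sensitivity_defined) format(round(x$sensitivity, 1)) else "undefined",
              if (x$specificity_defined) format(round(x$specificity, 1)) else "undefined"))
  invisible(x)
}

#' Scan candidate discrimination limits
#'
#' Applies [classify_and_score()] at every limit in `limits` and reports the
#' largest limit that still achieves 100% sensitivity -- the selection rule
#' implied by choosing the highest cut-off that misses no case of the
#' condition. Sensitivity is monotone non-increasing, and specificity monotone
#' non-decreasing, in the limit.
#'
#' @param intensities,tsb,clinical_threshold as [classify_and_score()].
#' @param limits integer intensity grid (default 0:255).
#' @return list of class `threshold_scan`: `scan` (data.frame with one row per
#'   limit: `limit`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`) and
#'   `chosen_limit` (largest limit with sensitivity 100, or `NA` if none).
#' @export
threshold_scan <- function(intensities, tsb, clinical_threshold = 205,
                           limits = 0:255) {
  rows <- lapply(limits, function(L) {
    s <- classify_and_score(intensities, tsb, L, clinical_threshold)
    data.frame(limit = L, tp = s$confusion$tp, fp = s$confusion$fp,
               tn = s$confusion$tn, fn = s$confusion$fn,
               sensitivity = s$sensitivity, specificity = s$specificity)
  })
  scan <- do.call(rbind, rows)
  full <- scan$limit[!is.na(scan$sensitivity) & scan$sensitivity == 100]
  structure(list(scan = scan,
                 chosen_limit = if (length(full)) max(full) else NA_integer_),
            class = "threshold_scan")
}

#' Stepwise forward multiple linear regression
#'
#' Ordinary-least-squares forward selection: at each step the candidate with
#' the smallest partial-F p-value joins the model if that p-value is below
#' `entry_alpha`; selection stops when no candidate qualifies. Ties are broken
#' by candidate order (first listed wins). The partial F for a single added
#' term uses `F = (RSS0 - RSS1) / (RSS1 / (n - k - 1))` with 1 and n - k - 1
#' degrees of freedom; an exact fit (RSS1 = 0) enters with p = 0.
#'
#' @param y numeric response (e.g. TsB, or a channel intensity).
#' @param candidates data.frame or matrix of candidate covariate columns
#'   (channel intensities, demographic and clinical variables). Columns must
#'   be non-constant and not collinear.
#' @param entry_alpha entry criterion on the partial-F p-value (default 0.05,
#'   the conventional default).
#' @return object of class `regression_model`: `selected_terms` (in entry
#'   order), `coefficients` (final OLS fit, including intercept),
#'   `entry_p_values`, `n`, `entry_alpha`.
#' @export
stepwise_forward <- function(y, candidates, entry_alpha = 0.05) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 2)
    stopf("stepwise_forward: need n > number of candidates + 2 (n=%d, p=%d)", n, p)
  csd <- apply(X, 2, stats::sd)
  if (any(csd == 0))
    stopf("stepwise_forward: constant candidate column '%s'",
          colnames(X)[which(csd == 0)[1]])
  if (p >= 2) {
    cc <- stats::cor(X)
    cc[upper.tri(cc, diag = TRUE)] <- 0
    bad <- which(abs(cc) > 1 - 1e-8, arr.ind = TRUE)
    if (nrow(bad))
      stopf("stepwise_forward: collinear candidates '%s' and '%s'",
            colnames(X)[bad[1, 2]], colnames(X)[bad[1, 1]])
  }
  rss <- function(design) {
    fit <- stats::lm.fit(design, y)
    sum(fit$residuals^2)
  }
  selected <- character(0)
  entry_p <- numeric(0)
  design <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  rss0 <- rss(design)
  remaining <- colnames(X)
  repeat {
    if (!length(remaining)) break
    k <- ncol(design)              # parameters currently in the model
    df2 <- n - k - 1
    if (df2 <= 0) break
    pvals <- vapply(remaining, function(nm) {
      rss1 <- rss(cbind(design, X[, nm]))
      if (rss1 < 1e-12 * max(rss0, 1)) return(0)
      f <- (rss0 - rss1) / (rss1 / df2)
      stats::pf(max(f, 0), 1, df2, lower.tail = FALSE)
    }, numeric(1))
    best <- which.min(pvals)       # ties: first candidate in order wins
    if (pvals[best] >= entry_alpha) break
    nm <- remaining[best]
    design <- cbind(design, X[, nm, drop = FALSE])
    colnames(design)[ncol(design)] <- nm
    selected <- c(selected, nm)
    entry_p <- c(entry_p, unname(pvals[best]))
    rss0 <- rss(design)
    remaining <- setdiff(remaining, nm)
  }
  fit <- stats::lm.fit(design, y)
  structure(list(selected_terms = selected,
                 coefficients = fit$coefficients,
                 entry_p_values = entry_p, n = n, entry_alpha = entry_alpha),
            class = "regression_model")
}
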