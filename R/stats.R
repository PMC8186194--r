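#' Bland-Altman agreement analysis
#'
#' For paired measurements (a, b) of the same quantity, computes the bias
#' (mean difference), the SD of the differences, limits of agreement
#' (bias +/- 1.96 SD, the interval expected to contain ~95\% of differences
#' under normality) and the coefficient of variation.
#'
#' Two difference scales are in clinical use and both are provided:
#' `units_mode = "percent"` (default) works on relative differences
#' `d_i = 100 (a_i - b_i) / ((a_i + b_i) / 2)` so bias and limits are
#' percentages of the pair mean; `"absolute"` works on raw differences.
#' The CV is, in both modes, the SD of the raw (absolute-units, signed)
#' differences divided by the grand mean of all 2n values, times 100 —
#' the agreement index conventional in CTR method-comparison studies
#' (lower CV, better agreement).
#'
#' @param a,b numeric vectors of equal length (> 0 values, n >= 2).
#' @param units_mode `"percent"` or `"absolute"`.
#' @return An object of class `agreement_result`: list with `bias`,
#'   `loa_lower`, `loa_upper`, `sd_diff`, `cv`, `n_pairs`, `units_mode`.
#' @examples
#' bland_altman(c(0.50, 0.60, 0.55), c(0.52, 0.58, 0.55))
#' @export
bland_altman <- function(a, b, units_mode = c("percent", "absolute")) {
  units_mode <- match.arg(units_mode)
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) stop("insufficient data: need at least 2 complete pairs")
  if (any(a <= 0) || any(b <= 0))
    stop("domain error: all measurements must be positive")
  d <- if (units_mode == "percent") 100 * (a - b) / ((a + b) / 2) else a - b
  bias <- mean(d)
  sd_d <- sd(d)
  cv <- 100 * sd(a - b) / mean(c(a, b))
  structure(list(bias = bias, loa_lower = bias - 1.96 * sd_d,
                 loa_upper = bias + 1.96 * sd_d, sd_diff = sd_d, cv = cv,
                 n_pairs = n, units_mode = units_mode),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  u <- if (x$units_mode == "percent") "%" else ""
  cat(sprintf("Bland-Altman (n=%d): bias %.2f%s, LoA (%.2f, %.2f)%s, CV %.2f%%\n",
              x$n_pairs, x$bias, u, x$loa_lower, x$loa_upper, u, x$cv))
  invisible(x)
}

#' Coefficient of variation between two paired measurement series
#'
#' SD of the signed pairwise differences divided by the grand mean of all
#' values, expressed as a percentage.  Invariant to common rescaling of both
#' series.
#'
#' @inheritParams bland_altman
#' @return CV in percent (scalar).
#' @export
cv_percent <- function(a, b) bland_altman(a, b)$cv

#' Linear fit and coefficient of determination
#'
#' Ordinary least-squares fit of y on x with R^2 = 1 - SS_res/SS_tot, banded
#' into the conventional association categories: poor (< 0.5), moderate
#' (0.5-0.75), good (0.75-0.9), excellent (> 0.9); boundary values fall in
#' the lower band (0.75 is moderate, 0.9 is good).  R^2 measures linear
#' association, not agreement — see [bland_altman()] for agreement.
#'
#' @param x,y numeric vectors (n >= 3, x non-degenerate).
#' @return An object of class `correlation_result`: list with `slope`,
#'   `intercept`, `r2`, `category`, `n`.
#' @export
linear_fit_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("insufficient data: need at least 3 complete pairs")
  if (sd(x) == 0) stop("degenerate input: x has zero variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  category <- if (r2 < 0.5) "poor" else if (r2 <= 0.75) "moderate"
              else if (r2 <= 0.9) "good" else "excellent"
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 category = category, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("linear fit (n=%d): y = %.4f + %.4f x, R2 %.4f (%s)\n",
              x$n, x$intercept, x$slope, x$r2, x$category))
  invisible(x)
}

#' Paired Student's t-test
#'
#' Two-sided paired t on the differences.  Zero-variance differences are
#' reported explicitly rather than erroring silently: all-zero differences
#' give t = 0, p = 1 (no effect by convention); a nonzero constant
#' difference gives infinite t, p = 0; both are flagged `degenerate`.
#'
#' @param a,b numeric vectors of equal length (n >= 2).
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  d <- (a - b)[keep]
  n <- length(d)
  if (n < 2L) stop("insufficient data: need at least 2 complete pairs")
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0,
                            degenerate = TRUE))
    return(list(t = sign(m) * Inf, p = 0, df = n - 1L, mean_diff = m,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1L), df = n - 1L,
       mean_diff = m, degenerate = FALSE)
}

#' Evaluate a binary cardiomegaly classification at a fixed CTR cutoff
#'
#' A case is called positive when its value exceeds the cutoff (strictly:
#' CTR > 0.5 indicates cardiomegaly by convention).  AUC is computed by the
#' rank statistic (probability a random positive outranks a random negative,
#' ties counting one half) and is independent of the cutoff.
#'
#' @param values numeric measurement vector.
#' @param labels binary ground truth (0/1 or logical), both classes present.
#' @param cutoff decision threshold.
#' @param cutoff_kind label: `"standard"`, `"optimum"` or
#'   `"max_sensitivity"`.
#' @return An object of class `classification_result`: list with `cutoff`,
#'   `sensitivity`, `specificity`, `accuracy` (percent), `f1`, `auc`
#'   (fractions), `cutoff_kind`.
#' @export
classification_eval <- function(values, labels, cutoff,
                                cutoff_kind = "standard") {
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels),
            all(labels %in% c(0L, 1L)))
  keep <- is.finite(values)
  values <- values[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    stop("undefined metric: both classes must be present")
  pos <- labels == 1L
  pred <- values > cutoff
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / length(values)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  # Mann-Whitney rank AUC with midranks for ties
  r <- rank(values)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(cutoff = cutoff, sensitivity = sens, specificity = spec,
                 accuracy = acc, f1 = f1, auc = auc,
                 cutoff_kind = cutoff_kind),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "%s cutoff %.3f: sens %.1f%%, spec %.1f%%, acc %.1f%%, F1 %.3f, AUC %.3f\n",
    x$cutoff_kind, x$cutoff, x$sensitivity, x$specificity, x$accuracy,
    x$f1, x$auc))
  invisible(x)
}

# Candidate thresholds: midpoints between adjacent sorted unique values,
# with sentinels just below the minimum and at the maximum.
roc_candidates <- function(values) {
  u <- sort(unique(values))
  c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, u[length(u)])
}

#' Cutoff selection: standard, Youden optimum and maximum sensitivity
#'
#' Evaluates the classification at three cutoffs: the standard clinical 0.5;
#' the optimum maximising Youden's J = sensitivity + specificity - 1 over
#' candidate thresholds (midpoints between adjacent sorted unique values,
#' plus sentinels; ties broken toward the lowest cutoff, favouring
#' sensitivity); and the maximum-sensitivity cutoff, the largest candidate
#' with sensitivity exactly 100\% (the rule-out threshold: no positive case
#' is missed).
#'
#' @inheritParams classification_eval
#' @param standard the standard cutoff; default 0.5.
#' @return List of three `classification_result` objects: `standard`,
#'   `optimum`, `max_sensitivity`.
#' @export
find_cutoffs <- function(values, labels, standard = 0.5) {
  labels <- as.integer(labels)
  keep <- is.finite(values)
  values <- values[keep]; labels <- labels[keep]
  cand <- roc_candidates(values)
  evals <- lapply(cand, function(ct) classification_eval(values, labels, ct))
  j <- vapply(evals, function(e) e$sensitivity + e$specificity - 100,
              numeric(1))
  sens <- vapply(evals, function(e) e$sensitivity, numeric(1))
  i_opt <- which(j >= max(j) - 1e-9)[1L]          # lowest cutoff among ties
  i_max <- max(which(sens >= 100 - 1e-9))          # largest 100%-sens cutoff
  opt <- evals[[i_opt]]; opt$cutoff_kind <- "optimum"
  mx <- evals[[i_max]]; mx$cutoff_kind <- "max_sensitivity"
  class(opt) <- class(mx) <- "classification_result"
  list(standard = classification_eval(values, labels, standard, "standard"),
       optimum = opt, max_sensitivity = mx)
}

# Resolve one measurement series from a study table.
# spec: "manual" / "ai_only" / "ai_assisted" / "reference"  -> consensus
#       (or the single record for single-record methods);
#       "method/observer/replicate" -> that exact series.
resolve_series <- function(measurements, spec) {
  parts <- strsplit(spec, "/", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) {
    sub <- measurements[measurements$method == parts, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty comparison: no records for ", spec)
    cons <- consensus_values(sub, parts)
    cons$values
  } else if (length(parts) == 3L) {
    sub <- measurements[measurements$method == parts[1L] &
                        measurements$observer_id == parts[2L] &
                        measurements$replicate == as.integer(parts[3L]) &
                        !measurements$failed, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty comparison: no records for ", spec)
    data.frame(case_id = sub$case_id, ctr = sub$ctr, stringsAsFactors = FALSE)
  } else stop("input error: series spec must be 'method' or ",
              "'method/observer/replicate'")
}

#' Compare two measurement series: agreement, correlation and paired t
#'
#' Joins two series on case id (optionally restricted to one diagnostic
#' group), then reports the Bland-Altman agreement, the linear fit with R^2
#' and the paired t-test as one consolidated row — the layout of a
#' method-comparison table.  Series specs name either a method (consensus or
#' single-record value) like `"manual"`, or an exact observer series like
#' `"manual/obs1/1"`.
#'
#' @param measurements a measurement data.frame (all methods stacked).
#' @param spec_a,spec_b series specifications (see Details).
#' @param cases optional case table with `case_id` and `group`, required for
#'   `subset != "all"`.
#' @param subset `"all"`, `"cardiomegaly"` or `"normal"`.
#' @return An object of class `comparison_row`: a one-row data.frame with
#'   comparison, subset, n, bias, loa_lower, loa_upper, cv, r2, r2_category,
#'   t, p, n_excluded.
#' @export
compare_methods <- function(measurements, spec_a, spec_b, cases = NULL,
                            subset = c("all", "cardiomegaly", "normal")) {
  subset <- match.arg(subset)
  sa <- resolve_series(measurements, spec_a)
  sb <- resolve_series(measurements, spec_b)
  if (subset != "all") {
    if (is.null(cases))
      stop("input error: a case table is required for group subsets")
    ids <- cases$case_id[cases$group == subset]
    sa <- sa[sa$case_id %in% ids, , drop = FALSE]
    sb <- sb[sb$case_id %in% ids, , drop = FALSE]
  }
  m <- merge(sa, sb, by = "case_id", suffixes = c("_a", "_b"))
  n_union <- length(union(sa$case_id, sb$case_id))
  if (nrow(m) == 0L) stop("empty comparison: no overlapping cases")
  ba <- bland_altman(m$ctr_a, m$ctr_b)
  fit <- linear_fit_r2(m$ctr_a, m$ctr_b)
  tt <- paired_t_test(m$ctr_a, m$ctr_b)
  out <- data.frame(comparison = paste(spec_a, "vs", spec_b),
                    subset = subset, n = nrow(m), bias = ba$bias,
                    loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
                    cv = ba$cv, r2 = fit$r2, r2_category = fit$category,
                    t = tt$t, p = tt$p,
                    n_excluded = n_union - nrow(m),
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_row", "data.frame")
  out
}

#' Bland-Altman and scatter plots for a comparison
#'
#' Writes a two-panel PNG: scatter of the two series with the identity line
#' and the least-squares fit, and the Bland-Altman plot (percent differences
#' against pair means) with bias and limits of agreement.
#'
#' @inheritParams compare_methods
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
plot_comparison <- function(measurements, spec_a, spec_b, path,
                            cases = NULL,
                            subset = c("all", "cardiomegaly", "normal")) {
  subset <- match.arg(subset)
  sa <- resolve_series(measurements, spec_a)
  sb <- resolve_series(measurements, spec_b)
  m <- merge(sa, sb, by = "case_id", suffixes = c("_a", "_b"))
  if (subset != "all" && !is.null(cases))
    m <- m[m$case_id %in% cases$case_id[cases$group == subset], ,
           drop = FALSE]
  ba <- bland_altman(m$ctr_a, m$ctr_b)
  fit <- linear_fit_r2(m$ctr_a, m$ctr_b)
  grDevices::png(path, width = 1200, height = 600)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot(m$ctr_a, m$ctr_b, pch = 16, cex = 0.5,
                 col = grDevices::rgb(0, 0, 0, 0.35),
                 xlab = spec_a, ylab = spec_b,
                 main = sprintf("R2 = %.4f (%s)", fit$r2, fit$category))
  graphics::abline(0, 1, col = "grey60")
  graphics::abline(fit$intercept, fit$slope, col = "red")
  mid <- (m$ctr_a + m$ctr_b) / 2
  dpc <- 100 * (m$ctr_a - m$ctr_b) / mid
  graphics::plot(mid, dpc, pch = 16, cex = 0.5,
                 col = grDevices::rgb(0, 0, 0, 0.35),
                 xlab = "mean of pair", ylab = "difference (% of mean)",
                 main = sprintf("bias %.2f%%, LoA (%.2f, %.2f), CV %.2f%%",
                                ba$bias, ba$loa_lower, ba$loa_upper, ba$cv))
  graphics::abline(h = c(ba$bias, ba$loa_lower, ba$loa_upper),
                   col = c("red", "blue", "blue"), lty = c(1, 2, 2))
  invisible(path)
}
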