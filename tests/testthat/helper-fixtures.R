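# Shared fixtures: small geometry for speed, calibrated models, and
# independent oracles used by several test files.

test_geometry <- function(image_size = 64L, pixel_spacing = 1)
  phantom_geometry(image_size = image_size, pixel_spacing = pixel_spacing)

small_pop <- function(n_normal = 10L, n_cardio = 10L, seed = 7L,
                      render = TRUE, image_size = 64L)
  generate_population(
    population_spec(n_normal = n_normal, n_cardiomegaly = n_cardio,
                    seed = seed),
    test_geometry(image_size), render = render)

# Rectangle mask: rows 2..5 filled over the given (1-based) column range.
rect_mask <- function(ncol_total, cols, nrow_total = 8L) {
  m <- matrix(FALSE, nrow_total, ncol_total)
  m[2:5, cols] <- TRUE
  m
}

# Brute-force CTR oracle: exhaustive per-pixel min/max column scan.
brute_force_ctr <- function(heart, lung) {
  hmin <- Inf; hmax <- -Inf; lmin <- Inf; lmax <- -Inf
  for (i in seq_len(nrow(heart))) for (j in seq_len(ncol(heart))) {
    if (heart[i, j]) { hmin <- min(hmin, j); hmax <- max(hmax, j) }
    if (lung[i, j]) { lmin <- min(lmin, j); lmax <- max(lmax, j) }
  }
  (hmax - hmin + 1) / (lmax - lmin + 1)
}

# Trapezoidal ROC AUC oracle: sweep every distinct threshold, integrate.
trapezoid_auc <- function(values, labels) {
  thr <- c(-Inf, sort(unique(values)), Inf)
  tpr <- fpr <- numeric(length(thr))
  pos <- labels == 1
  for (i in seq_along(thr)) {
    pred <- values > thr[i]
    tpr[i] <- sum(pred & pos) / sum(pos)
    fpr[i] <- sum(pred & !pos) / sum(!pos)
  }
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Brute-force Youden maximum over every candidate threshold.
brute_force_youden <- function(values, labels) {
  cand <- ctrval:::roc_candidates(values)
  best_j <- -Inf; best_ct <- NA
  for (ct in cand) {
    pred <- values > ct
    pos <- labels == 1
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_ct <- ct }
  }
  list(j = best_j, cutoff = best_ct)
}
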