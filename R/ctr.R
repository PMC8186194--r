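#' Compute the cardiothoracic ratio from a heart and a lung mask
#'
#' Diameters are horizontal extreme-point spans: the heart diameter is the
#' inclusive column span of the heart mask (rightmost - leftmost + 1,
#' times the pixel spacing) and the thoracic diameter is the same span over
#' the union of lung pixels.  CTR = heart diameter / thoracic diameter.
#' The inclusive-span convention is applied identically to both masks, so a
#' heart occupying exactly half of the thoracic columns yields CTR 0.5.
#'
#' Failure rules mirror clinical screening of automatic segmentations: an
#' empty mask, a heart (or lung) span under `min_heart_mm` (`min_lung_mm`),
#' or a heart span exceeding the thoracic span by more than 2 px yield a
#' failed result rather than a number — segmentation bleed must not silently
#' produce CTR > 1.
#'
#' @param heart_mask,lung_mask logical matrices of identical shape
#'   (rows = vertical, columns = horizontal axis).
#' @param pixel_spacing mm per pixel (> 0, isotropic).
#' @param min_heart_mm minimum credible heart diameter in mm; default 3.
#' @param min_lung_mm minimum credible thoracic diameter in mm; default 3.
#' @return An object of class `ctr_result`: list with `heart_diameter_mm`,
#'   `thoracic_diameter_mm`, `ctr`, `failed`, `failure_reason` (one of
#'   `"none"`, `"empty_heart"`, `"empty_lung"`, `"heart_too_small"`,
#'   `"lung_too_small"`, `"heart_exceeds_thorax"`).  When failed, `ctr` is
#'   `NA`.
#' @examples
#' lung <- matrix(FALSE, 10, 100); lung[4:8, 1:100] <- TRUE
#' heart <- matrix(FALSE, 10, 100); heart[5:7, 26:75] <- TRUE
#' compute_ctr(heart, lung, pixel_spacing = 1)$ctr  # 0.5
#' @export
compute_ctr <- function(heart_mask, lung_mask, pixel_spacing,
                        min_heart_mm = 3.0, min_lung_mm = 3.0) {
  if (!identical(dim(heart_mask), dim(lung_mask)))
    stop("input error: heart_mask and lung_mask must have identical shape")
  stopifnot(pixel_spacing > 0)

  fail <- function(reason)
    structure(list(heart_diameter_mm = NA_real_,
                   thoracic_diameter_mm = NA_real_,
                   ctr = NA_real_, failed = TRUE, failure_reason = reason),
              class = "ctr_result")

  hc <- which(colSums(heart_mask) > 0)
  lc <- which(colSums(lung_mask) > 0)
  if (length(lc) == 0L) return(fail("empty_lung"))
  if (length(hc) == 0L) return(fail("empty_heart"))

  span_h <- hc[length(hc)] - hc[1L] + 1L
  span_l <- lc[length(lc)] - lc[1L] + 1L
  d_h <- span_h * pixel_spacing
  d_l <- span_l * pixel_spacing
  if (d_l < min_lung_mm) return(fail("lung_too_small"))
  if (d_h < min_heart_mm) return(fail("heart_too_small"))
  if (span_h > span_l + 2L) return(fail("heart_exceeds_thorax"))

  structure(list(heart_diameter_mm = d_h, thoracic_diameter_mm = d_l,
                 ctr = span_h / span_l, failed = FALSE,
                 failure_reason = "none"),
            class = "ctr_result")
}

#' @export
print.ctr_result <- function(x, ...) {
  if (x$failed) cat("ctr_result: FAILED (", x$failure_reason, ")\n", sep = "")
  else cat(sprintf("ctr_result: CTR %.4f (heart %.1f mm / thorax %.1f mm)\n",
                   x$ctr, x$heart_diameter_mm, x$thoracic_diameter_mm))
  invisible(x)
}

#' Measure CTR across a population from masks
#'
#' Runs [compute_ctr()] on every case of a phantom population, using either
#' the ground-truth masks (`source = "truth"`, method label `"reference"`)
#' or masks predicted by a trained segmentation model
#' (`source = "predicted"`, method label `"ai_only"`).  Failures propagate
#' as failed records and are counted per group.
#'
#' @param pop a `phantom_population` (rendered or renderable on demand).
#' @param source `"truth"` or `"predicted"`.
#' @param model a trained `unet_model`; required when `source = "predicted"`.
#' @param min_heart_mm forwarded to [compute_ctr()].
#' @return List with `records` (measurement data.frame) and `failures`
#'   (data.frame of failure counts by group and reason).
#' @export
measure_population <- function(pop, source = c("truth", "predicted"),
                               model = NULL, min_heart_mm = 3.0) {
  stopifnot(inherits(pop, "phantom_population"))
  source <- match.arg(source)
  if (source == "predicted" && is.null(model))
    stop("input error: a trained model is required when source='predicted'")
  n <- nrow(pop$cases)
  method <- if (source == "truth") "reference" else "ai_only"
  if (n == 0L)
    return(list(records = empty_measurements(),
                failures = data.frame(group = character(0),
                                      reason = character(0),
                                      n = integer(0))))
  ctr <- rep(NA_real_, n)
  failed <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    ph <- phantom_image(pop, i)
    if (source == "truth") {
      res <- compute_ctr(ph$heart_mask, ph$lung_mask, ph$pixel_spacing,
                         min_heart_mm = min_heart_mm)
    } else {
      seg <- unet_predict(model, ph$image)
      res <- compute_ctr(seg$heart_mask, seg$lung_mask, ph$pixel_spacing,
                         min_heart_mm = min_heart_mm)
    }
    failed[i] <- res$failed
    reason[i] <- res$failure_reason
    if (!res$failed) ctr[i] <- res$ctr
  }
  records <- data.frame(case_id = pop$cases$case_id, method = method,
                        observer_id = if (source == "truth") "truth" else "ai",
                        replicate = 1L, ctr = ctr, failed = failed,
                        stringsAsFactors = FALSE)
  f <- records$failed
  failures <- if (any(f))
    as.data.frame(table(group = pop$cases$group[f], reason = reason[f]),
                  responseName = "n", stringsAsFactors = FALSE)
  else data.frame(group = character(0), reason = character(0), n = integer(0))
  failures <- failures[failures$n > 0, , drop = FALSE]
  list(records = records, failures = failures)
}

#' Measure CTR for cases listed in a manifest of mask files
#'
#' Reads PNG mask pairs referenced by a manifest CSV (columns `case_id`,
#' `group`, `pixel_spacing_mm`, `lung_mask_path`, `heart_mask_path`;
#' relative paths are resolved against the manifest's directory) and applies
#' [compute_ctr()] to each case.
#'
#' @param manifest_path path to a manifest CSV as written by
#'   [write_population()].
#' @param method method label for the records, default `"reference"`.
#' @param min_heart_mm forwarded to [compute_ctr()].
#' @return As [measure_population()].
#' @export
measure_manifest <- function(manifest_path, method = "reference",
                             min_heart_mm = 3.0) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  n <- nrow(man)
  ctr <- rep(NA_real_, n); failed <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    lp <- file.path(base, man$lung_mask_path[i])
    hp <- file.path(base, man$heart_mask_path[i])
    if (!file.exists(lp) || !file.exists(hp))
      stop("I/O error: missing mask file for case ", man$case_id[i])
    res <- compute_ctr(read_mask_png(hp), read_mask_png(lp),
                       man$pixel_spacing_mm[i], min_heart_mm = min_heart_mm)
    failed[i] <- res$failed
    reason[i] <- res$failure_reason
    if (!res$failed) ctr[i] <- res$ctr
  }
  records <- data.frame(case_id = man$case_id, method = method,
                        observer_id = "truth", replicate = 1L,
                        ctr = ctr, failed = failed, stringsAsFactors = FALSE)
  f <- records$failed
  failures <- if (any(f))
    as.data.frame(table(group = man$group[f], reason = reason[f]),
                  responseName = "n", stringsAsFactors = FALSE)
  else data.frame(group = character(0), reason = character(0), n = integer(0))
  failures <- failures[failures$n > 0, , drop = FALSE]
  list(records = records, failures = failures)
}
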