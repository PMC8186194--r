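# File-format plumbing: PNG images/masks, manifest and measurement CSVs.

# Image matrices are row = vertical, column = horizontal; png stores the same
# orientation, so matrices pass through unchanged.
write_gray_png <- function(mat, path) {
  png::writePNG(pmin(pmax(mat, 0), 1), target = path)
  invisible(path)
}

read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a >= 0.5
}

#' Write a phantom population to disk
#'
#' One 8-bit grayscale PNG per case for the image and each mask (masks as
#' 0/255), plus `manifest.csv` with columns case_id, group, true_ctr,
#' pixel_spacing_mm, image_path, lung_mask_path, heart_mask_path (paths
#' relative to the manifest).
#'
#' @param pop a `phantom_population`.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_population <- function(pop, outdir) {
  stopifnot(inherits(pop, "phantom_population"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(pop$cases)
  rel <- function(id, kind) file.path("cases", sprintf("%s_%s.png", id, kind))
  dir.create(file.path(outdir, "cases"), showWarnings = FALSE)
  for (i in seq_len(n)) {
    ph <- phantom_image(pop, i)
    id <- ph$case_id
    write_gray_png(ph$image, file.path(outdir, rel(id, "image")))
    write_gray_png(ph$lung_mask * 1, file.path(outdir, rel(id, "lung")))
    write_gray_png(ph$heart_mask * 1, file.path(outdir, rel(id, "heart")))
  }
  man <- data.frame(case_id = pop$cases$case_id, group = pop$cases$group,
                    true_ctr = pop$cases$true_ctr,
                    pixel_spacing_mm = pop$cases$pixel_spacing,
                    image_path = rel(pop$cases$case_id, "image"),
                    lung_mask_path = rel(pop$cases$case_id, "lung"),
                    heart_mask_path = rel(pop$cases$case_id, "heart"),
                    stringsAsFactors = FALSE)
  path <- file.path(outdir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Write a measurement table to CSV
#'
#' Schema: case_id, method, observer, replicate, ctr (empty when failed),
#' failed (0/1).  Byte-stable across identical runs.
#'
#' @param records measurement data.frame.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(records, path) {
  out <- data.frame(case_id = records$case_id, method = records$method,
                    observer = records$observer_id,
                    replicate = records$replicate,
                    ctr = ifelse(records$failed, "",
                                 sprintf("%.6f", records$ctr)),
                    failed = as.integer(records$failed),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table from CSV
#'
#' @param path CSV path as written by [write_measurements()].
#' @return Measurement data.frame (internal schema: `observer_id`, logical
#'   `failed`, `NA` ctr for failed records).
#' @export
read_measurements <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(ctr = "character"))
  data.frame(case_id = as.character(d$case_id), method = d$method,
             observer_id = as.character(d$observer),
             replicate = as.integer(d$replicate),
             ctr = suppressWarnings(as.numeric(d$ctr)),
             failed = d$failed == 1L, stringsAsFactors = FALSE)
}
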