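#' Population specification for synthetic chest phantoms
#'
#' Describes the two diagnostic groups of a simulated chest-radiograph
#' population by their true-CTR distributions.  Defaults reproduce a large
#' clinical PACS cohort: normal cases with CTR 0.454 +/- 0.043 and
#' cardiomegaly cases with CTR 0.569 +/- 0.047, with 4,933 and 2,517 cases
#' respectively.
#'
#' @param n_normal,n_cardiomegaly number of cases per group (>= 0).
#' @param ctr_mean_normal,ctr_sd_normal mean and SD of true CTR, normal group.
#' @param ctr_mean_cardiomegaly,ctr_sd_cardiomegaly mean and SD of true CTR,
#'   cardiomegaly group.
#' @param truncate_cardiomegaly_at optional lower bound for cardiomegaly CTR
#'   draws (e.g. 0.5, the conventional cardiomegaly threshold); `NULL` for no
#'   truncation.  Truncation is appropriate when the cardiomegaly group is
#'   defined by exceeding the clinical cutoff (classification experiments);
#'   leave off for pure agreement experiments.
#' @param seed integer seed controlling all sampling for this population.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_normal = 4933L, n_cardiomegaly = 2517L,
                            ctr_mean_normal = 0.454, ctr_sd_normal = 0.043,
                            ctr_mean_cardiomegaly = 0.569,
                            ctr_sd_cardiomegaly = 0.047,
                            truncate_cardiomegaly_at = NULL,
                            seed = 1L) {
  stopifnot(n_normal >= 0, n_cardiomegaly >= 0,
            ctr_sd_normal > 0, ctr_sd_cardiomegaly > 0,
            ctr_mean_normal > 0, ctr_mean_normal < 1,
            ctr_mean_cardiomegaly > 0, ctr_mean_cardiomegaly < 1)
  structure(list(n_normal = as.integer(n_normal),
                 n_cardiomegaly = as.integer(n_cardiomegaly),
                 ctr_mean_normal = ctr_mean_normal,
                 ctr_sd_normal = ctr_sd_normal,
                 ctr_mean_cardiomegaly = ctr_mean_cardiomegaly,
                 ctr_sd_cardiomegaly = ctr_sd_cardiomegaly,
                 truncate_cardiomegaly_at = truncate_cardiomegaly_at,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Phantom geometry configuration
#'
#' The phantom is a deliberately minimal stand-in for a PA-upright chest
#' radiograph: the thorax is a large ellipse, the two lung fields are lateral
#' ellipses whose outer edges coincide with the thoracic extremes, and the
#' heart is a central ellipse whose horizontal pixel span is set directly from
#' the designed CTR.  This makes extreme-point CTR exact by construction (to
#' within rasterisation).
#'
#' @param image_size square image side in pixels; default 256.
#' @param pixel_spacing isotropic pixel spacing in mm/px; default 0.7 (a
#'   typical downsampled-CXR scale; full-resolution CXRs are finer).
#' @param thorax_frac range of thoracic span as a fraction of image width;
#'   one value per case is drawn uniformly from this range.
#' @param mediastinum_frac half-width of the central mediastinal strip that
#'   separates the two lung ellipses, as a fraction of the thoracic span.
#' @param heart_offset_frac leftward shift of the heart centre as a fraction
#'   of thoracic span (the heart sits slightly off-midline); clamped so the
#'   heart stays within the lung extent.
#' @param intensities named list of grey levels in \[0,1\] for background,
#'   body (mediastinum/soft tissue), lung and heart.
#' @param noise_sd SD of additive Gaussian pixel noise (image only; masks are
#'   exact rasterisations and unaffected).
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(image_size = 256L, pixel_spacing = 0.7,
                             thorax_frac = c(0.70, 0.80),
                             mediastinum_frac = 0.10,
                             heart_offset_frac = 0.05,
                             intensities = list(background = 0.08,
                                                body = 0.55,
                                                lung = 0.22,
                                                heart = 0.78),
                             noise_sd = 0.03) {
  stopifnot(image_size >= 16, pixel_spacing > 0,
            length(thorax_frac) %in% c(1L, 2L),
            all(thorax_frac > 0), all(thorax_frac < 1),
            mediastinum_frac >= 0, mediastinum_frac < 0.5, noise_sd >= 0)
  if (length(thorax_frac) == 1L) thorax_frac <- rep(thorax_frac, 2L)
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing,
                 thorax_frac = sort(thorax_frac),
                 mediastinum_frac = mediastinum_frac,
                 heart_offset_frac = heart_offset_frac,
                 intensities = intensities, noise_sd = noise_sd),
            class = "phantom_geometry")
}

#' Observer measurement-noise model
#'
#' A human observer measuring CTR is modelled with multiplicative (relative)
#' error: `measured = true_ctr * (1 + relative_bias + eps)` with
#' `eps ~ N(0, relative_sd^2)`.  Relative noise is the natural scale here
#' because observer variation in CTR studies is reported as a percentage of
#' the mean (coefficients of variation of order 1-2\%).
#'
#' @param observer_id label, e.g. `"obs1"`.
#' @param relative_bias systematic relative offset (fraction; 0.01 = +1\%).
#' @param relative_sd SD of the relative error (fraction, >= 0).
#' @param seed integer seed for this observer's draws.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(observer_id, relative_bias = 0,
                           relative_sd = 0.015, seed = 1L) {
  stopifnot(is.character(observer_id), length(observer_id) == 1L,
            relative_sd >= 0)
  structure(list(observer_id = observer_id, relative_bias = relative_bias,
                 relative_sd = relative_sd, seed = as.integer(seed)),
            class = "observer_model")
}

#' Calibrated pair of observers
#'
#' Two observers calibrated so that, with the 2+1 replication design, the
#' intra-observer CV of observer 1 is about 1.5\% and the inter-observer CV
#' about 2.1\% — the scale reported for trained human readers measuring CTR.
#'
#' Closed forms used for the calibration: intra-observer
#' CV = sqrt(2) * sd1 * 100 and inter-observer
#' CV = sqrt(sd1^2 + sd2^2) * 100 for independent relative errors.
#' The defaults carry no systematic observer bias: clinical readers do show
#' inter-observer biases of order 1-2\%, but a fixed observer-level bias
#' interacts with the assisted accept-or-adjust rule (it makes the
#' inter-observer differences bimodal), so bias is left to explicit
#' [observer_model()] configuration rather than baked into the defaults.
#'
#' @param seed base seed; the two observers use `seed` and `seed + 1`.
#' @return List of two `observer_model` objects.
#' @export
default_observers <- function(seed = 101L) {
  list(observer_model("obs1", relative_bias = 0, relative_sd = 0.0107,
                      seed = seed),
       observer_model("obs2", relative_bias = 0, relative_sd = 0.0184,
                      seed = seed + 1L))
}

#' AI-only measurement error and failure model
#'
#' Automatic CTR measurement errs differently from humans: its relative error
#' is heavier-tailed (a two-component normal mixture) and it can fail outright
#' (unsegmentable heart), with failures concentrated in the normal group.
#'
#' The defaults are pinned by two calibration targets observed for a
#' clinical VGG-16 U-Net CTR system: (i) the CV of manual-consensus vs
#' AI-only of about 5.8\% fixes the mixture's total variance
#' (`0.9 * core_sd^2 + 0.1 * outlier_sd^2` of about `0.057^2`), and (ii) an
#' "excellent" (accepted by both observers at the +/- 1.8\% tolerance) rate
#' of about 40\% requires roughly 40\% of AI errors to fall within about
#' 1.8\% of manual readings, forcing a sharp core (`core_sd` about 1.2\%)
#' and a correspondingly heavy tail (`outlier_sd` about 18\%) rather than a
#' moderately wide single component.  Failure rates default to 290/4933
#' (normal) and 9/2517 (cardiomegaly).
#'
#' @param core_sd relative SD of the well-behaved error component.
#' @param outlier_sd relative SD of the heavy-tail component
#'   (>= `core_sd`).
#' @param outlier_prob probability a draw comes from the heavy tail.
#' @param fail_prob_normal,fail_prob_cardiomegaly per-group probability of a
#'   failed (no-value) outcome.
#' @param seed integer seed.
#' @return An object of class `ai_error_model`.
#' @export
ai_error_model <- function(core_sd = 0.012, outlier_sd = 0.177,
                           outlier_prob = 0.10,
                           fail_prob_normal = 290 / 4933,
                           fail_prob_cardiomegaly = 9 / 2517,
                           seed = 2L) {
  stopifnot(core_sd >= 0, outlier_sd >= core_sd,
            outlier_prob >= 0, outlier_prob <= 1,
            fail_prob_normal >= 0, fail_prob_normal <= 1,
            fail_prob_cardiomegaly >= 0, fail_prob_cardiomegaly <= 1)
  structure(list(core_sd = core_sd, outlier_sd = outlier_sd,
                 outlier_prob = outlier_prob,
                 fail_prob_normal = fail_prob_normal,
                 fail_prob_cardiomegaly = fail_prob_cardiomegaly,
                 seed = as.integer(seed)),
            class = "ai_error_model")
}

# Rasterise a filled ellipse onto an image_size x image_size logical matrix.
# Matrix rows index y (vertical), columns index x (horizontal); pixel centres
# at integer coordinates 1..n.
ellipse_mask <- function(n, cx, cy, a, b) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# Half-integer alignment so that a horizontal pixel span of exactly `span`
# columns is rasterised around column `centre`: odd spans centre on an
# integer, even spans on an integer + 0.5.
span_axis <- function(span, centre) {
  if (span %% 2L == 1L) list(cx = round(centre), a = (span - 1) / 2 + 0.49)
  else list(cx = floor(centre) + 0.5, a = span / 2 - 0.01)
}

#' Render one synthetic chest phantom
#'
#' Builds the image and exact ground-truth masks for a single case.  The lung
#' masks exclude the heart region, so lung and heart classes are disjoint;
#' the lateral lung extremes coincide with the thoracic extremes, so the
#' thoracic diameter equals the lung-union horizontal span.
#'
#' @param true_ctr designed cardiothoracic ratio, strictly inside (0, 1).
#' @param geometry a [phantom_geometry()].
#' @param seed integer seed (thoracic width draw and pixel noise).
#' @param case_id label stored in the case.
#' @param group `"normal"` or `"cardiomegaly"` (metadata only).
#' @return An object of class `phantom_case`: list with `case_id`, `image`
#'   (matrix in \[0,1\]), `lung_mask`, `heart_mask` (logical matrices),
#'   `pixel_spacing`, `true_ctr`, `group`.
#' @export
render_phantom <- function(true_ctr, geometry = phantom_geometry(),
                           seed = 1L, case_id = "case", group = "normal") {
  stopifnot(inherits(geometry, "phantom_geometry"))
  if (!is.finite(true_ctr) || true_ctr <= 0 || true_ctr >= 1)
    stop("invalid_geometry: true_ctr must lie strictly inside (0, 1)")
  n <- geometry$image_size
  local_seed(seed, {
    tf <- runif(1, geometry$thorax_frac[1], geometry$thorax_frac[2])
    span_t <- floor(n * tf)
    if (span_t %% 2L == 0L) span_t <- span_t - 1L  # odd span, integer centre
    cx <- round(n / 2)
    cy <- round(n * 0.52)
    a_t <- (span_t - 1) / 2 + 0.49
    b_t <- n * 0.41

    span_h <- round(true_ctr * span_t)
    if (span_h >= span_t)
      stop("invalid_geometry: heart span cannot reach the thoracic span ",
           "(the heart must sit inside the lung fields)")
    if (span_h < 1)
      stop("invalid_geometry: designed heart span below one pixel")

    thorax <- ellipse_mask(n, cx, cy, a_t, b_t)

    med <- geometry$mediastinum_frac * span_t  # mediastinal half-width, px
    a_l <- (a_t - med) / 2
    lung_b <- 0.80 * b_t
    lung_cy <- cy - 0.06 * n
    left  <- ellipse_mask(n, cx - a_t + a_l, lung_cy, a_l, lung_b)
    right <- ellipse_mask(n, cx + a_t - a_l, lung_cy, a_l, lung_b)
    lungs <- (left | right) & thorax

    off_max <- (span_t - span_h) / 2 - 0.6
    off <- min(geometry$heart_offset_frac * span_t, max(off_max, 0))
    hx <- span_axis(span_h, cx - off)
    b_h <- max(0.34 * b_t, span_h * 0.35)
    heart_cy <- cy + 0.16 * b_t
    heart <- ellipse_mask(n, hx$cx, heart_cy, hx$a, b_h)

    ints <- geometry$intensities
    img <- matrix(ints$background, n, n)
    img[thorax] <- ints$body
    img[lungs] <- ints$lung
    img[heart] <- ints$heart
    if (geometry$noise_sd > 0)
      img <- img + matrix(rnorm(n * n, 0, geometry$noise_sd), n, n)
    img <- pmin(pmax(img, 0), 1)

    structure(list(case_id = case_id, image = img,
                   lung_mask = lungs & !heart, heart_mask = heart,
                   pixel_spacing = geometry$pixel_spacing,
                   true_ctr = true_ctr, group = group),
              class = "phantom_case")
  })
}

# Truncated-normal CTR draws in (lo, hi) by bounded rejection.
rtrunc_ctr <- function(n, mean, sd, lo = 0, hi = 1, max_tries = 1000L) {
  if (n == 0L) return(numeric(0))
  out <- rnorm(n, mean, sd)
  for (i in seq_len(max_tries)) {
    bad <- out <= lo | out >= hi
    if (!any(bad)) return(out)
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop("sampling_failure: could not draw CTR inside (", lo, ", ", hi,
       ") after ", max_tries, " rounds")
}

#' Generate a phantom population
#'
#' Draws per-case true CTRs from the group distributions in `spec` and
#' (optionally) renders every case.  With `render = FALSE` only the case
#' table and per-case render seeds are stored; [phantom_image()] can render
#' any case on demand, bit-identically, from its stored seed — useful for
#' large populations where holding thousands of images is wasteful.
#'
#' @param spec a [population_spec()].
#' @param geometry a [phantom_geometry()].
#' @param render logical; render images and masks now?
#' @return An object of class `phantom_population`: list with `cases` (a
#'   data.frame: case_id, group, true_ctr, pixel_spacing, render_seed),
#'   `geometry`, `spec`, and `phantoms` (list of `phantom_case` or `NULL`).
#' @export
generate_population <- function(spec = population_spec(),
                                geometry = phantom_geometry(),
                                render = TRUE) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(geometry, "phantom_geometry"))
  n <- spec$n_normal + spec$n_cardiomegaly
  if (n == 0L) {
    pop <- list(cases = data.frame(case_id = character(0),
                                   group = character(0),
                                   true_ctr = numeric(0),
                                   pixel_spacing = numeric(0),
                                   render_seed = integer(0)),
                geometry = geometry, spec = spec, phantoms = NULL)
    return(structure(pop, class = "phantom_population"))
  }
  lo_c <- if (is.null(spec$truncate_cardiomegaly_at)) 0
          else spec$truncate_cardiomegaly_at
  draws <- local_seed(spec$seed, {
    ctr_n <- rtrunc_ctr(spec$n_normal, spec$ctr_mean_normal,
                        spec$ctr_sd_normal)
    ctr_c <- rtrunc_ctr(spec$n_cardiomegaly, spec$ctr_mean_cardiomegaly,
                        spec$ctr_sd_cardiomegaly, lo = lo_c)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    list(ctr = c(ctr_n, ctr_c), seeds = seeds)
  })
  cases <- data.frame(
    case_id = c(sprintf("N%05d", seq_len(spec$n_normal)),
                sprintf("C%05d", seq_len(spec$n_cardiomegaly))),
    group = rep(c("normal", "cardiomegaly"),
                c(spec$n_normal, spec$n_cardiomegaly)),
    true_ctr = draws$ctr,
    pixel_spacing = geometry$pixel_spacing,
    render_seed = draws$seeds,
    stringsAsFactors = FALSE)
  phantoms <- NULL
  if (render)
    phantoms <- lapply(seq_len(n), function(i)
      render_phantom(cases$true_ctr[i], geometry, cases$render_seed[i],
                     cases$case_id[i], cases$group[i]))
  structure(list(cases = cases, geometry = geometry, spec = spec,
                 phantoms = phantoms),
            class = "phantom_population")
}

#' Fetch (rendering on demand if needed) one case of a population
#'
#' @param pop a `phantom_population`.
#' @param i case index (row of `pop$cases`).
#' @return A `phantom_case`.
#' @export
phantom_image <- function(pop, i) {
  stopifnot(inherits(pop, "phantom_population"))
  if (!is.null(pop$phantoms)) return(pop$phantoms[[i]])
  with(pop$cases[i, ], render_phantom(true_ctr, pop$geometry, render_seed,
                                      case_id, group))
}

#' @export
print.phantom_population <- function(x, ...) {
  tab <- table(x$cases$group)
  cat("phantom_population:", nrow(x$cases), "cases (",
      paste(names(tab), tab, collapse = ", "), ")\n")
  cat("  rendered:", !is.null(x$phantoms),
      " image:", x$geometry$image_size, "px @",
      x$geometry$pixel_spacing, "mm/px\n")
  invisible(x)
}

# Canonical empty measurement table (shared schema for all simulators).
empty_measurements <- function() {
  data.frame(case_id = character(0), method = character(0),
             observer_id = character(0), replicate = integer(0),
             ctr = numeric(0), failed = logical(0), stringsAsFactors = FALSE)
}

#' Simulate manual CTR measurements by one observer
#'
#' One measurement per case: `true_ctr * (1 + bias + eps)`,
#' `eps ~ N(0, relative_sd^2)`.  Manual measurements never fail.  The draw
#' seed is `observer$seed + 7919 * replicate + seed_offset`, so replicates
#' (and independent sessions, via `seed_offset`) are independent but
#' reproducible.
#'
#' @param pop a `phantom_population`.
#' @param observer an [observer_model()].
#' @param replicate replicate index (>= 1).
#' @param method method label for the records, default `"manual"`.
#' @param seed_offset extra seed displacement for an independent session.
#' @return A measurement data.frame: case_id, method, observer_id,
#'   replicate, ctr, failed.
#' @export
simulate_manual <- function(pop, observer, replicate = 1L,
                            method = "manual", seed_offset = 0L) {
  stopifnot(inherits(pop, "phantom_population"),
            inherits(observer, "observer_model"), replicate >= 1L)
  n <- nrow(pop$cases)
  if (n == 0L) return(empty_measurements())
  eps <- local_seed(observer$seed + 7919L * as.integer(replicate) +
                      as.integer(seed_offset),
                    rnorm(n, 0, observer$relative_sd))
  data.frame(case_id = pop$cases$case_id, method = method,
             observer_id = observer$observer_id,
             replicate = as.integer(replicate),
             ctr = pop$cases$true_ctr * (1 + observer$relative_bias + eps),
             failed = FALSE, stringsAsFactors = FALSE)
}

#' Simulate AI-only CTR measurements
#'
#' Each case fails with its group's failure probability (record flagged, no
#' value); otherwise `ctr = true_ctr * (1 + eps)` with `eps` drawn from the
#' two-component normal mixture of the [ai_error_model()].
#'
#' @param pop a `phantom_population`.
#' @param model an [ai_error_model()].
#' @return A measurement data.frame (method `"ai_only"`, observer `"ai"`),
#'   with `ctr = NA` and `failed = TRUE` for failed cases.
#' @export
simulate_ai_only <- function(pop, model = ai_error_model()) {
  stopifnot(inherits(pop, "phantom_population"),
            inherits(model, "ai_error_model"))
  n <- nrow(pop$cases)
  if (n == 0L) return(empty_measurements())
  local_seed(model$seed, {
    p_fail <- ifelse(pop$cases$group == "normal",
                     model$fail_prob_normal, model$fail_prob_cardiomegaly)
    failed <- runif(n) < p_fail
    tail <- runif(n) < model$outlier_prob
    eps <- rnorm(n, 0, ifelse(tail, model$outlier_sd, model$core_sd))
    ctr <- pop$cases$true_ctr * (1 + eps)
    ctr[failed] <- NA_real_
    data.frame(case_id = pop$cases$case_id, method = "ai_only",
               observer_id = "ai", replicate = 1L, ctr = ctr,
               failed = failed, stringsAsFactors = FALSE)
  })
}
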