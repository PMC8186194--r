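# Encoder-decoder (U-Net style) segmentation: a contraction path of
# convolution blocks with 2x2 max pooling, an expansion path of x2
# upsampling + 2x2 convolution blocks with stage-wise skip concatenation and
# two 3x3 convolutions per decoder block, and a 1x1 softmax head.
# Heavy tensor ops (conv/pool/upsample fw+bw) live in src/unet_ops.cpp;
# the network graph, loss and optimiser are orchestrated here.

#' Segmentation network configuration
#'
#' @param input_size square input side in pixels; must be divisible by
#'   `2^encoder_stages`.
#' @param encoder_stages number of contraction stages (each halves the
#'   spatial dimensions).
#' @param base_channels channels of the first stage for the `"reduced"`
#'   preset; each later stage doubles them.
#' @param encoder_preset `"reduced"` (two 3x3 convolutions per block,
#'   `base_channels` wide — trains on a CPU in minutes) or `"vgg16_like"`
#'   (the VGG-16 channel plan: 64/128/256/512 channels with 2/2/3/3
#'   convolutions over up to four stages and a 512-channel, 3-convolution
#'   bottleneck — the architecture used by clinical CTR systems, far heavier
#'   to train).
#' @param classes output classes; default 3 (background, lung, heart).
#' @param seed integer seed for weight initialisation.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(input_size = 64L, encoder_stages = 3L,
                        base_channels = 8L,
                        encoder_preset = c("reduced", "vgg16_like"),
                        classes = 3L, seed = 1L) {
  encoder_preset <- match.arg(encoder_preset)
  stopifnot(classes >= 2L, encoder_stages >= 1L, base_channels >= 1L)
  if (input_size %% (2^encoder_stages) != 0)
    stop("configuration error: input_size must be divisible by 2^stages")
  if (encoder_preset == "vgg16_like" && encoder_stages > 4L)
    stop("configuration error: vgg16_like supports at most 4 encoder ",
         "stages (plus its 512-channel bottleneck)")
  structure(list(input_size = as.integer(input_size),
                 encoder_stages = as.integer(encoder_stages),
                 base_channels = as.integer(base_channels),
                 encoder_preset = encoder_preset,
                 classes = as.integer(classes), seed = as.integer(seed)),
            class = "unet_config")
}

# Channel/conv-count plan for a config.
unet_plan <- function(config) {
  s <- config$encoder_stages
  if (config$encoder_preset == "reduced") {
    enc_ch <- config$base_channels * 2^(seq_len(s) - 1L)
    enc_convs <- rep(2L, s)
    bot_ch <- config$base_channels * 2^s
    bot_convs <- 2L
  } else {
    vgg_ch <- c(64L, 128L, 256L, 512L)
    vgg_convs <- c(2L, 2L, 3L, 3L)
    enc_ch <- vgg_ch[seq_len(s)]
    enc_convs <- vgg_convs[seq_len(s)]
    bot_ch <- 512L
    bot_convs <- 3L
  }
  list(stages = s, enc_ch = enc_ch, enc_convs = enc_convs,
       bot_ch = bot_ch, bot_convs = bot_convs,
       classes = config$classes, input_size = config$input_size)
}

he_init <- function(k, cin, cout)
  matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)

#' Build an untrained segmentation model
#'
#' Allocates He-initialised weights for the configured architecture.  The
#' contraction path halves spatial dimensions per stage; the expansion path
#' restores them with skip concatenation, so output score maps match the
#' input size exactly.
#'
#' @param config a [unet_config()].
#' @return An object of class `unet_model`: list with `config`, `plan`,
#'   `params` (named weight arrays) and `loss_history`.
#' @export
build_unet <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  plan <- unet_plan(config)
  params <- local_seed(config$seed, {
    P <- list()
    add_conv <- function(P, name, k, cin, cout) {
      P[[paste0(name, "_w")]] <- he_init(k, cin, cout)
      P[[paste0(name, "_b")]] <- numeric(cout)
      P
    }
    cin <- 1L
    for (s in seq_len(plan$stages)) {
      for (i in seq_len(plan$enc_convs[s])) {
        P <- add_conv(P, sprintf("enc_s%d_c%d", s, i), 3L, cin,
                      plan$enc_ch[s])
        cin <- plan$enc_ch[s]
      }
    }
    for (i in seq_len(plan$bot_convs)) {
      P <- add_conv(P, sprintf("bot_c%d", i), 3L, cin, plan$bot_ch)
      cin <- plan$bot_ch
    }
    for (s in rev(seq_len(plan$stages))) {
      P <- add_conv(P, sprintf("dec_s%d_up", s), 2L, cin, plan$enc_ch[s])
      cin <- 2L * plan$enc_ch[s]  # concat with the stage-s skip
      for (i in 1:2) {
        P <- add_conv(P, sprintf("dec_s%d_c%d", s, i), 3L, cin,
                      plan$enc_ch[s])
        cin <- plan$enc_ch[s]
      }
    }
    P <- add_conv(P, "out", 1L, cin, plan$classes)
    P
  })
  structure(list(config = config, plan = plan, params = params,
                 loss_history = numeric(0)),
            class = "unet_model")
}

#' Number of trainable parameters of a model
#' @param model a `unet_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("unet_model (%s): %d stages, input %d px, %d classes, %d params\n",
              x$config$encoder_preset, x$plan$stages, x$plan$input_size,
              x$plan$classes, n_params(x)))
  if (length(x$loss_history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(x$loss_history),
                x$loss_history[length(x$loss_history)]))
  invisible(x)
}

concat_slices <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# Forward pass on one image.  With cache=TRUE also returns everything the
# backward pass needs (conv inputs and post-ReLU outputs, pool indices).
unet_forward <- function(model, img, cache = FALSE) {
  plan <- model$plan; P <- model$params
  if (!all(dim(img) == plan$input_size))
    stop("shape error: image must be ", plan$input_size, "x",
         plan$input_size)
  conv_relu <- function(x, name, k) {
    z <- .conv2d_fw(x, P[[paste0(name, "_w")]], P[[paste0(name, "_b")]], k)
    y <- pmax(z, 0)
    if (cache) cc[[name]] <<- list(x_in = x, out = y)
    y
  }
  cc <- list()
  x <- array(img, c(plan$input_size, plan$input_size, 1L))
  skips <- vector("list", plan$stages)
  pool_idx <- vector("list", plan$stages)
  pool_dim <- vector("list", plan$stages)
  for (s in seq_len(plan$stages)) {
    for (i in seq_len(plan$enc_convs[s]))
      x <- conv_relu(x, sprintf("enc_s%d_c%d", s, i), 3L)
    skips[[s]] <- x
    mp <- .maxpool2_fw(x)
    pool_idx[[s]] <- mp$idx
    pool_dim[[s]] <- dim(x)
    x <- mp$y
  }
  for (i in seq_len(plan$bot_convs))
    x <- conv_relu(x, sprintf("bot_c%d", i), 3L)
  for (s in rev(seq_len(plan$stages))) {
    x <- .upsample2_fw(x)
    x <- conv_relu(x, sprintf("dec_s%d_up", s), 2L)
    x <- concat_slices(x, skips[[s]])
    for (i in 1:2)
      x <- conv_relu(x, sprintf("dec_s%d_c%d", s, i), 3L)
  }
  if (cache) cc[["out_in"]] <- x
  logits <- .conv2d_fw(x, P[["out_w"]], P[["out_b"]], 1L)
  C <- plan$classes
  m <- logits[, , 1L]
  for (c in seq_len(C)[-1L]) m <- pmax(m, logits[, , c])
  probs <- logits
  ssum <- 0
  for (c in seq_len(C)) {
    probs[, , c] <- exp(logits[, , c] - m)
    ssum <- ssum + probs[, , c]
  }
  for (c in seq_len(C)) probs[, , c] <- probs[, , c] / ssum
  out <- list(probs = probs, logits = logits)
  if (cache) {
    out$cache <- cc
    out$pool_idx <- pool_idx
    out$pool_dim <- pool_dim
  }
  out
}

# Loss = per-pixel cross-entropy + dice_weight * (1 - mean soft Dice).
# Returns loss value and gradient w.r.t. logits.
seg_loss <- function(probs, onehot, dice_weight = 1) {
  npix <- dim(probs)[1] * dim(probs)[2]
  C <- dim(probs)[3]
  eps <- 1e-7
  ce <- -sum(onehot * log(probs + eps)) / npix
  g_logits <- (probs - onehot) / npix
  dice_terms <- numeric(C)
  if (dice_weight > 0) {
    g_p <- array(0, dim(probs))
    for (c in seq_len(C)) {
      p <- probs[, , c]; y <- onehot[, , c]
      A <- sum(p * y); B <- sum(p) + sum(y)
      dice_terms[c] <- (2 * A + 1) / (B + 1)
      # d(1 - mean dice)/dp = -(2y - dice_c)/(B+1)/C
      g_p[, , c] <- -(2 * y - dice_terms[c]) / (B + 1) / C
    }
    # chain through softmax: g_z = p * (g_p - sum_c p_c g_p_c)
    inner <- probs[, , 1L] * g_p[, , 1L]
    for (c in seq_len(C)[-1L]) inner <- inner + probs[, , c] * g_p[, , c]
    g_logits <- g_logits +
      dice_weight * probs * (g_p - array(rep(inner, C), dim(probs)))
  }
  list(loss = ce + dice_weight * (1 - mean(dice_terms)),
       g_logits = g_logits)
}

# Backward pass; returns gradients named like params.
unet_backward <- function(model, fw, g_logits) {
  plan <- model$plan; P <- model$params; cc <- fw$cache
  G <- list()
  conv_bw <- function(g, name, k, relu = TRUE) {
    ent <- cc[[name]]
    if (relu) g <- g * (ent$out > 0)
    r <- .conv2d_bw(ent$x_in, P[[paste0(name, "_w")]], g, k)
    G[[paste0(name, "_w")]] <<- r$gw
    G[[paste0(name, "_b")]] <<- as.numeric(r$gb)
    r$gx
  }
  # output head (no ReLU)
  r <- .conv2d_bw(cc$out_in, P$out_w, g_logits, 1L)
  G$out_w <- r$gw; G$out_b <- as.numeric(r$gb)
  g <- r$gx
  g_skip <- vector("list", plan$stages)
  for (s in seq_len(plan$stages)) {   # reverse of decoder (ran stages..1)
    for (i in 2:1)
      g <- conv_bw(g, sprintf("dec_s%d_c%d", s, i), 3L)
    nch <- plan$enc_ch[s]
    g_skip[[s]] <- g[, , nch + seq_len(dim(g)[3] - nch), drop = FALSE]
    g <- g[, , seq_len(nch), drop = FALSE]
    g <- conv_bw(g, sprintf("dec_s%d_up", s), 2L)
    g <- .upsample2_bw(g)
  }
  for (i in rev(seq_len(plan$bot_convs)))
    g <- conv_bw(g, sprintf("bot_c%d", i), 3L)
  for (s in rev(seq_len(plan$stages))) {
    g <- .maxpool2_bw(g, fw$pool_idx[[s]], fw$pool_dim[[s]][1],
                      fw$pool_dim[[s]][2])
    g <- g + g_skip[[s]]
    for (i in rev(seq_len(plan$enc_convs[s])))
      g <- conv_bw(g, sprintf("enc_s%d_c%d", s, i), 3L)
  }
  G
}

# Class labels of a phantom: 1 background, 2 lung, 3 heart (disjoint masks).
phantom_onehot <- function(ph, classes = 3L) {
  n <- nrow(ph$image)
  oh <- array(0, c(n, n, classes))
  lung <- ph$lung_mask; heart <- ph$heart_mask
  oh[, , 1L] <- !(lung | heart)
  oh[, , 2L] <- lung
  oh[, , 3L] <- heart
  oh
}

#' Train a segmentation model on labelled phantoms
#'
#' Minimises per-pixel cross-entropy plus a soft-Dice term with Adam,
#' iterating over the cases one at a time in a seeded shuffled order.
#' Deterministic under a fixed seed on a single thread.  `epochs = 0`
#' returns the model unchanged.
#'
#' @param model a `unet_model`.
#' @param phantoms list of `phantom_case` objects (images sized to the
#'   model's `input_size`).
#' @param epochs training epochs (>= 0).
#' @param lr Adam learning rate.
#' @param dice_weight weight of the soft-Dice term (0 disables it).
#' @param seed integer seed for the shuffle order.
#' @param verbose print per-epoch loss?
#' @return The trained `unet_model` with `loss_history` extended.
#' @export
unet_train <- function(model, phantoms, epochs = 10L, lr = 1e-3,
                       dice_weight = 1, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), length(phantoms) >= 1L,
            epochs >= 0L)
  if (epochs == 0L) return(model)
  onehots <- lapply(phantoms, phantom_onehot, classes = model$plan$classes)
  opt <- list(m = lapply(model$params, function(p) p * 0),
              v = lapply(model$params, function(p) p * 0), t = 0L)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  for (ep in seq_len(epochs)) {
    ord <- local_seed(seed + ep, sample.int(length(phantoms)))
    ep_loss <- 0
    for (i in ord) {
      fw <- unet_forward(model, phantoms[[i]]$image, cache = TRUE)
      ls <- seg_loss(fw$probs, onehots[[i]], dice_weight)
      if (!is.finite(ls$loss))
        stop("training divergence: non-finite loss at epoch ", ep)
      ep_loss <- ep_loss + ls$loss
      G <- unet_backward(model, fw, ls$g_logits)
      opt$t <- opt$t + 1L
      corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
      for (nm in names(model$params)) {
        g <- G[[nm]]
        opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
        opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
        model$params[[nm]] <- model$params[[nm]] -
          lr * (opt$m[[nm]] / corr1) / (sqrt(opt$v[[nm]] / corr2) + adam_eps)
      }
    }
    model$loss_history <- c(model$loss_history, ep_loss / length(phantoms))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f", ep, ep_loss / length(phantoms)))
  }
  model
}

#' Predict lung and heart masks for one image
#'
#' Pure function of (model, image): runs the forward pass and derives binary
#' masks by per-pixel argmax over the class score maps.
#'
#' @param model a `unet_model`.
#' @param image numeric matrix sized to the model's `input_size`.
#' @return An object of class `segmentation_output`: list with `lung_mask`,
#'   `heart_mask` (logical matrices) and `scores` (H x W x classes array of
#'   softmax probabilities).
#' @export
unet_predict <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  fw <- unet_forward(model, image)
  cls <- apply(fw$probs, c(1, 2), which.max)
  structure(list(lung_mask = cls == 2L, heart_mask = cls == 3L,
                 scores = fw$probs),
            class = "segmentation_output")
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`; 1 for identical masks.  Two empty masks are
#' in perfect agreement (returns 1).
#'
#' @param a,b logical matrices of equal shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coef <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Save a model checkpoint
#'
#' Self-describing JSON: the configuration plus every weight tensor with its
#' dimensions.  Portable and diffable; loadable with [load_checkpoint()].
#'
#' @param model a `unet_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  payload <- list(
    format = "ctrval-unet-checkpoint-v1",
    config = unclass(model$config),
    loss_history = model$loss_history,
    params = lapply(model$params, function(p)
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           data = as.numeric(p))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file path.
#' @return A `unet_model`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "ctrval-unet-checkpoint-v1"))
    stop("input error: not a ctrval checkpoint file")
  cfg <- do.call(unet_config, payload$config[c(
    "input_size", "encoder_stages", "base_channels", "encoder_preset",
    "classes", "seed")])
  model <- build_unet(cfg)
  for (nm in names(model$params)) {
    ent <- payload$params[[nm]]
    p <- ent$data
    if (length(ent$dim) > 1L) dim(p) <- ent$dim
    stopifnot(length(p) == length(model$params[[nm]]))
    model$params[[nm]] <- p
  }
  model$loss_history <- as.numeric(payload$loss_history)
  model
}
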