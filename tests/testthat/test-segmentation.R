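test_that("configuration contracts are enforced", {
  expect_error(unet_config(input_size = 65, encoder_stages = 4),
               "divisible")
  expect_error(unet_config(encoder_preset = "vgg16_like",
                           encoder_stages = 5), "at most 4")
  expect_s3_class(unet_config(), "unet_config")
})

test_that("output score maps match input spatial dimensions", {
  for (cfg in list(unet_config(input_size = 64, encoder_stages = 4,
                               base_channels = 4, seed = 2),
                   unet_config(input_size = 32, encoder_stages = 2,
                               base_channels = 4, seed = 2))) {
    model <- build_unet(cfg)
    img <- matrix(runif(cfg$input_size^2), cfg$input_size)
    out <- unet_predict(model, img)
    expect_equal(dim(out$scores),
                 c(cfg$input_size, cfg$input_size, cfg$classes))
    expect_equal(dim(out$lung_mask), dim(img))
    # softmax head: per-pixel class scores sum to 1
    ssum <- out$scores[, , 1] + out$scores[, , 2] + out$scores[, , 3]
    expect_true(all(abs(ssum - 1) < 1e-9))
  }
  model <- build_unet(unet_config(input_size = 32, encoder_stages = 2,
                                  base_channels = 4))
  expect_error(unet_predict(model, matrix(0, 64, 64)), "shape")
})

test_that("parameter count equals the layer-by-layer arithmetic oracle", {
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  oracle_reduced <- function(stages, base, classes) {
    total <- 0; cin <- 1
    ch <- base * 2^(seq_len(stages) - 1)
    for (s in seq_len(stages)) for (i in 1:2) {
      total <- total + conv_p(3, cin, ch[s]); cin <- ch[s]
    }
    bot <- base * 2^stages
    for (i in 1:2) { total <- total + conv_p(3, cin, bot); cin <- bot }
    for (s in rev(seq_len(stages))) {
      total <- total + conv_p(2, cin, ch[s])
      cin <- 2 * ch[s]
      for (i in 1:2) { total <- total + conv_p(3, cin, ch[s]); cin <- ch[s] }
    }
    total + conv_p(1, cin, classes)
  }
  m <- build_unet(unet_config(input_size = 64, encoder_stages = 3,
                              base_channels = 8))
  expect_equal(n_params(m), oracle_reduced(3, 8, 3))
  m2 <- build_unet(unet_config(input_size = 32, encoder_stages = 2,
                               base_channels = 4, classes = 2))
  expect_equal(n_params(m2), oracle_reduced(2, 4, 2))
})

test_that("vgg16_like preset follows the VGG channel plan", {
  m <- build_unet(unet_config(input_size = 32, encoder_stages = 2,
                              encoder_preset = "vgg16_like"))
  expect_equal(m$plan$enc_ch, c(64L, 128L))
  expect_equal(m$plan$enc_convs, c(2L, 2L))
  expect_equal(m$plan$bot_ch, 512L)
  expect_equal(m$plan$bot_convs, 3L)
  # first conv block: 3x3, 1 -> 64 channels
  expect_equal(dim(m$params$enc_s1_c1_w), c(9L, 64L))
})

test_that("prediction is a pure, deterministic function of model and image", {
  model <- build_unet(unet_config(input_size = 32, encoder_stages = 2,
                                  base_channels = 4, seed = 5))
  img <- matrix(runif(32 * 32), 32)
  expect_identical(unet_predict(model, img), unet_predict(model, img))
})

test_that("zero-epoch training is a no-op", {
  pop <- small_pop(n_normal = 1L, n_cardio = 0L)
  model <- build_unet(unet_config(base_channels = 4))
  trained <- unet_train(model, pop$phantoms, epochs = 0L)
  expect_identical(trained$params, model$params)
})

test_that("training is seed-reproducible and loss decreases", {
  pop <- small_pop(n_normal = 4L, n_cardio = 4L, seed = 21L)
  cfg <- unet_config(base_channels = 4, seed = 7)
  m1 <- unet_train(build_unet(cfg), pop$phantoms, epochs = 3L, seed = 3L)
  m2 <- unet_train(build_unet(cfg), pop$phantoms, epochs = 3L, seed = 3L)
  expect_identical(m1$params, m2$params)
  expect_true(all(is.finite(m1$loss_history)))
  expect_lt(m1$loss_history[3], m1$loss_history[1])
})

test_that("a single phantom is memorised (overfit sanity)", {
  pop <- small_pop(n_normal = 1L, n_cardio = 0L, seed = 33L)
  model <- unet_train(build_unet(unet_config(seed = 1)), pop$phantoms,
                      epochs = 80L, seed = 1L)
  pr <- unet_predict(model, pop$phantoms[[1]]$image)
  expect_gte(dice_coef(pr$lung_mask, pop$phantoms[[1]]$lung_mask), 0.95)
  expect_gte(dice_coef(pr$heart_mask, pop$phantoms[[1]]$heart_mask), 0.95)
})

test_that("checkpoints round-trip through JSON", {
  pop <- small_pop(n_normal = 2L, n_cardio = 2L, seed = 13L)
  model <- unet_train(build_unet(unet_config(base_channels = 4, seed = 3)),
                      pop$phantoms, epochs = 2L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path)
  loaded <- load_checkpoint(path)
  expect_equal(loaded$params, model$params, tolerance = 1e-12)
  img <- pop$phantoms[[1]]$image
  expect_identical(unet_predict(loaded, img)$lung_mask,
                   unet_predict(model, img)$lung_mask)
  expect_error(load_checkpoint(withr::local_tempfile(lines = "{}",
                                                     fileext = ".json")),
               "not a ctrval checkpoint")
})

test_that("dice coefficient behaves at its boundaries", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(dice_coef(a, a), 1)
  expect_equal(dice_coef(a, !a), 0)
  none <- matrix(FALSE, 2, 2)
  expect_equal(dice_coef(none, none), 1)
})
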