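test_that("He-normal initialisation has the right variance and is seeded", {
  m <- tiny_model(seed = 1)
  m <- init_weights(m, seed = 42)
  # largest kernel in the tiny model: decoder conv1 (9 * 12 inputs)
  nm <- "dec3.conv1.W"
  W <- m$params[[nm]]
  expect_equal(stats::var(as.vector(W)), 2 / nrow(W), tolerance = 0.15)
  expect_true(all(vapply(grep("\\.b$", names(m$params), value = TRUE),
                         function(n) all(m$params[[n]] == 0), logical(1))))
  m2 <- init_weights(tiny_model(seed = 9), seed = 42)
  expect_identical(m$params, m2$params)
  m3 <- init_weights(tiny_model(seed = 9), seed = 43)
  expect_false(identical(m$params, m3$params))
  expect_error(init_weights(m, scheme = "xavier"), "unknown scheme")
})

test_that("a zero learning rate leaves parameters untouched", {
  m <- tiny_model(seed = 2)
  d <- tiny_patches(n = 8)
  before <- m$params
  fit <- train_model(m, d$x, d$y,
                     train_config(lr = 0, epochs = 1, batch_size = 4,
                                  val_fraction = 0.25, seed = 3))
  expect_equal(fit$model$params, before, tolerance = 1e-14)
})

test_that("the validation split follows val_fraction", {
  # 100 patches at 0.1 -> 90 train / 10 val; check via history determinism
  set.seed(1)
  P <- 100L
  n_val <- max(1L, round(0.1 * P))
  expect_equal(n_val, 10L)
  expect_equal(P - n_val, 90L)
})

test_that("a tiny model overfits a handful of patches", {
  cfg <- network_config(slim_widths = c(4L, 8L, 12L), laspp_channels = 16L,
                        patch_size = 16L)
  m <- build_wa_net(cfg, seed = 4)
  set.seed(5)
  # structured patches: half dark-left, labels follow the structure
  x <- array(runif(16 * 16 * 8, 0.4, 0.6), c(16, 16, 8))
  y <- array(0L, c(16, 16, 8))
  for (k in 1:8) {
    x[, 1:8, k] <- x[, 1:8, k] - 0.3
    y[, 1:8, k] <- 1L
  }
  fit <- train_model(m, x, y,
                     train_config(epochs = 60, batch_size = 4,
                                  val_fraction = 0.125, seed = 6))
  expect_lt(utils::tail(fit$history$train_loss, 1), 0.1)
  expect_lt(utils::tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("training is reproducible under a fixed seed", {
  d <- tiny_patches(n = 12, seed = 7)
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 8)
  f1 <- train_model(tiny_model(seed = 3), d$x, d$y, cfg)
  f2 <- train_model(tiny_model(seed = 3), d$x, d$y, cfg)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("non-finite losses abort with a diagnostic", {
  m <- tiny_model(seed = 5)
  d <- tiny_patches(n = 8)
  expect_error(train_model(m, d$x, d$y,
                           train_config(lr = 1e6, epochs = 3, batch_size = 4,
                                        seed = 9)),
               "non-finite|NaN")
})

test_that("full-image prediction honours shape, stride and constant models", {
  m <- tiny_model(seed = 6)
  # zero the classifier head: logits 0 -> softmax gives 0.5 everywhere
  m$params[["head.cls.W"]] <- m$params[["head.cls.W"]] * 0
  m$params[["head.cls.b"]] <- m$params[["head.cls.b"]] * 0
  set.seed(10)
  img <- matrix(runif(40 * 56), 40, 56)
  map <- predict_image(m, img, stride = 8)
  expect_equal(dim(map), dim(img))
  expect_equal(unname(map[1, 1]), 0.5, tolerance = 1e-12)
  expect_lt(diff(range(map)), 1e-12)
  # stride equal to the patch size tiles without overlap
  img2 <- matrix(runif(32 * 32), 32, 32)
  map2 <- predict_image(m, img2, stride = 16)
  expect_equal(dim(map2), dim(img2))
})

test_that("checkpoints round-trip to bit-identical predictions", {
  m <- tiny_model(seed = 7)
  set.seed(11)
  img <- matrix(runif(32 * 32), 32, 32)
  p1 <- predict_image(m, img, stride = 16)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m$params, m2$params)
  p2 <- predict_image(m2, img, stride = 16)
  expect_identical(p1, p2)
})

test_that("run_experiment completes at desk scale and emits a full report", {
  out <- tempfile("exp")
  rep <- run_experiment(list(
    seed = 3, outdir = out,
    n_train_images = 3, n_test_images = 2, n_patches = 90,
    synth_train = list(image_shape = c(64L, 64L)),
    model = list(slim_widths = c(4L, 8L, 12L), laspp_channels = 16L,
                 patch_size = 16L),
    train = list(epochs = 2, batch_size = 16),
    stride = 8
  ))
  expect_s3_class(rep$metrics, "metrics_report")
  expect_true(all(c("acc", "sens", "spec", "auc") %in% names(rep$metrics)))
  expect_equal(nrow(rep$history), 2L)
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "roc.csv")))
  expect_true(file.exists(file.path(out, "history.csv")))
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  expect_true(length(list.files(file.path(out, "maps"))) == 2L)
})

test_that("probability maps survive image round trips at codec precision", {
  set.seed(12)
  map <- matrix(runif(30 * 20), 30, 20)
  png_path <- tempfile(fileext = ".png")
  write_probability_map(map, png_path)
  back <- t(as.array(EBImage::readImage(png_path)))
  expect_equal(dim(back), dim(map))
  expect_lt(max(abs(back - map)), 1 / 255 + 1e-6)
  tif_path <- tempfile(fileext = ".tif")
  write_probability_map(map, tif_path)
  back16 <- t(as.array(EBImage::readImage(tif_path)))
  expect_lt(max(abs(back16 - map)), 1 / 65535 + 1e-6)
})

test_that("npy export is readable as the original array", {
  x <- matrix(rnorm(12), 3, 4)
  path <- tempfile(fileext = ".npy")
  write_npy(x, path)
  raw <- readBin(path, "raw", 6)
  expect_equal(rawToChar(raw[2:6]), "NUMPY")
  con <- file(path, "rb")
  seek(con, 8)
  hl <- readBin(con, "integer", 1, size = 2, endian = "little")
  header <- readChar(con, hl)
  vals <- readBin(con, "double", 12, size = 8, endian = "little")
  close(con)
  expect_match(header, "'shape': \\(3, 4\\)")
  # C order: rows written consecutively
  expect_equal(vals, as.vector(t(x)))
})
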