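test_that("receptive field formula matches the impulse response of an atrous layer", {
  expect_equal(receptive_field(3, 1), 3L)
  expect_equal(receptive_field(3, 2), 5L)
  expect_equal(receptive_field(3, 3), 7L)
  expect_error(receptive_field(0, 1))
  for (d in c(1L, 2L, 3L, 8L)) {
    n <- 2L * (3L - 1L) * d + 5L  # comfortably larger than the field
    x <- matrix(0, n, n)
    x[(n + 1) / 2, (n + 1) / 2] <- 1
    resp <- naive_atrous(x, matrix(1, 3, 3), d)
    span_r <- diff(range(which(rowSums(resp) > 0))) + 1L
    span_c <- diff(range(which(colSums(resp) > 0))) + 1L
    expect_equal(span_r, receptive_field(3, d))
    expect_equal(span_c, receptive_field(3, d))
  }
})

test_that("wide-activation widths satisfy the complexity identity", {
  bs <- wide_block_widths(16, r = 4)
  expect_equal(bs$expanded_width, 64L)
  expect_equal(bs$equivalent_width, 32L)
  expect_true(bs$exact)
  # r = 1 degenerates to the equal-width block
  b1 <- wide_block_widths(10, r = 1)
  expect_equal(b1$expanded_width, 10L)
  expect_equal(b1$equivalent_width, 10L)
  # exact integer equality of conv-weight counts for slim widths 8/16/32
  for (slim in c(8L, 16L, 32L)) {
    bs <- wide_block_widths(slim, r = 4)
    blk <- build_wdsr_a(bs, seed = 1)
    expect_identical(count_params(blk, "conv_weights"),
                     original_block_params(bs$equivalent_width, 3))
  }
  # inexact case is flagged
  expect_false(wide_block_widths(3, r = 2)$exact)
})

test_that("original block weight count is 2 c1^2 k^2", {
  expect_equal(original_block_params(1, 1), 2L)
  expect_equal(original_block_params(32, 3), 18432L)
  expect_equal(original_block_params(16, 3), 4608L)
})

test_that("weight normalization fixes the norm and ignores the scale of N", {
  w <- weight_normalize(c(3, 4), 10)
  expect_equal(w, c(6, 8))
  expect_equal(sqrt(sum(w^2)), 10)
  N <- matrix(rnorm(12), 3, 4)
  expect_equal(weight_normalize(N, sqrt(sum(N^2))), N)
  expect_equal(weight_normalize(7 * N, 2.5), weight_normalize(N, 2.5))
  expect_error(weight_normalize(c(0, 0), 1), "zero norm")
})

test_that("leaky relu follows the piecewise definition and degenerates to relu", {
  expect_equal(leaky_relu(2), 2)
  expect_equal(leaky_relu(-1, 0.3), -0.3)
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(leaky_relu(x, 0), pmax(x, 0))
})

test_that("a wide block with zeroed residual path is the identity map", {
  bs <- wide_block_widths(4, r = 4)
  blk <- build_wdsr_a(bs, seed = 2)
  for (nm in names(blk$params))
    blk$params[[nm]] <- blk$params[[nm]] * 0
  set.seed(3)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  expect_equal(block_forward(blk, x), x)  # no 1x1 adapter: pass-through
})

test_that("block output keeps spatial shape; channel mismatch uses the 1x1 adapter", {
  bs <- wide_block_widths(6, r = 4)
  blk <- build_wdsr_a(bs, in_channels = 3L, seed = 4)
  expect_true("block.id.W" %in% names(blk$params))
  set.seed(5)
  x <- array(runif(12 * 20 * 3), c(12, 20, 3))
  y <- block_forward(blk, x)
  expect_equal(dim(y), c(12, 20, 6))
  expect_error(block_forward(blk, array(0, c(12, 20, 5))), "channels")
})

test_that("pyramid branches respond at the dilation offsets and sum", {
  lp <- build_laspp(channels = 2L, dilations = c(1L, 4L), wn = FALSE,
                    in_channels = 1L, seed = 6)
  # zero weights -> zero output
  z <- lp
  for (nm in names(z$params)) z$params[[nm]] <- z$params[[nm]] * 0
  x0 <- array(runif(11 * 11), c(11, 11, 1))
  expect_equal(block_forward(z, x0), array(0, c(11, 11, 2)))
  # single-tap probe on the d = 4 branch: impulse response at offset -4
  p <- z
  W2 <- matrix(0, 9, 2)
  W2[1, 1] <- 1  # tap (a, b) = (-1, -1) of branch 2
  p$params[["block.branch2.W"]] <- W2
  imp <- array(0, c(11, 11, 1)); imp[6, 6, 1] <- 1
  out <- block_forward(p, imp)
  hits <- which(out[, , 1] != 0, arr.ind = TRUE)
  expect_equal(unname(hits), matrix(c(10L, 10L), 1))  # reads (i-4, j-4)
  # branch outputs add: all-one single taps on both branches at the centre
  q <- z
  for (br in 1:2) {
    W <- matrix(0, 9, 2); W[5, ] <- 1  # centre tap, both channels
    q$params[[paste0("block.branch", br, ".W")]] <- W
  }
  expect_equal(block_forward(q, imp)[6, 6, ], c(2, 2))
})

test_that("full network emits per-pixel probabilities that sum to one, deterministically", {
  m <- tiny_model(seed = 7)
  set.seed(8)
  patches <- array(runif(16 * 16 * 3), c(16, 16, 3))
  pr <- predict_patches(m, patches)
  expect_equal(dim(pr), c(16, 16, 2, 3))
  sums <- pr[, , 1, ] + pr[, , 2, ]
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(pr >= 0))
  expect_identical(pr, predict_patches(m, patches))
})

test_that("builds with the same seed agree; different seeds differ", {
  m1 <- tiny_model(seed = 11)
  m2 <- tiny_model(seed = 11)
  m3 <- tiny_model(seed = 12)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  expect_identical(count_params(m1), count_params(m3))
})

test_that("patch size must be divisible by the pooling factor", {
  expect_error(network_config(patch_size = 20L), "divisible")
})

test_that("ablation variants have the specified structure", {
  n1 <- build_variant("network_1", seed = 1)
  expect_equal(n1$config$block_type, "preact")
  expect_false(n1$config$wn_laspp)
  expect_true(any(grepl("bn1", names(n1$params))))

  n2 <- build_variant("network_2", seed = 1)
  expect_equal(n2$config$slim_widths, c(32L, 64L, 128L))
  expect_equal(n2$config$laspp_channels, 256L)
  expect_equal(n2$config$block_type, "preact")

  n3 <- build_variant("network_3", seed = 1)
  expect_equal(n3$config$laspp_dilations, c(1L, 2L, 4L))

  n4 <- build_variant("network_4", seed = 1)
  expect_equal(n4$config$laspp_dilations, c(1L, 2L, 4L, 8L, 16L))
  expect_equal(max(n4$config$laspp_dilations), 16L)
  expect_error(build_variant("network_9"))
})

test_that("weight-normalised pyramid convolutions keep ||w|| = g after updates", {
  m <- tiny_model(seed = 13)
  vnames <- grep("^laspp\\..*\\.V$", names(m$params), value = TRUE)
  expect_gt(length(vnames), 0)
  set.seed(14)
  for (vn in vnames) {
    gn <- sub("\\.V$", ".g", vn)
    # simulate an arbitrary optimizer update
    m$params[[vn]] <- m$params[[vn]] + matrix(rnorm(length(m$params[[vn]]), sd = 0.05),
                                              nrow(m$params[[vn]]))
    m$params[[gn]] <- m$params[[gn]] + rnorm(length(m$params[[gn]]), sd = 0.05)
    w <- wanet:::wn_effective(m$params[[vn]], m$params[[gn]])
    expect_equal(sqrt(colSums(w^2)), m$params[[gn]], tolerance = 1e-6)
  }
})

test_that("network gradients match finite differences along a random direction", {
  for (variant in c("wa_net", "network_1")) {
    cfg <- network_config(variant = variant, slim_widths = c(2L, 4L, 6L),
                          laspp_channels = 8L, patch_size = 16L)
    m <- build_wa_net(cfg, seed = 4)
    set.seed(4)
    N <- 2L; S <- 16L
    X <- matrix(runif(N * S * S), N * S * S, 1)
    y <- rbinom(N * S * S, 1, 0.3)
    lossfn <- function(mm) {
      fw <- wanet:::wa_forward(mm, X, N, training = TRUE)
      pv <- fw$prob[, 2]
      cross_entropy(pv, y, reduction = "mean") + dice_loss(pv, y)
    }
    fw <- wanet:::wa_forward(m, X, N, training = TRUE, keep_cache = TRUE)
    pv <- fw$prob[, 2]
    dpv <- cross_entropy_grad(pv, y, reduction = "mean") + dice_loss_grad(pv, y)
    dz2 <- pv * (1 - pv) * dpv
    G <- wanet:::wa_backward(m, fw, cbind(-dz2, dz2))
    set.seed(5)
    v <- lapply(m$params, function(p)
      array(rnorm(length(p)), if (is.null(dim(p))) length(p) else dim(p)))
    an <- sum(mapply(function(g, vv) sum(g * vv), G, v[names(G)]))
    h <- 1e-5  # small enough that no ReLU/pooling kink is crossed
    mp <- m; mm2 <- m
    for (nm in names(v)) {
      mp$params[[nm]] <- mp$params[[nm]] + h * v[[nm]]
      mm2$params[[nm]] <- mm2$params[[nm]] - h * v[[nm]]
    }
    fd <- (lossfn(mp) - lossfn(mm2)) / (2 * h)
    expect_equal(an, fd, tolerance = 5e-3)
  }
})
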