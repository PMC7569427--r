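test_that("cross-entropy matches hand-computed values and label symmetry", {
  expect_lt(cross_entropy(c(1, 0, 1), c(1, 0, 1)), 3 * 1e-7 * 2)
  expect_equal(cross_entropy(0.5, 1), -log(0.5), tolerance = 1e-12)
  expect_equal(cross_entropy(0.5, 0), cross_entropy(0.5, 1))
  expect_equal(cross_entropy(c(0.5, 0.5), c(1, 0), reduction = "mean"),
               -log(0.5))
  expect_error(cross_entropy(c(0.5, 0.5), 1), "lengths")
})

test_that("dice loss follows the smoothed formula and its identities", {
  # perfect binary overlap -> exactly zero
  set.seed(1)
  for (i in 1:100) {
    y <- rbinom(20, 1, runif(1, 0.1, 0.9))
    expect_identical(dice_loss(y, y), 0)
  }
  expect_equal(dice_loss(rep(0, 10), rep(1, 10)), 1 - 1 / 11)
  expect_equal(dice_loss(rep(0, 5), rep(0, 5)), 0)
  # range: [0, 1) for valid inputs
  for (i in 1:50) {
    p <- runif(15); y <- rbinom(15, 1, 0.4)
    dl <- dice_loss(p, y)
    expect_gte(dl, 0); expect_lt(dl, 1)
  }
})

test_that("combined loss is exactly the sum of its terms", {
  set.seed(2)
  p <- runif(30); y <- rbinom(30, 1, 0.3)
  cfg <- loss_config()
  expect_identical(combined_loss(p, y, cfg),
                   cross_entropy(p, y, cfg$clip, cfg$reduction) +
                     dice_loss(p, y, cfg$smooth))
  # single-pixel worked example: CE -log(0.5), Dice 1 - 2/2.5
  expect_equal(combined_loss(0.5, 1), 0.6931472 + 0.2, tolerance = 1e-4)
  expect_lt(combined_loss(c(1, 0), c(1, 0)), 1e-5)
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  for (rep in 1:5) {
    p <- runif(12, 0.05, 0.95)
    y <- rbinom(12, 1, 0.5)
    h <- 1e-6
    for (fn in list(
      list(f = function(q) cross_entropy(q, y), g = function(q) cross_entropy_grad(q, y)),
      list(f = function(q) dice_loss(q, y), g = function(q) dice_loss_grad(q, y)),
      list(f = function(q) combined_loss(q, y), g = function(q) combined_loss_grad(q, y)))) {
      gr <- fn$g(p)
      for (k in sample(12, 4)) {
        pp <- p; pp[k] <- pp[k] + h
        pm <- p; pm[k] <- pm[k] - h
        fd <- (fn$f(pp) - fn$f(pm)) / (2 * h)
        expect_equal(gr[k], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("combined loss decreases monotonically towards the true labels", {
  set.seed(4)
  y <- rbinom(40, 1, 0.3)
  wrong <- 1 - y  # fully wrong binary prediction
  eps <- 1e-3     # keep the path strictly inside (0, 1)
  a <- pmin(pmax(wrong, eps), 1 - eps)
  b <- pmin(pmax(y, eps), 1 - eps)
  ts <- seq(0, 1, length.out = 10)
  losses <- vapply(ts, function(t) combined_loss((1 - t) * a + t * b, y),
                   numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("loss configuration validates its fields", {
  expect_error(loss_config(smooth = 0), "smooth")
  expect_error(loss_config(clip = 0.7), "clip")
})
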