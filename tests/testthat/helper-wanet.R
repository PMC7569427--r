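# Shared fixtures: everything is generated in code, seeded.

# A small network that still exercises all three levels and the pyramid.
tiny_config <- function(...) {
  network_config(slim_widths = c(2L, 4L, 6L), laspp_channels = 8L,
                 patch_size = 16L, ...)
}

tiny_model <- function(seed = 1L, ...) build_wa_net(tiny_config(...), seed = seed)

# Seeded stack of random patches + binary labels.
tiny_patches <- function(n = 24L, size = 16L, seed = 5L) {
  set.seed(seed)
  list(x = array(runif(size * size * n), c(size, size, n)),
       y = array(rbinom(size * size * n, 1L, 0.3), c(size, size, n)))
}

# Independent single-layer atrous convolution oracle operating on an
# (H, W) matrix with a single-channel 3x3 kernel, zero padding. Used to
# cross-check receptive fields by impulse response.
naive_atrous <- function(x, kernel3, d) {
  H <- nrow(x); W <- ncol(x)
  y <- matrix(0, H, W)
  for (a in -1:1) for (b in -1:1) {
    w <- kernel3[a + 2, b + 2]
    if (w == 0) next
    for (i in 1:H) for (j in 1:W) {
      si <- i + a * d; sj <- j + b * d
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        y[i, j] <- y[i, j] + w * x[si, sj]
    }
  }
  y
}

# All-pairs (Mann-Whitney) AUC with half credit for ties.
rank_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
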