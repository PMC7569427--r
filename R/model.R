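#' Receptive field of an atrous convolution layer
#'
#' For a convolution with kernel size \code{k} and dilation rate \code{d},
#' the taps of the kernel are spaced \code{d} pixels apart, so one layer sees
#' \code{(k - 1) * (d - 1) + k} input pixels per axis.
#'
#' @param k odd kernel size (pixels), k >= 1.
#' @param d dilation rate, d >= 1.
#' @return Integer receptive-field size in pixels.
#' @examples
#' receptive_field(3, 3) # 7
#' @export
receptive_field <- function(k, d) {
  if (length(k) != 1L || length(d) != 1L || k < 1 || d < 1)
    stop("receptive_field: k and d must be positive scalars")
  if (k %% 2 == 0) stop("receptive_field: kernel size must be odd")
  as.integer((k - 1) * (d - 1) + k)
}

#' Weight count of an original (equal-width) residual block
#'
#' A residual block whose two convolutions both carry \code{c1} input and
#' output channels holds \code{2 * c1^2 * k^2} convolution weights
#' (biases excluded).
#'
#' @param c1 channel width of both convolutions.
#' @param k kernel size.
#' @return Integer weight count.
#' @export
original_block_params <- function(c1, k = 3) {
  if (c1 < 1 || k < 1) stop("original_block_params: c1 and k must be >= 1")
  as.integer(2 * c1^2 * k^2)
}

#' Widths of a wide-activation residual block
#'
#' In a wide-activation block the identity path is slimmed to
#' \code{slim} channels and the features are expanded to
#' \code{r * slim} channels before the ReLU. Matching the weight count of an
#' equal-width block of width \code{c1} requires \code{c1^2 = slim * (r * slim)},
#' i.e. \code{c1 = slim * sqrt(r)}.
#'
#' @param slim identity-path width (channels).
#' @param r expansion factor (default 4).
#' @param k kernel size.
#' @return A \code{block_spec}: slim, expanded and equivalent widths, with
#'   \code{exact = TRUE} when \code{r * slim^2} is a perfect square so the
#'   complexity identity holds as an integer equality.
#' @export
wide_block_widths <- function(slim, r = 4, k = 3) {
  if (slim < 1 || r <= 0) stop("wide_block_widths: slim >= 1 and r > 0 required")
  expanded <- as.integer(round(r * slim))
  eq <- sqrt(slim * expanded)
  structure(list(
    slim_width = as.integer(slim),
    expansion = r,
    kernel = as.integer(k),
    expanded_width = expanded,
    equivalent_width = as.integer(round(eq)),
    exact = abs(eq - round(eq)) < 1e-9
  ), class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("wide-activation block: slim %d -> expanded %d (r = %g, k = %d)\n",
              x$slim_width, x$expanded_width, x$expansion, x$kernel))
  cat(sprintf("equivalent equal-width block: %d channels%s\n", x$equivalent_width,
              if (x$exact) "" else " (rounded; complexity identity inexact)"))
  invisible(x)
}

#' Weight normalization
#'
#' Reparameterises a weight vector as a direction times a scalar norm:
#' \code{w = g * N / ||N||}, so that \code{||w|| = g} independently of
#' \code{N}. Applied per output channel inside the network's
#' weight-normalised convolutions.
#'
#' @param N direction array (any shape), nonzero norm.
#' @param g target Euclidean norm (scalar).
#' @return Array of the same shape as \code{N} with norm \code{g}.
#' @examples
#' weight_normalize(c(3, 4), 10) # c(6, 8)
#' @export
weight_normalize <- function(N, g) {
  nrm <- sqrt(sum(N^2))
  if (nrm == 0) stop("weight_normalize: N has zero norm; direction undefined")
  g / nrm * N
}

#' Leaky rectified linear unit
#'
#' \code{f(x) = x} for \code{x > 0} and \code{a * x} otherwise; reduces to
#' ReLU at \code{a = 0}. The network uses \code{a = 0.3} in its output head.
#'
#' @param x numeric array.
#' @param a slope of the negative part.
#' @export
leaky_relu <- function(x, a = 0.3) {
  ifelse(x > 0, x, a * x)
}

# ---------------------------------------------------------------------------
# Parameter registry construction
# ---------------------------------------------------------------------------

# Shape plan for one wide-activation block. `wn` turns every convolution into
# a (V, g) weight-normalised pair.
.wdsr_shapes <- function(prefix, cin, slim, r, wn) {
  exp_w <- as.integer(round(r * slim))
  sh <- list()
  wkey <- if (wn) "V" else "W"
  sh[[paste0(prefix, ".conv1.", wkey)]] <- c(9L * cin, exp_w)
  if (wn) sh[[paste0(prefix, ".conv1.g")]] <- exp_w
  sh[[paste0(prefix, ".conv1.b")]] <- exp_w
  sh[[paste0(prefix, ".conv2.", wkey)]] <- c(9L * exp_w, slim)
  if (wn) sh[[paste0(prefix, ".conv2.g")]] <- slim
  sh[[paste0(prefix, ".conv2.b")]] <- slim
  if (cin != slim) {
    sh[[paste0(prefix, ".id.W")]] <- c(cin, slim)
    sh[[paste0(prefix, ".id.b")]] <- slim
  }
  sh
}

# Shape plan for one pre-activated residual block (BN-ReLU-Conv twice).
.preact_shapes <- function(prefix, cin, width) {
  sh <- list()
  sh[[paste0(prefix, ".bn1.gamma")]] <- cin
  sh[[paste0(prefix, ".bn1.beta")]] <- cin
  sh[[paste0(prefix, ".conv1.W")]] <- c(9L * cin, width)
  sh[[paste0(prefix, ".conv1.b")]] <- width
  sh[[paste0(prefix, ".bn2.gamma")]] <- width
  sh[[paste0(prefix, ".bn2.beta")]] <- width
  sh[[paste0(prefix, ".conv2.W")]] <- c(9L * width, width)
  sh[[paste0(prefix, ".conv2.b")]] <- width
  if (cin != width) {
    sh[[paste0(prefix, ".id.W")]] <- c(cin, width)
    sh[[paste0(prefix, ".id.b")]] <- width
  }
  sh
}

.laspp_shapes <- function(prefix, cin, channels, dilations, wn) {
  sh <- list()
  for (j in seq_along(dilations)) {
    br <- paste0(prefix, ".branch", j)
    if (wn) {
      sh[[paste0(br, ".V")]] <- c(9L * cin, channels)
      sh[[paste0(br, ".g")]] <- channels
    } else {
      sh[[paste0(br, ".W")]] <- c(9L * cin, channels)
    }
    sh[[paste0(br, ".b")]] <- channels
  }
  sh
}

#' Network hyperparameter record
#'
#' Collects every architectural choice of the segmentation network: the slim
#' widths of the three encoder levels (the decoder mirrors them), the atrous
#' pyramid width and dilation rates, the wide-activation expansion factor,
#' the leaky-ReLU slope of the output head, and where weight normalization
#' is applied. The named ablation variants reconfigure these fields.
#'
#' @param variant one of \code{"wa_net"}, \code{"network_1"} ...
#'   \code{"network_4"}.
#' @param slim_widths identity-path widths of encoder levels 1..3.
#' @param laspp_channels channels of every atrous pyramid branch.
#' @param laspp_dilations dilation rates of the pyramid branches.
#' @param r expansion factor inside wide-activation blocks.
#' @param leaky_slope negative slope of the head's leaky ReLUs.
#' @param patch_size input patch side (must be divisible by 8).
#' @param in_channels input channels (1 for grayscale patches).
#' @param classes output classes (2: background / vessel).
#' @param wn_all apply weight normalization to all convolutions, not only
#'   the pyramid branches.
#' @return A \code{network_config} list.
#' @export
network_config <- function(variant = "wa_net",
                           slim_widths = c(16L, 32L, 64L),
                           laspp_channels = 128L,
                           laspp_dilations = c(1L, 2L, 4L, 8L),
                           r = 4,
                           leaky_slope = 0.3,
                           patch_size = 48L,
                           in_channels = 1L,
                           classes = 2L,
                           wn_all = FALSE) {
  variant <- match.arg(variant,
                       c("wa_net", "network_1", "network_2", "network_3", "network_4"))
  cfg <- list(variant = variant,
              block_type = "wdsr_a",
              slim_widths = as.integer(slim_widths),
              laspp_channels = as.integer(laspp_channels),
              laspp_dilations = as.integer(laspp_dilations),
              r = r,
              leaky_slope = leaky_slope,
              patch_size = as.integer(patch_size),
              in_channels = as.integer(in_channels),
              classes = as.integer(classes),
              wn_laspp = TRUE,
              wn_all = wn_all)
  if (variant == "network_1") {
    cfg$block_type <- "preact"
    cfg$wn_laspp <- FALSE
    cfg$wn_all <- FALSE
  } else if (variant == "network_2") {
    cfg$block_type <- "preact"
    cfg$wn_laspp <- FALSE
    cfg$wn_all <- FALSE
    cfg$slim_widths <- c(32L, 64L, 128L)
    cfg$laspp_channels <- 256L
  } else if (variant == "network_3") {
    cfg$laspp_dilations <- c(1L, 2L, 4L)
  } else if (variant == "network_4") {
    cfg$laspp_dilations <- c(1L, 2L, 4L, 8L, 16L)
  }
  if (length(cfg$slim_widths) != 3L)
    stop("network_config: exactly three encoder levels are supported")
  if (cfg$patch_size %% 8L != 0L)
    stop("network_config: patch_size must be divisible by 8 (three 2x2 poolings)")
  structure(cfg, class = "network_config")
}

# Full shape plan of the network's parameter registry.
.network_shapes <- function(cfg) {
  sw <- cfg$slim_widths
  wn_blocks <- cfg$wn_all && cfg$block_type == "wdsr_a"
  sh <- list()
  sh[["bn0.gamma"]] <- cfg$in_channels
  sh[["bn0.beta"]] <- cfg$in_channels
  cin <- cfg$in_channels
  for (i in 1:3) {
    pre <- paste0("enc", i)
    sh <- c(sh, if (cfg$block_type == "wdsr_a")
      .wdsr_shapes(pre, cin, sw[i], cfg$r, wn_blocks)
      else .preact_shapes(pre, cin, sw[i]))
    cin <- sw[i]
  }
  sh <- c(sh, .laspp_shapes("laspp", sw[3], cfg$laspp_channels,
                            cfg$laspp_dilations, cfg$wn_laspp))
  below <- cfg$laspp_channels
  for (i in 3:1) {
    pre <- paste0("dec", i)
    sh[[paste0(pre, ".upconv.W")]] <- c(9L * below, sw[i])
    sh[[paste0(pre, ".upconv.b")]] <- sw[i]
    cat_ch <- 2L * sw[i]  # upsampled features concatenated with the skip
    sh <- c(sh, if (cfg$block_type == "wdsr_a")
      .wdsr_shapes(pre, cat_ch, sw[i], cfg$r, wn_blocks)
      else .preact_shapes(pre, cat_ch, sw[i]))
    below <- sw[i]
  }
  sh[["head.shortcut.W"]] <- c(cfg$in_channels, sw[1])
  sh[["head.shortcut.b"]] <- sw[1]
  sh[["head.cls.W"]] <- c(sw[1], cfg$classes)
  sh[["head.cls.b"]] <- cfg$classes
  sh
}

# He-normal initialisation of a parameter registry given its shape plan.
# Kernel entries (W or V) are N(0, 2/fan_in); biases and BN betas start at
# zero, BN gammas at one; WN scales g start at the column norms of V so the
# effective weight initially equals V itself.
.init_registry <- function(shapes) {
  params <- list()
  for (nm in names(shapes)) {
    dm <- shapes[[nm]]
    leaf <- sub(".*\\.", "", nm)
    if (leaf %in% c("W", "V")) {
      fan_in <- dm[1]
      params[[nm]] <- matrix(stats::rnorm(prod(dm), sd = sqrt(2 / fan_in)),
                             dm[1], dm[2])
    } else if (leaf == "gamma") {
      params[[nm]] <- rep(1, dm)
    } else {
      params[[nm]] <- rep(0, dm)  # b, beta; g is fixed up below
    }
  }
  for (nm in names(params)) {
    if (grepl("\\.g$", nm)) {
      vn <- sub("\\.g$", ".V", nm)
      params[[nm]] <- sqrt(colSums(params[[vn]]^2))
    }
  }
  params
}

.bn_names <- function(params) {
  unique(sub("\\.(gamma|beta)$", "", grep("\\.gamma$", names(params), value = TRUE)))
}

.fresh_state <- function(params, shapes) {
  st <- new.env(parent = emptyenv())
  for (bn in .bn_names(params)) {
    n <- length(params[[paste0(bn, ".gamma")]])
    st[[bn]] <- list(running_mean = rep(0, n), running_var = rep(1, n))
  }
  st
}

#' Build the segmentation network
#'
#' Assembles the encoder-decoder: a single input batch normalization, three
#' residual blocks (wide-activation or pre-activated, per the variant) each
#' followed by 2x2 max pooling, the atrous spatial pyramid at the bottom,
#' three decoder stages (2x nearest-neighbour upsampling + 3x3 convolution,
#' concatenation with the encoder skip at that resolution, residual block),
#' and a head that sums a leaky ReLU on the decoder output with a leaky ReLU
#' on a global 1x1-convolution shortcut from the post-BN input, then applies
#' a 1x1 convolution to two channels with per-pixel softmax.
#'
#' @param cfg a \code{\link{network_config}}.
#' @param seed RNG seed for the He-normal initialisation (reproducible
#'   builds); \code{NULL} uses the current RNG state.
#' @return A \code{wanet_model} with fields \code{config}, \code{params}
#'   (named registry of arrays) and \code{state} (batch-norm running
#'   statistics).
#' @export
build_wa_net <- function(cfg = network_config(), seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  shapes <- .network_shapes(cfg)
  if (!is.null(seed)) set.seed(seed)
  params <- .init_registry(shapes)
  structure(list(config = cfg, params = params, shapes = shapes,
                 state = .fresh_state(params, shapes)),
            class = "wanet_model")
}

#' Build an ablation variant of the network
#'
#' \code{network_1} replaces the wide-activation blocks with pre-activated
#' residual blocks (BN-ReLU-Conv, twice) and removes weight normalization
#' from the pyramid; \code{network_2} additionally widens the channel
#' sequence to 32-64-128-256-128-64-32; \code{network_3} keeps the base
#' network but uses three pyramid branches (d = 1, 2, 4); \code{network_4}
#' uses five (d = 1, 2, 4, 8, 16).
#'
#' @param name variant name, \code{"network_1"} .. \code{"network_4"} (or
#'   \code{"wa_net"} for the base network).
#' @param patch_size,seed passed to the builder.
#' @export
build_variant <- function(name, patch_size = 48L, seed = NULL) {
  build_wa_net(network_config(variant = name, patch_size = patch_size),
               seed = seed)
}

#' Count parameters of a model or block
#'
#' @param x a \code{wanet_model} or standalone block.
#' @param what \code{"all"} counts every trainable scalar;
#'   \code{"conv_weights"} counts convolution kernel entries only (the
#'   quantity entering the wide-activation complexity identity).
#' @return Integer count.
#' @export
count_params <- function(x, what = c("all", "conv_weights")) {
  what <- match.arg(what)
  params <- if (!is.null(x$params)) x$params else x
  keep <- if (what == "conv_weights")
    grepl("\\.(W|V)$", names(params)) else rep(TRUE, length(params))
  sum(vapply(params[keep], length, integer(1)))
}

#' @export
print.wanet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("wanet_model (%s): patch %dx%d, widths %s, pyramid %d ch d=[%s]\n",
              cfg$variant, cfg$patch_size, cfg$patch_size,
              paste(cfg$slim_widths, collapse = "/"),
              cfg$laspp_channels, paste(cfg$laspp_dilations, collapse = ",")))
  cat(sprintf("parameters: %d (%d conv weights)\n",
              count_params(x), count_params(x, "conv_weights")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Standalone blocks (usable outside the full network, e.g. for probing
# receptive fields or parameter counts)
# ---------------------------------------------------------------------------

#' Build a standalone wide-activation residual block
#'
#' Computes \code{y = identity(x) + conv2(relu(conv1(x)))} where conv1
#' expands the channels by the factor \code{r} and conv2 slims them back to
#' the identity-path width. The identity path is a 1x1 convolution when the
#' input channel count differs from the slim width, else a pass-through.
#'
#' @param spec a \code{\link{wide_block_widths}} result.
#' @param wn apply weight normalization to the two convolutions.
#' @param in_channels input channels (defaults to the slim width).
#' @param seed RNG seed for initialisation.
#' @export
build_wdsr_a <- function(spec, wn = FALSE, in_channels = spec$slim_width,
                         seed = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  shapes <- .wdsr_shapes("block", in_channels, spec$slim_width, spec$expansion, wn)
  if (!is.null(seed)) set.seed(seed)
  structure(list(type = "wdsr_a", spec = spec, in_channels = in_channels,
                 wn = wn, params = .init_registry(shapes)),
            class = "wanet_block")
}

#' Build a standalone atrous spatial pyramid block
#'
#' Parallel 3x3 atrous convolutions with the given dilation rates act on the
#' same input; each is followed by ReLU and the branch outputs are summed
#' element-wise.
#'
#' @param channels output channels of every branch.
#' @param dilations dilation rates, one per branch.
#' @param wn apply weight normalization to the branch convolutions.
#' @param in_channels input channels.
#' @param seed RNG seed for initialisation.
#' @export
build_laspp <- function(channels = 128L, dilations = c(1L, 2L, 4L, 8L),
                        wn = TRUE, in_channels = channels, seed = NULL) {
  if (any(dilations < 1)) stop("build_laspp: dilations must be >= 1")
  shapes <- .laspp_shapes("block", in_channels, channels, dilations, wn)
  if (!is.null(seed)) set.seed(seed)
  structure(list(type = "laspp", channels = as.integer(channels),
                 dilations = as.integer(dilations), in_channels = in_channels,
                 wn = wn, params = .init_registry(shapes)),
            class = "wanet_block")
}

#' Apply a standalone block to a feature map
#'
#' @param block a \code{\link{build_wdsr_a}} or \code{\link{build_laspp}}
#'   result.
#' @param x numeric array of shape (H, W, C) with C equal to the block's
#'   input channels.
#' @return Array (H, W, C_out).
#' @export
block_forward <- function(block, x) {
  stopifnot(inherits(block, "wanet_block"), length(dim(x)) == 3L)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  if (C != block$in_channels)
    stop(sprintf("block_forward: expected %d input channels, got %d",
                 block$in_channels, C))
  X <- nhwc_from_array(x)
  p <- .strip_prefix(block$params, "block.")
  Y <- if (block$type == "wdsr_a")
    .wdsr_forward(p, X, 1L, H, W, wn = block$wn, slope = NULL)$Y
  else
    .laspp_forward(p, X, 1L, H, W, block$dilations, wn = block$wn)$Y
  array_from_nhwc(Y, 1L, H, W)[, , , 1L]
}

.strip_prefix <- function(params, prefix) {
  sel <- startsWith(names(params), prefix)
  out <- params[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

# ---------------------------------------------------------------------------
# Layout helpers: (H, W, C, N) arrays <-> (N*H*W, C) matrices
# ---------------------------------------------------------------------------

# x: array (H, W, C) or (H, W, C, N) -> matrix (N*H*W, C), rows scanned
# image-major, then row-major within an image.
nhwc_from_array <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) == 3L) dim(x) <- d <- c(d, 1L)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  # target row p = (n-1)HW + (i-1)W + j; build via aperm to (W, H, N, C)
  m <- aperm(x, c(2L, 1L, 4L, 3L))
  dim(m) <- c(H * W * N, C)
  m
}

array_from_nhwc <- function(X, N, H, W) {
  C <- ncol(X)
  dim(X) <- c(W, H, N, C)
  aperm(X, c(2L, 1L, 4L, 3L))
}

# ---------------------------------------------------------------------------
# Block-level forward/backward
# ---------------------------------------------------------------------------

.conv_eff <- function(p, name, wn) {
  if (wn) wn_effective(p[[paste0(name, ".V")]], p[[paste0(name, ".g")]])
  else p[[paste0(name, ".W")]]
}

.wdsr_forward <- function(p, X, N, H, W, wn, slope = NULL) {
  W1 <- .conv_eff(p, "conv1", wn)
  W2 <- .conv_eff(p, "conv2", wn)
  a1 <- conv3_forward(X, N, H, W, W1, p[["conv1.b"]], relu = TRUE)
  idp <- if (!is.null(p[["id.W"]]))
    conv1_forward(X, p[["id.W"]], p[["id.b"]]) else X
  Y <- conv3_forward(a1, N, H, W, W2, p[["conv2.b"]], add = idp)
  list(Y = Y, X = X, a1 = a1, W1 = W1, W2 = W2, N = N, H = H, W = W)
}

.wdsr_backward <- function(p, cache, dY, wn) {
  g <- list()
  bw2 <- conv3_backward(dY, cache$a1, cache$N, cache$H, cache$W, cache$W2)
  da1 <- cpp_relu_bwd(bw2$dX, cache$a1)
  if (!is.null(p[["id.W"]])) {
    bid <- conv1_backward(dY, cache$X, p[["id.W"]])
    g[["id.W"]] <- bid$dW; g[["id.b"]] <- bid$db
    id_dx <- bid$dX
  } else {
    id_dx <- dY
  }
  bw1 <- conv3_backward(da1, cache$X, cache$N, cache$H, cache$W, cache$W1,
                        add = id_dx)
  dX <- bw1$dX
  if (wn) {
    w1 <- wn_backward(bw1$dW, p[["conv1.V"]], p[["conv1.g"]])
    w2 <- wn_backward(bw2$dW, p[["conv2.V"]], p[["conv2.g"]])
    g[["conv1.V"]] <- w1$dV; g[["conv1.g"]] <- w1$dg
    g[["conv2.V"]] <- w2$dV; g[["conv2.g"]] <- w2$dg
  } else {
    g[["conv1.W"]] <- bw1$dW
    g[["conv2.W"]] <- bw2$dW
  }
  g[["conv1.b"]] <- bw1$db
  g[["conv2.b"]] <- bw2$db
  list(dX = dX, grads = g)
}

.preact_forward <- function(p, X, N, H, W, training, state, key) {
  k1 <- paste0(key, ".bn1"); k2 <- paste0(key, ".bn2")
  b1 <- bn_forward(X, p[["bn1.gamma"]], p[["bn1.beta"]], training, state[[k1]])
  a1 <- relu_forward(b1$Y)
  h1 <- conv3_forward(a1, N, H, W, p[["conv1.W"]], p[["conv1.b"]])
  b2 <- bn_forward(h1, p[["bn2.gamma"]], p[["bn2.beta"]], training, state[[k2]])
  a2 <- relu_forward(b2$Y)
  idp <- if (!is.null(p[["id.W"]]))
    conv1_forward(X, p[["id.W"]], p[["id.b"]]) else X
  h2 <- conv3_forward(a2, N, H, W, p[["conv2.W"]], p[["conv2.b"]], add = idp)
  if (training) {
    state[[k1]] <- b1$state
    state[[k2]] <- b2$state
  }
  list(Y = h2, X = X, a1 = a1, a2 = a2, bn1 = b1, bn2 = b2,
       h1 = h1, N = N, H = H, W = W)
}

.preact_backward <- function(p, cache, dY) {
  g <- list()
  bw2 <- conv3_backward(dY, cache$a2, cache$N, cache$H, cache$W, p[["conv2.W"]])
  bb2 <- bn_backward(cpp_relu_bwd(bw2$dX, cache$a2), cache$bn2, p[["bn2.gamma"]])
  bw1 <- conv3_backward(bb2$dX, cache$a1, cache$N, cache$H, cache$W, p[["conv1.W"]])
  bb1 <- bn_backward(cpp_relu_bwd(bw1$dX, cache$a1), cache$bn1, p[["bn1.gamma"]])
  dX <- bb1$dX
  if (!is.null(p[["id.W"]])) {
    bid <- conv1_backward(dY, cache$X, p[["id.W"]])
    dX <- dX + bid$dX
    g[["id.W"]] <- bid$dW; g[["id.b"]] <- bid$db
  } else {
    dX <- dX + dY
  }
  g[["conv1.W"]] <- bw1$dW; g[["conv1.b"]] <- bw1$db
  g[["conv2.W"]] <- bw2$dW; g[["conv2.b"]] <- bw2$db
  g[["bn1.gamma"]] <- bb1$dgamma; g[["bn1.beta"]] <- bb1$dbeta
  g[["bn2.gamma"]] <- bb2$dgamma; g[["bn2.beta"]] <- bb2$dbeta
  list(dX = dX, grads = g)
}

.laspp_forward <- function(p, X, N, H, W, dilations, wn) {
  acts <- vector("list", length(dilations))
  Weff <- vector("list", length(dilations))
  Y <- NULL
  for (j in seq_along(dilations)) {
    br <- paste0("branch", j)
    Wj <- .conv_eff(p, br, wn)
    aj <- conv3_forward(X, N, H, W, Wj, p[[paste0(br, ".b")]],
                        d = dilations[j], relu = TRUE)
    acts[[j]] <- aj
    Weff[[j]] <- Wj
    Y <- if (is.null(Y)) aj else Y + aj
  }
  list(Y = Y, X = X, acts = acts, Weff = Weff, N = N, H = H, W = W)
}

.laspp_backward <- function(p, cache, dY, dilations, wn) {
  g <- list()
  dX <- NULL
  for (j in seq_along(dilations)) {
    br <- paste0("branch", j)
    dh <- cpp_relu_bwd(dY, cache$acts[[j]])
    bw <- conv3_backward(dh, cache$X, cache$N, cache$H, cache$W,
                         cache$Weff[[j]], d = dilations[j])
    dX <- if (is.null(dX)) bw$dX else dX + bw$dX
    if (wn) {
      wb <- wn_backward(bw$dW, p[[paste0(br, ".V")]], p[[paste0(br, ".g")]])
      g[[paste0(br, ".V")]] <- wb$dV
      g[[paste0(br, ".g")]] <- wb$dg
    } else {
      g[[paste0(br, ".W")]] <- bw$dW
    }
    g[[paste0(br, ".b")]] <- bw$db
  }
  list(dX = dX, grads = g)
}

# ---------------------------------------------------------------------------
# Full network forward / backward
# ---------------------------------------------------------------------------

# X: (N*S*S, in_channels) matrix of patches. Returns per-pixel class
# probabilities and, when keep_cache, everything the backward pass needs.
wa_forward <- function(model, X, N, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  S <- cfg$patch_size
  sw <- cfg$slim_widths
  wn_blk <- cfg$wn_all && cfg$block_type == "wdsr_a"
  cc <- list()

  # single input batch normalization
  bn0st <- st[["bn0"]]
  b0 <- bn_forward(X, p[["bn0.gamma"]], p[["bn0.beta"]], training, bn0st)
  if (training) st[["bn0"]] <- b0$state
  x0 <- b0$Y
  cc$bn0 <- b0

  cur <- x0
  H <- S; W <- S
  skips <- list(); pools <- list(); enc <- list()
  for (i in 1:3) {
    pre <- paste0("enc", i, ".")
    bp <- .strip_prefix(p, pre)
    fw <- if (cfg$block_type == "wdsr_a")
      .wdsr_forward(bp, cur, N, H, W, wn_blk)
    else .preact_forward(bp, cur, N, H, W, training, st, paste0("enc", i))
    enc[[i]] <- fw
    skips[[i]] <- fw$Y
    pl <- maxpool2_forward(fw$Y, N, H, W)
    pools[[i]] <- pl
    cur <- pl$Y
    H <- H %/% 2L; W <- W %/% 2L
  }

  lsp <- .laspp_forward(.strip_prefix(p, "laspp."), cur, N, H, W,
                        cfg$laspp_dilations, cfg$wn_laspp)
  cur <- lsp$Y

  dec <- list(); ups <- list()
  for (i in 3:1) {
    pre <- paste0("dec", i, ".")
    bp <- .strip_prefix(p, pre)
    up <- upsample2_forward(cur, N, H, W)
    Hu <- 2L * H; Wu <- 2L * W
    uc <- conv3_forward(up, N, Hu, Wu, bp[["upconv.W"]], bp[["upconv.b"]])
    cat_in <- cbind(uc, skips[[i]])
    fw <- if (cfg$block_type == "wdsr_a")
      .wdsr_forward(bp, cat_in, N, Hu, Wu, wn_blk)
    else .preact_forward(bp, cat_in, N, Hu, Wu, training, st, paste0("dec", i))
    ups[[i]] <- list(up_in = up, H = H, W = W, Hu = Hu, Wu = Wu)
    dec[[i]] <- fw
    cur <- fw$Y
    H <- Hu; W <- Wu
  }

  a <- cfg$leaky_slope
  hd_pre <- cur
  hd <- cpp_leaky_relu(hd_pre, a)
  sc_pre <- conv1_forward(x0, p[["head.shortcut.W"]], p[["head.shortcut.b"]])
  sc <- cpp_leaky_relu(sc_pre, a)
  ssum <- hd + sc
  logits <- conv1_forward(ssum, p[["head.cls.W"]], p[["head.cls.b"]])
  zmax <- pmax(logits[, 1L], logits[, 2L])
  ez <- exp(logits - zmax)
  prob <- ez / rowSums(ez)

  out <- list(prob = prob, logits = logits, N = N)
  if (keep_cache) {
    out$cache <- list(X = X, x0 = x0, bn0 = b0, enc = enc, pools = pools,
                      skips = skips, laspp = lsp, dec = dec, ups = ups,
                      hd_pre = hd_pre, sc_pre = sc_pre, ssum = ssum)
  }
  out
}

# Backward pass from a gradient w.r.t. the logits. Returns the parameter
# gradient registry (same names as model$params).
wa_backward <- function(model, fw, dLogits) {
  cfg <- model$config
  p <- model$params
  cc <- fw$cache
  a <- cfg$leaky_slope
  wn_blk <- cfg$wn_all && cfg$block_type == "wdsr_a"
  G <- list()
  add_g <- function(prefix, g) {
    for (nm in names(g)) G[[paste0(prefix, nm)]] <<- g[[nm]]
  }

  bcls <- conv1_backward(dLogits, cc$ssum, p[["head.cls.W"]])
  G[["head.cls.W"]] <- bcls$dW; G[["head.cls.b"]] <- bcls$db
  dsum <- bcls$dX
  dhd <- dsum * (a + (1 - a) * (cc$hd_pre > 0))
  dsc <- dsum * (a + (1 - a) * (cc$sc_pre > 0))
  bsc <- conv1_backward(dsc, cc$x0, p[["head.shortcut.W"]])
  G[["head.shortcut.W"]] <- bsc$dW; G[["head.shortcut.b"]] <- bsc$db
  dx0 <- bsc$dX  # accumulated below with the encoder path

  N <- fw$N
  dcur <- dhd
  for (i in 1:3) {  # decoder stages in reverse topological order (1,2,3)
    pre <- paste0("dec", i, ".")
    bp <- .strip_prefix(p, pre)
    fwB <- cc$dec[[i]]
    bk <- if (cfg$block_type == "wdsr_a")
      .wdsr_backward(bp, fwB, dcur, wn_blk)
    else .preact_backward(bp, fwB, dcur)
    add_g(pre, bk$grads)
    sw_i <- cfg$slim_widths[i]
    duc <- bk$dX[, seq_len(ncol(bk$dX) - sw_i), drop = FALSE]
    dskip <- bk$dX[, (ncol(bk$dX) - sw_i + 1L):ncol(bk$dX), drop = FALSE]
    ui <- cc$ups[[i]]
    buc <- conv3_backward(duc, ui$up_in, N, ui$Hu, ui$Wu, bp[["upconv.W"]])
    G[[paste0(pre, "upconv.W")]] <- buc$dW
    G[[paste0(pre, "upconv.b")]] <- buc$db
    dbelow <- upsample2_backward(buc$dX, N, ui$H, ui$W)
    # stash the skip gradient for the encoder sweep
    cc$skip_grad[[i]] <- dskip
    dcur <- dbelow
  }

  blsp <- .laspp_backward(.strip_prefix(p, "laspp."), cc$laspp, dcur,
                          cfg$laspp_dilations, cfg$wn_laspp)
  add_g("laspp.", blsp$grads)
  dcur <- blsp$dX

  for (i in 3:1) {
    dpool <- maxpool2_backward(dcur, cc$pools[[i]])
    dblk <- dpool + cc$skip_grad[[i]]
    pre <- paste0("enc", i, ".")
    bp <- .strip_prefix(p, pre)
    bk <- if (cfg$block_type == "wdsr_a")
      .wdsr_backward(bp, cc$enc[[i]], dblk, wn_blk)
    else .preact_backward(bp, cc$enc[[i]], dblk)
    add_g(pre, bk$grads)
    dcur <- bk$dX
  }

  dx0 <- dx0 + dcur
  bb0 <- bn_backward(dx0, cc$bn0, p[["bn0.gamma"]])
  G[["bn0.gamma"]] <- bb0$dgamma
  G[["bn0.beta"]] <- bb0$dbeta
  G
}

#' Run the network on a stack of patches
#'
#' @param model a \code{wanet_model}.
#' @param patches array (S, S, N) or (S, S, 1, N) of grayscale patches with
#'   S equal to the model's patch size.
#' @param batch_size forward mini-batch size (memory control only).
#' @return Array (S, S, 2, N) of per-pixel class probabilities
#'   (channel 1 background, channel 2 vessel).
#' @export
predict_patches <- function(model, patches, batch_size = 128L) {
  stopifnot(inherits(model, "wanet_model"))
  d <- dim(patches)
  if (length(d) == 2L) dim(patches) <- d <- c(d, 1L)
  if (length(d) == 3L) dim(patches) <- d <- c(d[1], d[2], 1L, d[3])
  S <- model$config$patch_size
  if (d[1] != S || d[2] != S)
    stop(sprintf("predict_patches: patches must be %dx%d", S, S))
  N <- d[4]
  out <- array(0, c(S, S, model$config$classes, N))
  for (start in seq(1L, N, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, N)
    X <- nhwc_from_array(patches[, , , sel, drop = FALSE])
    fw <- wa_forward(model, X, length(sel))
    out[, , , sel] <- array_from_nhwc(fw$prob, length(sel), S, S)
  }
  out
}
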