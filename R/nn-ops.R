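# Internal tensor primitives for the segmentation network.
#
# Feature maps are stored as dense matrices of shape (N*H*W, C): one row per
# spatial position (images stacked, rows scanned row-major within an image),
# one column per channel. The 3x3 convolutions, pooling and upsampling run
# in compiled code (src/convops.cpp); 1x1 convolutions and batch
# normalisation stay in R on BLAS.

# 3x3 (possibly atrous) convolution, "same" zero padding, evaluated by the
# compiled direct kernel.
# X: (N*H*W, Cin); Wmat: (9*Cin, Cout) with tap-major row blocks; b: (Cout).
conv3_forward <- function(X, N, H, W, Wmat, b, d = 1L, relu = FALSE,
                          add = NULL) {
  cpp_conv3_fwd(X, N, H, W, Wmat,
                if (is.null(b)) numeric(0) else b, as.integer(d), relu, add)
}

# Backward pass of conv3_forward. X is the saved layer input; `add` is an
# optional matrix accumulated onto the input gradient (residual branches).
conv3_backward <- function(dY, X, N, H, W, Wmat, d = 1L, add = NULL) {
  list(dX = cpp_conv3_dx(dY, N, H, W, Wmat, as.integer(d), add),
       dW = cpp_conv3_dw(X, dY, N, H, W, as.integer(d)),
       db = colSums(dY))
}

# 1x1 convolution is a plain affine map over channels.
conv1_forward <- function(X, Wmat, b) {
  Y <- X %*% Wmat
  if (!is.null(b)) Y <- sweep(Y, 2L, b, "+")
  Y
}

conv1_backward <- function(dY, X, Wmat) {
  list(dX = tcrossprod(dY, Wmat), dW = crossprod(X, dY), db = colSums(dY))
}

# 2x2 max pooling, stride 2. Returns pooled map and the argmax rows needed
# for the backward scatter. H and W must be even.
maxpool2_forward <- function(X, N, H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  cpp_maxpool2(X, N, H, W)
}

maxpool2_backward <- function(dY, pool) {
  cpp_maxpool2_bwd(dY, pool$argmax, as.integer(pool$in_rows))
}

# Nearest-neighbour 2x upsampling and its adjoint (sum over each 2x2 group).
upsample2_forward <- function(X, N, H, W) cpp_upsample2(X, N, H, W)

upsample2_backward <- function(dY, N, H, W) cpp_upsample2_bwd(dY, N, H, W)

# Batch normalisation over all rows, per channel (population variance).
bn_forward <- function(X, gamma, beta, training, state, eps = 1e-5, momentum = 0.99) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    state$running_mean <- momentum * state$running_mean + (1 - momentum) * mu
    state$running_var <- momentum * state$running_var + (1 - momentum) * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  invstd <- 1 / sqrt(v + eps)
  Xhat <- sweep(sweep(X, 2L, mu, "-"), 2L, invstd, "*")
  Y <- sweep(sweep(Xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(Y = Y, Xhat = Xhat, invstd = invstd, state = state)
}

bn_backward <- function(dY, cache, gamma) {
  m <- nrow(dY)
  Xhat <- cache$Xhat
  dgamma <- colSums(dY * Xhat)
  dbeta <- colSums(dY)
  dXhat <- sweep(dY, 2L, gamma, "*")
  s1 <- colSums(dXhat)
  s2 <- colSums(dXhat * Xhat)
  dX <- sweep(dXhat, 2L, s1 / m, "-") - sweep(Xhat, 2L, s2 / m, "*")
  dX <- sweep(dX, 2L, cache$invstd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) cpp_relu(X)

# Effective weight of a weight-normalised convolution: each output-channel
# column of V is rescaled to Euclidean norm g[j].
wn_effective <- function(V, g) {
  nrm <- sqrt(colSums(V^2))
  if (any(nrm == 0)) stop("weight normalization: zero-norm direction vector")
  sweep(V, 2L, g / nrm, "*")
}

# Chain rule through the reparameterisation w_j = g_j * V_j / ||V_j||.
wn_backward <- function(dW, V, g) {
  nrm <- sqrt(colSums(V^2))
  Vhat <- sweep(V, 2L, nrm, "/")
  dg <- colSums(dW * Vhat)
  dV <- sweep(dW, 2L, g / nrm, "*") -
    sweep(Vhat, 2L, dg * g / nrm, "*")
  list(dV = dV, dg = dg)
}
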