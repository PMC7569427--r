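#' Preprocessing configuration
#'
#' Parameters of the image preparation chain applied to every fundus image
#' before patch extraction: grayscale conversion, standardization,
#' contrast-limited adaptive histogram equalization (CLAHE) and gamma
#' correction.
#'
#' @param gamma exponent of the gamma correction (default 1.2).
#' @param clahe_clip CLAHE clip limit (default 2).
#' @param clahe_tiles CLAHE tile grid, (rows, cols) (default 8x8).
#' @param standardize_mode \code{"per_image"} (z-score each image) or
#'   \code{"per_dataset"} (z-score with externally supplied moments).
#' @return A \code{preprocess_config} list.
#' @export
preprocess_config <- function(gamma = 1.2, clahe_clip = 2,
                              clahe_tiles = c(8L, 8L),
                              standardize_mode = c("per_image", "per_dataset")) {
  if (gamma <= 0) stop("preprocess_config: gamma must be > 0")
  if (clahe_clip <= 0) stop("preprocess_config: clahe_clip must be > 0")
  if (any(clahe_tiles < 1)) stop("preprocess_config: clahe_tiles must be >= 1")
  structure(list(gamma = gamma, clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 standardize_mode = match.arg(standardize_mode)),
            class = "preprocess_config")
}

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114). Inputs on
#' a 0--255 scale are rescaled to [0, 1] first.
#'
#' @param rgb numeric array H x W x 3.
#' @return H x W matrix in [0, 1].
#' @export
rgb_to_gray <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L)
    stop("rgb_to_gray: expected an H x W x 3 array")
  if (max(rgb, na.rm = TRUE) > 1) rgb <- rgb / 255
  w <- c(0.299, 0.587, 0.114)
  ch <- function(i) { x <- rgb[, , i, drop = FALSE]; dim(x) <- d[1:2]; x }
  g <- ch(1L) * w[1] + ch(2L) * w[2] + ch(3L) * w[3]
  pmin(pmax(g, 0), 1)
}

#' Standardize an image and rescale to [0, 1]
#'
#' Z-scores the pixel values (per image by default) and then min-max
#' rescales the result back to [0, 1] so the following CLAHE and gamma
#' stages operate on a bounded range. A constant image has no scale; it is
#' returned as an all-0.5 image with a warning.
#'
#' @param img numeric matrix.
#' @param mode \code{"per_image"} or \code{"per_dataset"}.
#' @param center,scale dataset moments, required for
#'   \code{mode = "per_dataset"}.
#' @return Matrix of the same shape with values in [0, 1].
#' @export
standardize <- function(img, mode = c("per_image", "per_dataset"),
                        center = NULL, scale = NULL) {
  mode <- match.arg(mode)
  if (mode == "per_dataset") {
    if (is.null(center) || is.null(scale))
      stop("standardize: per_dataset mode needs center and scale")
    z <- (img - center) / scale
  } else {
    s <- stats::sd(as.vector(img))
    if (!is.finite(s) || s == 0) {
      warning("standardize: constant image; returning all-0.5")
      return(matrix(0.5, nrow(img), ncol(img)))
    }
    z <- (img - mean(img)) / s
  }
  rng <- range(z)
  if (rng[1] == rng[2]) {
    warning("standardize: constant image; returning all-0.5")
    return(matrix(0.5, nrow(img), ncol(img)))
  }
  (z - rng[1]) / (rng[2] - rng[1])
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast enhancement on a tile grid with a clip limit, as commonly
#' applied to fundus images before vessel segmentation. Deterministic for
#' fixed parameters.
#'
#' @param img numeric matrix in [0, 1].
#' @param clip clip limit.
#' @param tiles (rows, cols) tile grid.
#' @return Enhanced matrix in [0, 1].
#' @export
clahe <- function(img, clip = 2, tiles = c(8L, 8L)) {
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("clahe: image must be in [0, 1]")
  if (tiles[1] > nrow(img) || tiles[2] > ncol(img))
    stop("clahe: tile grid larger than the image")
  # the tile grid must divide the image; reflect-pad to the next multiple
  # and crop back, so arbitrary image sizes are supported
  H <- nrow(img); W <- ncol(img)
  Hp <- ceiling(H / tiles[1]) * tiles[1]
  Wp <- ceiling(W / tiles[2]) * tiles[2]
  if (Hp > H) img <- rbind(img, img[seq.int(H, by = -1L, length.out = Hp - H), , drop = FALSE])
  if (Wp > W) img <- cbind(img, img[, seq.int(W, by = -1L, length.out = Wp - W), drop = FALSE])
  out <- as.matrix(EBImage::clahe(img, nx = tiles[2], ny = tiles[1],
                                  limit = clip))
  pmin(pmax(out[seq_len(H), seq_len(W), drop = FALSE], 0), 1)
}

#' Gamma correction
#'
#' Raises every pixel to the power \code{gamma}; 0 and 1 are fixed points,
#' and \code{gamma = 1} is the identity. \code{gamma > 1} darkens midtones.
#'
#' @param img numeric matrix in [0, 1].
#' @param gamma positive exponent (default 1.2).
#' @export
gamma_correct <- function(img, gamma = 1.2) {
  if (gamma <= 0) stop("gamma_correct: gamma must be > 0")
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("gamma_correct: image must be in [0, 1]")
  pmin(pmax(img, 0), 1)^gamma
}

#' Full preprocessing chain
#'
#' Grayscale conversion, standardization, CLAHE and gamma correction, in
#' that order. Grayscale input (a matrix) skips the conversion step.
#'
#' @param rgb H x W x 3 array or H x W matrix.
#' @param cfg a \code{\link{preprocess_config}}.
#' @param center,scale dataset moments for per-dataset standardization.
#' @return H x W matrix in [0, 1].
#' @export
preprocess_pipeline <- function(rgb, cfg = preprocess_config(),
                                center = NULL, scale = NULL) {
  g <- if (is.matrix(rgb)) rgb else rgb_to_gray(rgb)
  g <- standardize(g, cfg$standardize_mode, center = center, scale = scale)
  g <- clahe(g, cfg$clahe_clip, cfg$clahe_tiles)
  gamma_correct(g, cfg$gamma)
}

# Sliding-window start positions (0-based) covering a dimension, with one
# extra edge-aligned window when the stride does not tile exactly.
.grid_starts <- function(dim, size, stride) {
  starts <- seq.int(0L, dim - size, by = stride)
  if ((dim - size) %% stride != 0L) starts <- c(starts, dim - size)
  as.integer(starts)
}

#' Extract patches from an image (and optional mask)
#'
#' Grid mode enumerates sliding-window positions row-major with the given
#' stride, appending edge-aligned windows so every pixel is covered; random
#' mode samples \code{n} uniformly distributed fully-inside positions with
#' a seed. Image and mask patches share coordinates.
#'
#' @param img H x W matrix.
#' @param mask optional H x W binary matrix (ground-truth labels).
#' @param size patch side in pixels (default 48).
#' @param stride grid stride in pixels (default 5).
#' @param mode \code{"grid"} or \code{"random"}.
#' @param n number of patches (random mode).
#' @param seed RNG seed (random mode).
#' @param fov optional binary field-of-view mask; in random mode, patch
#'   centres are restricted to lie inside it.
#' @return A \code{patch_grid}: \code{patches} (S x S x P array),
#'   \code{coords} (P x 2 matrix of 0-based top-left (row, col)),
#'   \code{source_shape}, \code{patch_size}, \code{stride}, and
#'   \code{mask_patches} when a mask was supplied.
#' @export
extract_patches <- function(img, mask = NULL, size = 48L, stride = 5L,
                            mode = c("grid", "random"), n = NULL, seed = NULL,
                            fov = NULL) {
  mode <- match.arg(mode)
  H <- nrow(img); W <- ncol(img)
  if (size > H || size > W)
    stop(sprintf("extract_patches: patch size %d exceeds image %dx%d",
                 size, H, W))
  if (!is.null(mask) && !all(dim(mask) == dim(img)))
    stop("extract_patches: mask shape differs from image")
  if (mode == "grid") {
    rs <- .grid_starts(H, size, stride)
    cs <- .grid_starts(W, size, stride)
    coords <- cbind(rep(rs, each = length(cs)), rep(cs, times = length(rs)))
  } else {
    if (is.null(n) || is.null(seed))
      stop("extract_patches: random mode requires n and seed")
    set.seed(seed)
    if (is.null(fov)) {
      coords <- cbind(sample.int(H - size + 1L, n, replace = TRUE) - 1L,
                      sample.int(W - size + 1L, n, replace = TRUE) - 1L)
    } else {
      cand_r <- sample.int(H - size + 1L, 4L * n, replace = TRUE) - 1L
      cand_c <- sample.int(W - size + 1L, 4L * n, replace = TRUE) - 1L
      ctr <- cbind(cand_r + size %/% 2L + 1L, cand_c + size %/% 2L + 1L)
      ok <- fov[ctr] > 0
      if (sum(ok) < n) {  # top up by rejection sampling
        while (sum(ok) < n) {
          extra_r <- sample.int(H - size + 1L, n, replace = TRUE) - 1L
          extra_c <- sample.int(W - size + 1L, n, replace = TRUE) - 1L
          keep <- fov[cbind(extra_r + size %/% 2L + 1L,
                            extra_c + size %/% 2L + 1L)] > 0
          cand_r <- c(cand_r, extra_r[keep])
          cand_c <- c(cand_c, extra_c[keep])
          ok <- c(ok, rep(TRUE, sum(keep)))
        }
      }
      sel <- which(ok)[seq_len(n)]
      coords <- cbind(cand_r[sel], cand_c[sel])
    }
  }
  P <- nrow(coords)
  patches <- array(0, c(size, size, P))
  mpatches <- if (!is.null(mask)) array(0L, c(size, size, P)) else NULL
  for (k in seq_len(P)) {
    ri <- coords[k, 1L] + seq_len(size)
    ci <- coords[k, 2L] + seq_len(size)
    patches[, , k] <- img[ri, ci]
    if (!is.null(mask)) mpatches[, , k] <- mask[ri, ci]
  }
  structure(list(patches = patches, coords = coords,
                 source_shape = c(H, W), patch_size = as.integer(size),
                 stride = as.integer(stride), mode = mode,
                 mask_patches = mpatches),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("patch_grid: %d patches of %dx%d from a %dx%d image (%s mode)\n",
              dim(x$patches)[3], x$patch_size, x$patch_size,
              x$source_shape[1], x$source_shape[2], x$mode))
  invisible(x)
}

#' Reassemble a full-image map from patch predictions
#'
#' Averages all patch values covering each pixel. Every pixel of the source
#' shape must be covered by at least one patch.
#'
#' @param pg a \code{patch_grid} whose \code{patches} hold per-pixel values
#'   (e.g. vessel probabilities).
#' @param patches optional S x S x P array overriding \code{pg$patches}
#'   (e.g. model outputs for the same coordinates).
#' @return H x W matrix of per-pixel averages.
#' @export
reconstruct_map <- function(pg, patches = NULL) {
  stopifnot(inherits(pg, "patch_grid"))
  if (is.null(patches)) patches <- pg$patches
  H <- pg$source_shape[1]; W <- pg$source_shape[2]
  S <- pg$patch_size
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (k in seq_len(dim(patches)[3])) {
    ri <- pg$coords[k, 1L] + seq_len(S)
    ci <- pg$coords[k, 2L] + seq_len(S)
    acc[ri, ci] <- acc[ri, ci] + patches[, , k]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0)) {
    miss <- which(cnt == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("reconstruct_map: pixel (%d, %d) not covered by any patch",
                 miss[1], miss[2]))
  }
  acc / cnt
}
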