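#' Synthetic fundus configuration
#'
#' Parameters of the synthetic retina generator: recursive bifurcating
#' vessel trees of tapering calibre drawn dark on a bright, vignetted
#' circular field of view, softened by Gaussian blur and corrupted by
#' additive noise. The defaults aim at the qualitative structure of fundus
#' photographs — a vessel pixel fraction of a few percent to ~15%, low
#' vessel/background contrast, and mixed vessel calibres.
#'
#' @param image_shape (H, W) in pixels.
#' @param n_trees number of vessel trees rooted near the disc edge.
#' @param branch_depth bifurcation depth (0 = a single segment per tree).
#' @param root_width stroke width of a root segment, pixels.
#' @param terminal_width stroke width at maximal depth, pixels.
#' @param branch_angle_spread opening angle between sibling branches,
#'   degrees.
#' @param vessel_darkness vessel contrast as a fraction of the local
#'   background intensity, in (0, 1).
#' @param background_base background gray level inside the field of view.
#' @param vignette_strength radial intensity falloff towards the rim.
#' @param blur_sigma Gaussian blur of the rendered image, pixels.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed RNG seed.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(image_shape = c(128L, 128L), n_trees = 4L,
                         branch_depth = 4L, root_width = 4,
                         terminal_width = 1, branch_angle_spread = 40,
                         vessel_darkness = 0.35, background_base = 0.65,
                         vignette_strength = 0.35, blur_sigma = 0.7,
                         noise_sd = 0.03, seed = 1L) {
  if (terminal_width > root_width)
    stop("synth_config: terminal_width must not exceed root_width")
  if (terminal_width < 0.5) stop("synth_config: widths must be >= 0.5 pixel")
  if (vessel_darkness <= 0 || vessel_darkness >= 1)
    stop("synth_config: vessel_darkness must be in (0, 1)")
  structure(list(image_shape = as.integer(image_shape), n_trees = n_trees,
                 branch_depth = branch_depth, root_width = root_width,
                 terminal_width = terminal_width,
                 branch_angle_spread = branch_angle_spread,
                 vessel_darkness = vessel_darkness,
                 background_base = background_base,
                 vignette_strength = vignette_strength,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Rasterize a thick line segment into a logical mask (TRUE on the stroke).
.draw_segment <- function(mask, p0, p1, width) {
  H <- nrow(mask); W <- ncol(mask)
  hw <- width / 2
  r0 <- max(1L, floor(min(p0[1], p1[1]) - hw)); r1 <- min(H, ceiling(max(p0[1], p1[1]) + hw))
  c0 <- max(1L, floor(min(p0[2], p1[2]) - hw)); c1 <- min(W, ceiling(max(p0[2], p1[2]) + hw))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  gr <- matrix(rr, length(rr), length(cc))
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 == 0) {
    d2 <- (gr - p0[1])^2 + (gc - p0[2])^2
  } else {
    t <- ((gr - p0[1]) * v[1] + (gc - p0[2]) * v[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (gr - (p0[1] + t * v[1]))^2 + (gc - (p0[2] + t * v[2]))^2
  }
  mask[rr, cc] <- mask[rr, cc] | (d2 <= hw^2)
  mask
}

# Recursive bifurcation: each branch is a straight segment; children leave
# at +/- half the opening angle with per-branch jitter, lengths shrink and
# widths taper linearly with depth.
.grow_tree <- function(mask, pos, angle, depth, cfg, seg_len) {
  max_d <- cfg$branch_depth
  frac <- if (max_d == 0) 1 else (max_d - depth) / max_d
  width <- cfg$terminal_width + frac * (cfg$root_width - cfg$terminal_width)
  len <- seg_len * stats::runif(1, 0.8, 1.2)
  end <- pos + len * c(sin(angle), cos(angle))
  mask <- .draw_segment(mask, pos, end, width)
  if (depth < max_d) {
    half <- cfg$branch_angle_spread / 2 * pi / 180
    for (s in c(-1, 1)) {
      child <- angle + s * half + stats::rnorm(1, sd = 0.15)
      mask <- .grow_tree(mask, end, child, depth + 1L, cfg, seg_len * 0.75)
    }
  }
  mask
}

#' Generate a binary vessel mask
#'
#' Rasterizes \code{n_trees} recursive bifurcating trees, rooted on a ring
#' near the rim of the field of view and growing inwards. Deterministic for
#' a fixed seed.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return H x W binary (0/1) matrix.
#' @export
generate_vessel_mask <- function(cfg = synth_config()) {
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  if (H < 16 || W < 16) stop("generate_vessel_mask: image too small")
  set.seed(cfg$seed)
  mask <- matrix(FALSE, H, W)
  centre <- c(H, W) / 2
  radius <- 0.48 * min(H, W)
  n <- cfg$n_trees
  if (n > 0) {
    for (k in seq_len(n)) {
      theta <- 2 * pi * (k - 1) / n + stats::runif(1, -0.3, 0.3)
      pos <- centre + 0.85 * radius * c(sin(theta), cos(theta))
      # grow towards the disc centre; angles are (sin, cos) on (row, col)
      angle <- atan2(centre[1] - pos[1], centre[2] - pos[2])
      seg_len <- 0.45 * radius
      mask <- .grow_tree(mask, pos, angle, 0L, cfg, seg_len)
    }
  }
  mode(mask) <- "integer"
  mask
}

#' Render a fundus-like image from a vessel mask
#'
#' Background at \code{background_base} with a radial vignette inside a
#' circular field of view, vessels darkened by \code{vessel_darkness},
#' Gaussian blur for soft vessel edges, then additive Gaussian noise
#' (seeded) and clipping to [0, 1].
#'
#' @param mask H x W binary vessel mask.
#' @param cfg a \code{\link{synth_config}} with matching
#'   \code{image_shape}.
#' @param rgb also return a 3-channel copy (gray replicated) under
#'   \code{$rgb}.
#' @return List with \code{image} (H x W in [0, 1]), \code{mask},
#'   \code{fov} (binary disc) and optionally \code{rgb}.
#' @export
render_fundus <- function(mask, cfg = synth_config(), rgb = FALSE) {
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  if (!all(dim(mask) == c(H, W)))
    stop("render_fundus: mask shape differs from cfg$image_shape")
  centre <- c(H, W) / 2
  radius <- 0.48 * min(H, W)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dist <- sqrt((rr - centre[1])^2 + (cc - centre[2])^2)
  fov <- (dist <= radius) * 1L
  vign <- 1 - cfg$vignette_strength * (dist / radius)^2
  img <- cfg$background_base * vign
  img[mask > 0] <- img[mask > 0] * (1 - cfg$vessel_darkness)
  img[fov == 0] <- 0.02
  if (cfg$blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = cfg$blur_sigma))
  set.seed(cfg$seed + 1L)
  if (cfg$noise_sd > 0)
    img <- img + stats::rnorm(length(img), sd = cfg$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  out <- list(image = img, mask = mask, fov = fov)
  if (rgb) out$rgb <- array(rep(img, 3L), c(H, W, 3L))
  out
}

#' Generate a seeded synthetic fundus dataset
#'
#' Draws \code{n_images} independent images; each image's seed is derived
#' reproducibly from the master seed.
#'
#' @param n_images number of images (>= 1).
#' @param cfg base \code{\link{synth_config}}.
#' @param seed master seed (defaults to \code{cfg$seed}).
#' @return List of \code{n_images} lists with \code{image}, \code{mask},
#'   \code{fov}.
#' @export
generate_fundus_dataset <- function(n_images, cfg = synth_config(),
                                    seed = cfg$seed) {
  if (n_images < 1) stop("generate_fundus_dataset: n_images must be >= 1")
  lapply(seq_len(n_images), function(i) {
    ci <- cfg
    ci$seed <- as.integer((seed %% 1000000L) * 1000L + i)
    m <- generate_vessel_mask(ci)
    render_fundus(m, ci)
  })
}
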