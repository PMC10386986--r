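#' Otsu tissue mask
#'
#' Separates H&E-stained tissue from background by Otsu's method: the
#' threshold maximizing between-class variance over a 256-bin histogram of
#' the grayscale image. Tissue is the darker side (H&E tissue absorbs;
#' glass background is bright).
#'
#' @param image Numeric matrix (grayscale, range 0-255 or 0-1) or an
#'   H x W x 3 RGB array, converted to gray by the standard luma weights
#'   (0.299, 0.587, 0.114).
#' @return A `tissue_mask`: binary matrix (1 = tissue) with attributes
#'   `threshold` (on the 0-255 scale) and the source dimensions.
#' @export
otsu_mask <- function(image) {
  g <- to_gray255(image)
  if (max(g) - min(g) < .Machine$double.eps) {
    stop("constant image: no Otsu threshold exists")
  }
  thr <- otsu_threshold(g)
  mask <- (g <= thr) * 1L
  structure(mask, class = "tissue_mask", threshold = thr)
}

to_gray255 <- function(image) {
  if (length(dim(image)) == 3) {
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  g <- as.matrix(image)
  if (max(g) <= 1) g <- g * 255
  g
}

# Between-class-variance maximization on the 256-bin histogram; returns the
# threshold t such that pixels <= t and > t form the two classes. Among
# maximizing thresholds the lowest is returned.
otsu_threshold <- function(g) {
  counts <- tabulate(pmin(pmax(floor(g), 0), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)                 # P(class0) for threshold t = level
  mu <- cumsum(p * levels)           # partial mean
  mu_total <- mu[256]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_total * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  levels[which.max(sigma_b)]
}

#' Extract tissue patches from an image
#'
#' Scans the image row-major with a square window of side `patch_size` and
#' step `stride` (half-open windows, 0-based origins that are multiples of
#' `stride`), keeping a patch iff the mean of the tissue mask inside the
#' window is at least `min_tissue_frac`.
#'
#' @param image H x W x 3 array (0-255) or grayscale matrix.
#' @param mask A [otsu_mask()] result or any binary matrix of matching size.
#' @param patch_size Window side, px; must not exceed either image dim.
#' @param stride Step between window origins, px.
#' @param min_tissue_frac Minimum tissue fraction in `(0, 1]` to keep a
#'   patch (default 0.5).
#' @return List of tiles, each a list with `pixels` and 0-based `origin`
#'   `(row, col)`; empty when no window qualifies.
#' @export
extract_patches <- function(image, mask, patch_size, stride = patch_size,
                            min_tissue_frac = 0.5) {
  dims <- dim(image)
  H <- dims[1]; W <- dims[2]
  stopifnot(patch_size <= H, patch_size <= W,
            min_tissue_frac > 0, min_tissue_frac <= 1, stride >= 1)
  stopifnot(nrow(mask) == H, ncol(mask) == W)
  r0 <- seq(0L, H - patch_size, by = stride)
  c0 <- seq(0L, W - patch_size, by = stride)
  out <- list()
  for (r in r0) for (cc in c0) {
    win <- mask[(r + 1):(r + patch_size), (cc + 1):(cc + patch_size)]
    if (mean(win) >= min_tissue_frac) {
      px <- if (length(dims) == 3) {
        image[(r + 1):(r + patch_size), (cc + 1):(cc + patch_size), ,
              drop = FALSE]
      } else {
        image[(r + 1):(r + patch_size), (cc + 1):(cc + patch_size)]
      }
      out[[length(out) + 1L]] <- list(pixels = px,
                                      origin = as.integer(c(r, cc)))
    }
  }
  out
}

#' Augmentation settings
#'
#' Training-time augmentation: random horizontal/vertical flips, right-angle
#' rotations, translations with reflection padding, and contrast scaling
#' around the tile mean. Degenerate ranges make [augment()] the identity.
#'
#' @param flips Allow random flips.
#' @param rotations Allowed rotation angles (degrees, multiples of 90).
#' @param max_translate_px Maximum |shift| per axis in pixels.
#' @param contrast_range Length-2 range for the contrast factor.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(flips = TRUE, rotations = c(0, 90, 180, 270),
                         max_translate_px = 8, contrast_range = c(0.8, 1.2)) {
  stopifnot(all(rotations %% 90 == 0), max_translate_px >= 0,
            length(contrast_range) == 2)
  structure(list(flips = flips, rotations = rotations,
                 max_translate_px = max_translate_px,
                 contrast_range = contrast_range), class = "augment_spec")
}

#' Augment a tile
#'
#' Applies (deterministically, given `seed`) a random flip, right-angle
#' rotation, translation with reflection padding and contrast scaling.
#' Pixel values stay in 0-255; shape and any class label are unchanged.
#'
#' @param tile `tissue_tile`, plain H x W x 3 array, or the list form
#'   produced by [extract_patches()].
#' @param ops_spec An [augment_spec()].
#' @param seed Integer seed.
#' @return Augmented tile of the same type/shape.
#' @export
augment <- function(tile, ops_spec = augment_spec(), seed = 1L) {
  px <- if (is.list(tile)) tile$pixels else tile
  withr_seed(seed, {
    if (ops_spec$flips && stats::runif(1) < 0.5) px <- flip_tile(px, "h")
    if (ops_spec$flips && stats::runif(1) < 0.5) px <- flip_tile(px, "v")
    k <- sample(ops_spec$rotations, 1) / 90
    px <- rotate90(px, k)
    mt <- ops_spec$max_translate_px
    sh <- if (mt > 0) sample(seq(-mt, mt), 2, replace = TRUE) else c(0L, 0L)
    px <- translate_reflect(px, sh[1], sh[2])
    cr <- ops_spec$contrast_range
    fac <- stats::runif(1, cr[1], cr[2])
    px <- contrast_scale(px, fac)
  })
  out <- px
  attrs <- attributes(if (is.list(tile)) tile$pixels else tile)
  attrs$dim <- dim(out)
  attributes(out) <- attrs
  if (is.list(tile)) { tile$pixels <- out; tile } else out
}

#' @rdname augment
#' @param px Pixel array.
#' @param axis `"h"` (mirror columns) or `"v"` (mirror rows).
#' @export
flip_tile <- function(px, axis = c("h", "v")) {
  axis <- match.arg(axis)
  d3 <- length(dim(px)) == 3
  if (axis == "h") {
    if (d3) px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    else px[, rev(seq_len(ncol(px))), drop = FALSE]
  } else {
    if (d3) px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    else px[rev(seq_len(nrow(px))), , drop = FALSE]
  }
}

#' @rdname augment
#' @param k Number of counter-clockwise 90-degree turns.
#' @export
rotate90 <- function(px, k = 1) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(px)
  d3 <- length(dim(px)) == 3
  rot1 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  for (i in seq_len(k)) {
    if (d3) {
      px <- {
        ch <- lapply(seq_len(dim(px)[3]), function(c) rot1(px[, , c]))
        array(unlist(ch), dim = c(dim(ch[[1]]), length(ch)))
      }
    } else px <- rot1(px)
  }
  px
}

# Shift by (dr, dc) filling exposed pixels by reflection.
translate_reflect <- function(px, dr, dc) {
  d <- dim(px)
  H <- d[1]; W <- d[2]
  reflect_idx <- function(i, n) {
    # reflect without repeating the border pixel (period 2n-2)
    i <- abs(i - 1) %% (2 * n - 2)
    ifelse(i >= n, 2 * n - 2 - i, i) + 1
  }
  ri <- reflect_idx(seq_len(H) - dr, H)
  ci <- reflect_idx(seq_len(W) - dc, W)
  if (length(d) == 3) px[ri, ci, , drop = FALSE] else px[ri, ci, drop = FALSE]
}

# Contrast scaling about the tile mean, rounded and clipped to 0-255.
contrast_scale <- function(px, factor) {
  m <- mean(px)
  out <- round((as.numeric(px) - m) * factor + m)
  out <- pmin(pmax(out, 0), 255)
  array(as.integer(out), dim = dim(px))
}
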