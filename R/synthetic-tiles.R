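#' Six histological tissue categories
#'
#' Class codes for the six tissue categories recognised on H&E slides of
#' hepatocellular carcinoma: tumor region (TR), normal liver tissue (NLT),
#' portal area (PA), fibrous tissue (FT), hemorrhagic/necrotic tissue (HNT)
#' and immune cells (IC).
#'
#' @format Character vector of length six.
#' @export
TISSUE_CLASSES <- c("TR", "NLT", "PA", "FT", "HNT", "IC")

# Class-specific texture palettes. Base RGB tones are spread in hue so that
# classes are visually (and statistically) separable; blob_scale is the
# correlation length of the low-frequency structure in pixels, amp its
# per-channel amplitude, noise_sd the white-noise level.
tile_palette <- function(cls) {
  pal <- list(
    TR  = list(base = c(140,  70, 170), accent = c( 90,  40, 120),
               blob_scale = 12, amp = 55, noise_sd = 14),
    NLT = list(base = c(245, 190, 205), accent = c(220, 150, 170),
               blob_scale = 32, amp = 25, noise_sd = 10),
    PA  = list(base = c( 95, 130, 210), accent = c( 60,  90, 170),
               blob_scale = 20, amp = 45, noise_sd = 12),
    FT  = list(base = c(235, 200, 150), accent = c(205, 160, 110),
               blob_scale = 48, amp = 30, noise_sd = 8),
    HNT = list(base = c(180,  75,  60), accent = c(120,  40,  30),
               blob_scale = 24, amp = 60, noise_sd = 18),
    IC  = list(base = c( 45, 105, 130), accent = c( 25,  70,  95),
               blob_scale = 6,  amp = 50, noise_sd = 16)
  )
  if (!cls %in% names(pal)) {
    stop("unknown tissue class code: '", cls, "' (expected one of ",
         paste(TISSUE_CLASSES, collapse = ", "), ")")
  }
  pal[[cls]]
}

# Smooth random field in [0,1]^2 via bilinear upscaling of a coarse normal
# grid; correlation length ~ `scale` pixels. Uses the current RNG stream.
smooth_field <- function(size, scale) {
  n_coarse <- max(2L, as.integer(ceiling(size / scale)) + 1L)
  g <- matrix(stats::rnorm(n_coarse^2), n_coarse, n_coarse)
  # positions of fine pixels on the coarse grid
  u <- (seq_len(size) - 1) / (size - 1) * (n_coarse - 1) + 1
  i0 <- pmin(floor(u), n_coarse - 1)
  fr <- u - i0
  # separable bilinear interpolation
  gi <- g[i0, , drop = FALSE] * (1 - fr) + g[i0 + 1, , drop = FALSE] * fr
  f <- gi[, i0, drop = FALSE] * rep(1 - fr, each = size) +
       gi[, i0 + 1, drop = FALSE] * rep(fr, each = size)
  (f - mean(f)) / (stats::sd(f) + 1e-12)
}

#' Generate a synthetic tissue tile
#'
#' Produces a procedural RGB texture for one of the six tissue categories.
#' Each class has a fixed base tone, blob correlation length and noise level,
#' so tiles of different classes are separable by color and texture while
#' tiles of one class vary realistically. The texture is a deterministic
#' function of `(cls, size_px, seed, contrast)`.
#'
#' @param cls Tissue class code, one of [TISSUE_CLASSES].
#' @param size_px Tile side length in pixels (>= 32).
#' @param seed Integer seed; identical inputs give bit-identical tiles.
#' @param contrast Multiplier applied to the texture component around the
#'   class base tone (used by [generate_cohort()] to encode patient-level
#'   latent risk in tile appearance); 1 is the neutral texture.
#' @return A `tissue_tile`: integer array `size_px x size_px x 3` in 0-255
#'   with attributes `class` and `seed`.
#' @export
generate_tissue_tile <- function(cls, size_px, seed, contrast = 1) {
  p <- tile_palette(cls)
  if (!is.numeric(size_px) || length(size_px) != 1 || size_px < 32) {
    stop("size_px must be a single number >= 32, got ", size_px)
  }
  size_px <- as.integer(size_px)
  withr_seed(seed, {
    f <- smooth_field(size_px, p$blob_scale)
    noise <- matrix(stats::rnorm(size_px^2, sd = p$noise_sd), size_px)
    px <- array(0, dim = c(size_px, size_px, 3))
    for (ch in 1:3) {
      tex <- f * (p$accent[ch] - p$base[ch]) * (p$amp / 60) + noise
      px[, , ch] <- p$base[ch] + contrast * tex
    }
    px <- round(pmin(pmax(px, 0), 255))
    storage.mode(px) <- "integer"
    structure(px, class = "tissue_tile",
              tissue_class = cls, seed = as.integer(seed))
  })
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Mean hue of a tile
#'
#' Circular-naive hue (in turns, 0-1) of the mean RGB color, used to check
#' palette separability of the synthetic classes.
#' @param tile A `tissue_tile` or numeric H x W x 3 array.
#' @return Hue in `[0, 1)`.
#' @export
tile_mean_hue <- function(tile) {
  m <- apply(tile, 3, mean)
  grDevices::rgb2hsv(m[1], m[2], m[3], maxColorValue = 255)["h", 1]
}

#' Write a tile to a PNG file
#' @param tile A `tissue_tile`.
#' @param path Output path.
#' @export
write_tile_png <- function(tile, path) {
  arr <- aperm(array(as.numeric(tile) / 255, dim = dim(tile)), c(1, 2, 3))
  png::writePNG(arr, target = path)
  invisible(path)
}
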