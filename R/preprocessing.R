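# Tissue localization and patch extraction.  Tissue is separated from the
# near-grey slide background by the colorization value of each pixel,
# c(r,g,b) = |r-m| + |g-m| + |b-m| with m = (r+g+b)/3, which is zero exactly
# on grey pixels and large on stained (chromatic) tissue.

#' Colorization value of every pixel
#'
#' `c(r,g,b) = |r - m| + |g - m| + |b - m|` with `m = (r + g + b) / 3`.
#' Zero if and only if `r = g = b`; invariant under channel permutation and
#' under adding a common constant to all three channels.  Works on any common
#' numeric scale (0-1 or 0-255).
#'
#' @param image `H x W x 3` numeric array.
#' @return `H x W` numeric matrix of colorization values.
#' @examples
#' colorization_value(array(c(255, 0, 0), c(1, 1, 3)))  # 340
#' @export
colorization_value <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must be a H x W x 3 array", call. = FALSE)
  }
  r <- matrix(image[, , 1], dim(image)[1], dim(image)[2])
  g <- matrix(image[, , 2], dim(image)[1], dim(image)[2])
  b <- matrix(image[, , 3], dim(image)[1], dim(image)[2])
  m <- (r + g + b) / 3
  abs(r - m) + abs(g - m) + abs(b - m)
}

#' Tissue-mask parameters
#'
#' @param threshold_mode `"adaptive"` (local-mean threshold) or `"fixed"`.
#' @param window Odd window size (pixels) for the local mean in adaptive mode.
#' @param offset Threshold offset: a pixel is tissue when its colorization
#'   value exceeds `local mean + offset` (adaptive) or `offset` (fixed).
#' @param min_tissue_fraction Default acceptance fraction for
#'   [extract_patches()].
#' @return A `colorization_params` object.
#' @export
colorization_params <- function(threshold_mode = c("adaptive", "fixed"),
                                window = 31, offset = 0.02,
                                min_tissue_fraction = 0.1) {
  threshold_mode <- match.arg(threshold_mode)
  window <- as.integer(window)
  if (threshold_mode == "adaptive" && (window < 3L || window %% 2L == 0L)) {
    stop("`window` must be odd and >= 3", call. = FALSE)
  }
  if (min_tissue_fraction < 0 || min_tissue_fraction > 1) {
    stop("`min_tissue_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(threshold_mode = threshold_mode, window = window,
                 offset = offset, min_tissue_fraction = min_tissue_fraction),
            class = "colorization_params")
}

# Local mean over a w x w window with replicate padding, via an integral
# image; deterministic and edge-exact, which the adaptive threshold needs.
local_mean <- function(x, window) {
  r <- (window - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  pad <- x[pmin(pmax((1 - r):(n + r), 1), n), pmin(pmax((1 - r):(m + r), 1), m),
           drop = FALSE]
  S <- apply(apply(pad, 2, cumsum), 1, cumsum)        # transposed integral image
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  win_sum <- S[(2 * r + 1) + 1:n, (2 * r + 1) + 1:m] -
    S[(2 * r + 1) + 1:n, 1:m] - S[1:n, (2 * r + 1) + 1:m] + S[1:n, 1:m]
  win_sum / window^2
}

#' Binary tissue mask
#'
#' Marks a pixel as tissue when its colorization value exceeds the threshold:
#' a local-mean threshold (`adaptive`, window + offset) or a global constant
#' (`fixed`, offset).  Fixed mode is exactly reproducible on flat synthetic
#' textures; adaptive mode follows stain intensity drift on realistic input.
#'
#' @param image `H x W x 3` numeric array.
#' @param params A [colorization_params()].
#' @return Logical `H x W` matrix (`TRUE` = tissue).
#' @export
tissue_mask <- function(image, params = colorization_params()) {
  cv <- colorization_value(image)
  if (params$threshold_mode == "fixed") {
    return(cv > params$offset)
  }
  if (params$window > nrow(cv) || params$window > ncol(cv)) {
    stop("adaptive window (", params$window, ") larger than image", call. = FALSE)
  }
  cv > local_mean(cv, params$window) + params$offset
}

#' Extract fixed-size patches from a tissue-masked image
#'
#' Non-overlapping row-major tiling; edge remainders that do not fill a full
#' tile are dropped.  A tile is emitted iff its tissue-pixel fraction is at
#' least `min_tissue_fraction`.
#'
#' @param image `H x W x 3` numeric array.
#' @param mask Logical `H x W` tissue mask (e.g. from [tissue_mask()]).
#' @param patch_size Tile side length in pixels (default 256, the working
#'   patch size for whole-slide inputs; tests use smaller tiles).
#' @param min_tissue_fraction Minimum tissue fraction for a tile to be kept.
#' @return A list with `patches` (list of `patch_size x patch_size x 3`
#'   arrays) and `manifest` (data.frame: `patch_id`, `row`, `col`,
#'   `tissue_fraction`; `row`/`col` are 0-based grid coordinates).
#' @export
extract_patches <- function(image, mask, patch_size = 256,
                            min_tissue_fraction = 0.1) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < patch_size || w < patch_size) {
    stop("image smaller than one patch", call. = FALSE)
  }
  stopifnot(all(dim(mask) == c(h, w)))
  nr <- h %/% patch_size; nc <- w %/% patch_size
  patches <- list(); rows <- integer(0); cols <- integer(0); fracs <- numeric(0)
  for (r in 0:(nr - 1)) {
    for (c in 0:(nc - 1)) {
      ri <- (r * patch_size + 1):((r + 1) * patch_size)
      ci <- (c * patch_size + 1):((c + 1) * patch_size)
      frac <- mean(mask[ri, ci])
      if (frac >= min_tissue_fraction) {
        patches[[length(patches) + 1L]] <- image[ri, ci, , drop = FALSE]
        rows <- c(rows, r); cols <- c(cols, c); fracs <- c(fracs, frac)
      }
    }
  }
  list(patches = patches,
       manifest = data.frame(patch_id = seq_along(patches) - 1L,
                             row = rows, col = cols, tissue_fraction = fracs))
}

#' Read an RGB image from a PNG file
#' @param path File path.
#' @return `H x W x 3` array in `[0, 1]` (alpha dropped, grey replicated).
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px
}

#' Write an RGB image to a PNG file
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}
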