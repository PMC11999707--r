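#' Patched image
#'
#' An RGB image partitioned into a regular grid of square patches.  The patch
#' is the unit of masking and attribution throughout the package: patch index
#' `i` (1-based in R) maps row-major onto grid cell
#' `(ceiling(i / cols), ((i - 1) %% cols) + 1)`.
#'
#' @param pixels Numeric array `height x width x 3` with values in `[0, 1]`.
#' @param patch_size Side length of a patch in pixels; must divide both image
#'   dimensions exactly.
#' @return An object of class `patched_image` with fields `pixels`,
#'   `patch_size`, `grid` (`c(rows, cols)`) and `d` (number of patches).
#' @examples
#' img <- patched_image(array(0.5, c(8, 8, 3)), patch_size = 4)
#' img$d  # 4 patches in a 2 x 2 grid
#' @export
patched_image <- function(pixels, patch_size) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  }
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L) stop("`patch_size` must be positive", call. = FALSE)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h %% patch_size != 0L || w %% patch_size != 0L) {
    stop("image dimensions (", h, " x ", w, ") are not multiples of patch_size ",
         patch_size, call. = FALSE)
  }
  rows <- h %/% patch_size
  cols <- w %/% patch_size
  structure(
    list(pixels = pixels, patch_size = patch_size,
         grid = c(rows = rows, cols = cols), d = rows * cols),
    class = "patched_image"
  )
}

#' @export
print.patched_image <- function(x, ...) {
  cat(sprintf("<patched_image> %d x %d px, %d x %d grid of %d px patches (d = %d)\n",
              dim(x$pixels)[1], dim(x$pixels)[2],
              x$grid[["rows"]], x$grid[["cols"]], x$patch_size, x$d))
  invisible(x)
}

# Row/column pixel ranges of patch i (1-based row-major patch index).
patch_extent <- function(image, i) {
  cols <- image$grid[["cols"]]
  r <- (i - 1L) %/% cols
  c <- (i - 1L) %% cols
  ps <- image$patch_size
  list(rows = (r * ps + 1L):((r + 1L) * ps),
       cols = (c * ps + 1L):((c + 1L) * ps))
}

#' Extract the pixels of one patch
#'
#' @param image A [patched_image()].
#' @param i Patch index in `1..d`, row-major.
#' @return A `patch_size x patch_size x 3` array.
#' @export
patch_pixels <- function(image, i) {
  ext <- patch_extent(image, i)
  image$pixels[ext$rows, ext$cols, , drop = FALSE]
}

#' Mean intensity of every patch
#'
#' The mean over all pixels and all three channels of each patch, the feature
#' the linear patch scorer operates on.
#'
#' @param image A [patched_image()].
#' @return Numeric vector of length `d`.
#' @export
patch_mean_intensity <- function(image) {
  vapply(seq_len(image$d), function(i) mean(patch_pixels(image, i)), numeric(1))
}

#' Mask patches of an image
#'
#' Replaces every pixel of each patch `i` with `mask[i] == 0` by `fill`.
#' An all-ones mask returns the input pixels unchanged (bit-identical).
#'
#' @param image A [patched_image()].
#' @param mask Binary (0/1) vector of length `d`.
#' @param fill Fill value in `[0, 1]` for masked patches (0 = black).
#' @return A [patched_image()] with masked pixels.
#' @export
apply_mask <- function(image, mask, fill = 0) {
  mask <- check_mask(mask, image$d)
  if (all(mask == 1)) return(image)
  px <- image$pixels
  for (i in which(mask == 0)) {
    ext <- patch_extent(image, i)
    px[ext$rows, ext$cols, ] <- fill
  }
  patched_image(px, image$patch_size)
}

check_mask <- function(mask, d) {
  if (length(mask) != d) {
    stop("mask length ", length(mask), " does not match number of patches ", d,
         call. = FALSE)
  }
  mask <- as.numeric(mask)
  if (!all(mask %in% c(0, 1))) stop("mask entries must be 0 or 1", call. = FALSE)
  mask
}

# All 2^d binary masks as a (2^d) x d matrix, row-major over integers 0..2^d-1
# (bit j -> column j).  Guarded: enumeration is the desk-scale oracle path.
enumerate_masks <- function(d, guard = 14L) {
  if (d > guard) {
    stop("exhaustive enumeration requested for d = ", d,
         " but the guard is d <= ", guard, call. = FALSE)
  }
  n <- 2L^d
  m <- matrix(0L, nrow = n, ncol = d)
  for (j in seq_len(d)) {
    m[, j] <- bitwAnd(0:(n - 1L), bitwShiftL(1L, j - 1L)) > 0L
  }
  storage.mode(m) <- "numeric"
  m
}
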