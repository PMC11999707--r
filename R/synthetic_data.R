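# Seed-reproducible pseudo-histology: colored "tissue" textures with planted
# high-signal "tumor" patches on a near-grey background, plus toy classifiers
# with closed-form attributions.  Default palette mimics an H&E appearance:
# tumor regions purple-dominant, normal tissue pink-dominant, background a
# near-grey glass tone whose colorization value is (near) zero.

#' Specification of a synthetic pseudo-slide
#'
#' @param grid `c(rows, cols)` of the patch grid.
#' @param patch_size Patch side length in pixels.
#' @param tumor_patches Integer patch indices (1-based, row-major) drawn with
#'   the tumor texture.
#' @param background_patches Patch indices drawn near-grey; every other patch
#'   gets the normal-tissue texture.  The three sets must be disjoint.
#' @param colors Named list of RGB means in `[0,1]` for `tumor`, `normal`,
#'   `background`.
#' @param noise_sd Per-pixel Gaussian noise scale (clamped to `[0,1]` after
#'   adding).  Zero gives flat, exactly reproducible textures.
#' @param seed Integer seed.
#' @return A `synthetic_slide_spec` object.
#' @export
synthetic_slide_spec <- function(grid = c(3, 3), patch_size = 8,
                                 tumor_patches = integer(0),
                                 background_patches = integer(0),
                                 colors = list(tumor = c(0.55, 0.25, 0.60),
                                               normal = c(0.95, 0.70, 0.80),
                                               background = c(0.92, 0.92, 0.92)),
                                 noise_sd = 0.02, seed = 1) {
  d <- grid[1] * grid[2]
  tumor_patches <- as.integer(tumor_patches)
  background_patches <- as.integer(background_patches)
  idx <- c(tumor_patches, background_patches)
  if (anyDuplicated(idx) > 0) {
    stop("tumor and background patch index sets must be disjoint", call. = FALSE)
  }
  if (length(idx) && (min(idx) < 1 || max(idx) > d)) {
    stop("patch indices must lie in 1..d", call. = FALSE)
  }
  stopifnot(all(vapply(colors, function(x) all(x >= 0 & x <= 1), logical(1))))
  structure(list(grid = grid, patch_size = as.integer(patch_size),
                 tumor_patches = tumor_patches,
                 background_patches = background_patches,
                 colors = colors, noise_sd = noise_sd, seed = as.integer(seed),
                 d = d),
            class = "synthetic_slide_spec")
}

#' Generate a pseudo-histology slide with known ground truth
#'
#' Draws each patch as its class color plus i.i.d. Gaussian pixel noise
#' (clamped to `[0,1]`).  The same spec (including seed) reproduces the image
#' bit for bit.
#'
#' @param spec A [synthetic_slide_spec()].
#' @return A list with `image` (a [patched_image()]) and `ground_truth`
#'   (factor of length `d` over levels tumor/normal/background).
#' @examples
#' sp <- synthetic_slide_spec(grid = c(2, 2), patch_size = 4,
#'                            tumor_patches = 1, noise_sd = 0)
#' gen <- generate_pseudo_slide(sp)
#' table(gen$ground_truth)
#' @export
generate_pseudo_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  labels <- rep("normal", spec$d)
  labels[spec$tumor_patches] <- "tumor"
  labels[spec$background_patches] <- "background"
  ps <- spec$patch_size
  h <- spec$grid[1] * ps; w <- spec$grid[2] * ps
  px <- array(0, c(h, w, 3))
  with_seed(spec$seed, {
    for (i in seq_len(spec$d)) {
      base <- spec$colors[[labels[i]]]
      tile <- array(rep(base, each = ps * ps), c(ps, ps, 3))
      if (spec$noise_sd > 0) {
        tile <- tile + array(stats::rnorm(ps * ps * 3, sd = spec$noise_sd),
                             c(ps, ps, 3))
        tile <- pmin(pmax(tile, 0), 1)
      }
      r <- (i - 1L) %/% spec$grid[2]; c <- (i - 1L) %% spec$grid[2]
      px[(r * ps + 1):((r + 1) * ps), (c * ps + 1):((c + 1) * ps), ] <- tile
    }
  })
  list(image = patched_image(px, ps),
       ground_truth = factor(labels, levels = c("tumor", "normal", "background")))
}

#' Linear patch scorer
#'
#' An analytic toy classifier: the class-2 score is
#' `s(x) = sum_i weights[i] * mean-intensity(patch i)`, turned into a
#' two-class probability vector through the chosen link (`identity`:
#' `(1 - s, s)`; `sigmoid`: `(1 - sigma(s), sigma(s))`).  Because the induced
#' removal game is additive under the identity link, its exact Shapley values
#' are `weights[i] * mean-intensity(patch i)` — the closed-form oracle used
#' throughout the test suite.  Supports probabilities and gradients plus a
#' vectorized masked-batch path.
#'
#' @param weights Numeric vector, one weight per patch.
#' @param link `"identity"` or `"sigmoid"`.
#' @return A [classifier_adapter()].
#' @export
make_linear_patch_scorer <- function(weights, link = c("identity", "sigmoid")) {
  link <- match.arg(link)
  stopifnot(all(is.finite(weights)))
  d <- length(weights)
  score <- function(image) sum(weights * patch_mean_intensity(image))
  to_probs <- function(s) {
    p2 <- if (link == "identity") s else stats::plogis(s)
    c(1 - p2, p2)
  }
  classifier_adapter(
    name = sprintf("linear_scorer(d%d,%s)", d, link),
    n_classes = 2,
    predict_fn = function(image) {
      stopifnot(image$d == d)
      to_probs(score(image))
    },
    logit_fn = function(image) {
      s <- score(image)
      # identity link: the score *is* the class-2 probability, so the "logit"
      # target coincides with it; sigmoid link: sigma(s) = softmax((0, s))[2]
      if (link == "identity") c(1 - s, s) else c(0, s)
    },
    gradient_fn = function(image, class_index, target) {
      s <- score(image)
      # d score / d pixel = w_i / (#pixels in patch * 3) inside patch i
      per_pixel <- weights / (image$patch_size^2 * 3)
      g <- array(0, dim(image$pixels))
      for (i in seq_len(d)) {
        ext <- patch_extent(image, i)
        g[ext$rows, ext$cols, ] <- per_pixel[i]
      }
      scale <- if (link == "identity") {
        if (class_index == 2) 1 else -1         # p1 = 1 - s for either target
      } else if (target == "logit") {
        if (class_index == 2) 1 else 0          # logits (0, s)
      } else {
        ds <- stats::plogis(s) * (1 - stats::plogis(s))
        if (class_index == 2) ds else -ds
      }
      g * scale
    },
    masked_batch_fn = function(image, masks, fill) {
      stopifnot(image$d == d)
      mi <- patch_mean_intensity(image)
      # masked patch contributes fill instead of its mean intensity
      s <- as.numeric(masks %*% (weights * mi) + (1 - masks) %*% (weights * fill))
      p2 <- if (link == "identity") s else stats::plogis(s)
      cbind(1 - p2, p2)
    }
  )
}
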