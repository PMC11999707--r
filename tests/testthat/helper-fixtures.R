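# Shared fixtures: tiny images, toy adapters with closed-form behavior, and
# random-game generators.  Everything is built in code, seed-reproducible.

random_image <- function(d = 4, patch_size = 4, seed = 1) {
  side <- sqrt(d)
  stopifnot(side %% 1 == 0)
  px <- patchattr:::with_seed(seed, {
    array(runif(side * patch_size * side * patch_size * 3),
          c(side * patch_size, side * patch_size, 3))
  })
  patched_image(px, patch_size)
}

# Image whose d patches are constant blocks with given intensities.
block_image <- function(intensities, patch_size = 2, cols = length(intensities)) {
  d <- length(intensities)
  rows <- d %/% cols
  px <- array(0, c(rows * patch_size, cols * patch_size, 3))
  img <- patched_image(px, patch_size)
  for (i in seq_len(d)) {
    ext <- patchattr:::patch_extent(img, i)
    px[ext$rows, ext$cols, ] <- intensities[i]
  }
  patched_image(px, patch_size)
}

# f_2 = scale * (number of patches with mean intensity > 0.5); with an
# all-0.9 image and fill 0 this counts the unmasked patches.
count_adapter <- function(d, scale = 1 / d) {
  classifier_adapter(
    "count", 2,
    predict_fn = function(im) {
      s <- scale * sum(patch_mean_intensity(im) > 0.5)
      c(1 - s, s)
    })
}

# f_2 = level iff patch `key` is present (mean intensity > 0.5), else 0.
indicator_adapter <- function(key = 1, level = 0.25) {
  classifier_adapter(
    "indicator", 2,
    predict_fn = function(im) {
      s <- if (patch_mean_intensity(im)[key] > 0.5) level else 0
      c(1 - s, s)
    })
}

constant_adapter <- function(p2 = 0.3) {
  classifier_adapter("constant", 2, predict_fn = function(im) c(1 - p2, p2),
                     gradient_fn = function(im, ci, tg) array(0, dim(im$pixels)))
}

# Random row-stochastic attention stack on d + 1 tokens.
random_stack <- function(d, layers, seed = 1) {
  patchattr:::with_seed(seed, {
    lapply(seq_len(layers), function(l) {
      A <- matrix(runif((d + 1)^2), d + 1, d + 1)
      A / rowSums(A)
    })
  })
}

# Random cooperative game from a value lookup table (v(0) = 0).
random_game <- function(d, seed = 1) {
  vals <- patchattr:::with_seed(seed, c(0, runif(2^d - 1, -1, 1)))
  cooperative_game(
    d,
    evaluate = function(m) vals[1 + sum(m * 2^(seq_len(d) - 1))],
    evaluate_batch = function(masks) {
      vals[1 + as.integer(masks %*% 2^(seq_len(d) - 1))]
    })
}

# Zero-noise pseudo-slide with 3 planted tumor and 2 background patches.
planted_slide <- function(seed = 11) {
  generate_pseudo_slide(synthetic_slide_spec(
    grid = c(3, 3), patch_size = 8, tumor_patches = c(1, 5, 9),
    background_patches = c(3, 7), noise_sd = 0, seed = seed))
}

top_k_precision <- function(ranking, truth_idx) {
  mean(ranking[seq_along(truth_idx)] %in% truth_idx)
}

# Additive image games sharing one linear scorer (fixed weights), with
# varying patch intensities: exact Shapley values are w_i * intensity_i, the
# closed form the explainer must learn.  Training and held-out sets must be
# built with the same `weights` (one classifier, many images).
additive_game_dataset <- function(n_games, d = 6, seed = 1,
                                  weights = patchattr:::with_seed(77, runif(d, 0.5, 1.5))) {
  lin <- make_linear_patch_scorer(weights, "identity")
  lapply(seq_len(n_games), function(g) {
    ints <- patchattr:::with_seed(seed + g, runif(d, 0.1, 0.9))
    img <- block_image(ints, patch_size = 2, cols = d)
    list(game = make_image_game(lin, img, 2),
         features = patch_mean_intensity(img),
         exact_phi = weights * ints)
  })
}
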