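# Shapley-value attribution.  A cooperative game over the d patches,
# v(m) = f_y(x (*) m) - f_y(0), is solved either exactly (2^d marginal
# enumeration), by the weighted-least-squares characterization under the
# Shapley kernel psh with the efficiency constraint 1' phi = v(1), or by a
# toy amortized explainer trained to emit Shapley maps in one forward pass.

#' Cooperative game over patches
#'
#' A set function `v : {0,1}^d -> R` with `v(0) = 0`.  `evaluate` takes a
#' single mask; `evaluate_batch` (optional, for speed) takes an `n x d` mask
#' matrix and returns a vector.
#'
#' @param d Number of players (patches).
#' @param evaluate Function of one binary mask returning a scalar.
#' @param evaluate_batch Optional vectorized form.
#' @return A `cooperative_game` object.
#' @export
cooperative_game <- function(d, evaluate, evaluate_batch = NULL) {
  g <- structure(list(d = as.integer(d), evaluate = evaluate,
                      evaluate_batch = evaluate_batch),
                 class = "cooperative_game")
  v0 <- game_values(g, matrix(0, 1, d))
  if (abs(v0) > 1e-9) {
    stop("cooperative game must satisfy v(0) = 0 (got ", format(v0), ")",
         call. = FALSE)
  }
  g
}

# v over a mask matrix (n x d).
game_values <- function(game, masks) {
  if (!is.matrix(masks)) masks <- matrix(masks, nrow = 1)
  if (!is.null(game$evaluate_batch)) {
    as.numeric(game$evaluate_batch(masks))
  } else {
    apply(masks, 1, game$evaluate)
  }
}

#' Grand-coalition value `v(1)`
#' @param game A [cooperative_game()].
#' @return Scalar.
#' @export
grand_value <- function(game) game_values(game, matrix(1, 1, game$d))

#' The removal game of an image classifier
#'
#' `v(m) = f_y(x (*) m) - f_y(0)`: the class-`y` probability of the image
#' with the patches outside the coalition replaced by `fill`, minus the
#' baseline prediction on the fully masked image (so `v(0) = 0`).  When the
#' original classifier is not robust to masked inputs, a surrogate adapter
#' fitted to masked images can be passed in its place.
#'
#' @param adapter A [classifier_adapter()].
#' @param image A [patched_image()].
#' @param class_index Target class `y`.
#' @param fill Fill value for removed patches (0 = black baseline).
#' @return A [cooperative_game()].
#' @export
make_image_game <- function(adapter, image, class_index, fill = 0) {
  require_capability(adapter, "probabilities")
  if (class_index < 1 || class_index > adapter$n_classes) {
    stop("invalid class_index", call. = FALSE)
  }
  d <- image$d
  base <- masked_predict(adapter, image, rep(0, d), fill)[class_index]
  cooperative_game(
    d,
    evaluate = function(m) {
      masked_predict(adapter, image, m, fill)[class_index] - base
    },
    evaluate_batch = function(masks) {
      masked_predict_batch(adapter, image, masks, fill)[, class_index] - base
    }
  )
}

#' Exact Shapley values by enumeration
#'
#' `phi_i = (1/d) sum_{m : m_i = 0} choose(d-1, |m|)^{-1} (v(m + e_i) - v(m))`
#' over all `2^(d-1)` coalitions excluding player `i`.  Efficiency
#' `sum(phi) = v(1)` holds exactly.  Cost: `2^d` game evaluations; guarded.
#'
#' @param game A [cooperative_game()].
#' @param guard Enumeration guard on `d`.
#' @return A `shapley_result`: list with `phi`, `grand_value`, `method`.
#' @export
exact_shapley <- function(game, guard = 14L) {
  d <- game$d
  masks <- enumerate_masks(d, guard)
  v <- game_values(game, masks)
  card <- rowSums(masks)
  phi <- numeric(d)
  for (i in seq_len(d)) {
    without <- masks[, i] == 0
    idx <- which(without)
    # mask integer of m + e_i is (row - 1) + 2^(i-1), rows are integer-ordered
    idx_with <- idx + 2L^(i - 1L)
    w <- 1 / choose(d - 1, card[idx])
    phi[i] <- sum(w * (v[idx_with] - v[idx])) / d
  }
  structure(list(phi = phi, grand_value = v[length(v)], method = "shapley-exact"),
            class = "shapley_result")
}

#' The Shapley kernel `psh`
#'
#' Weight of mask `m` proportional to `(|m| - 1)! (d - |m| - 1)!` on
#' `0 < |m| < d`, zero on the empty and full coalitions, normalized to a
#' probability law over all `2^d` masks.  Cardinality marginal:
#' `P(|m| = k) proportional to 1 / (k (d - k))`.
#'
#' @param d Number of players, `>= 2`.
#' @return A `kernel_weights` object: list with `d`, `cardinality_probs`
#'   (length `d + 1`, over `0..d`) and `mask_prob(masks)` returning the exact
#'   probability of each row.
#' @export
shapley_kernel <- function(d) {
  if (d < 2) stop("shapley kernel needs d >= 2", call. = FALSE)
  k <- 1:(d - 1)
  card_w <- 1 / (k * (d - k))                 # = choose(d,k) (k-1)!(d-k-1)! / d!
  card_p <- c(0, card_w / sum(card_w), 0)     # over cardinalities 0..d
  structure(list(
    d = d,
    cardinality_probs = card_p,
    mask_prob = function(masks) {
      if (!is.matrix(masks)) masks <- matrix(masks, nrow = 1)
      kk <- rowSums(masks)
      ifelse(kk == 0 | kk == d, 0, card_p[kk + 1] / choose(d, kk))
    },
    scheme = "shapley"),
    class = "kernel_weights")
}

#' Additive efficient normalization
#'
#' Projects a candidate attribution onto the efficiency constraint by adding
#' `(v(1) - sum(phi)) / d` to every coordinate.  Idempotent; the projection
#' applied after every explainer forward pass.
#'
#' @param phi Numeric vector.
#' @param grand_value Target total `v(1)`.
#' @return Vector with `sum == grand_value` exactly.
#' @export
additive_efficient_normalization <- function(phi, grand_value) {
  phi + (grand_value - sum(phi)) / length(phi)
}

#' Shapley values by constrained weighted least squares
#'
#' Minimizes the (weighted) squared error between `v(m)` and `m' phi` over a
#' mask design subject to `1' phi = v(1)`, solved in closed form by KKT
#' elimination.  With the exhaustive admissible-mask design and exact `psh`
#' weights this reproduces the enumeration definition exactly; with masks
#' sampled from `psh` (uniform weights) it is the Monte-Carlo estimator.
#'
#' @param game A [cooperative_game()].
#' @param masks `n x d` 0/1 matrix, a [sample_masks()] batch, or `NULL` for
#'   the exhaustive admissible design (all masks with `0 < |m| < d`; requires
#'   small `d`).
#' @param weights Per-mask weights; `NULL` means uniform (appropriate when
#'   masks were sampled from `psh`).  For the exhaustive design the exact
#'   `psh` weights are used automatically.
#' @param guard Enumeration guard for the exhaustive design.
#' @return A `shapley_result` (efficiency holds exactly).
#' @export
regression_shapley <- function(game, masks = NULL, weights = NULL, guard = 14L) {
  d <- game$d
  if (inherits(masks, "mask_batch")) masks <- masks$masks
  if (is.null(masks)) {
    masks <- enumerate_masks(d, guard)
    card <- rowSums(masks)
    keep <- card > 0 & card < d
    masks <- masks[keep, , drop = FALSE]
    if (is.null(weights)) weights <- shapley_kernel(d)$mask_prob(masks)
  }
  n <- nrow(masks)
  if (n < d + 1) {
    warning("fewer masks (", n, ") than players + 1; system may be rank-deficient")
  }
  if (is.null(weights)) weights <- rep(1, n)
  v1 <- grand_value(game)
  v <- game_values(game, masks)
  Mw <- masks * weights
  A <- t(Mw) %*% masks
  b <- as.numeric(t(Mw) %*% v)
  K <- rbind(cbind(A, rep(1, d)), c(rep(1, d), 0))
  sol <- tryCatch(solve(K, c(b, v1)), error = function(e) {
    stop("constrained least-squares system is rank-deficient: ",
         conditionMessage(e), call. = FALSE)
  })
  phi <- additive_efficient_normalization(sol[seq_len(d)], v1)
  structure(list(phi = phi, grand_value = v1, method = "shapley-regression",
                 n_masks = n),
            class = "shapley_result")
}

#' The surrogate masking law `p(m)`
#'
#' `p(m) = 1 / (choose(d, |m|) (d + 1))`: draw a cardinality uniformly on
#' `{0..d}`, then a uniform subset of that cardinality.  The mask law used to
#' expose a surrogate model to partially masked inputs during its fit.
#'
#' @param d Number of patches.
#' @return A `kernel_weights` object (see [shapley_kernel()]).
#' @export
surrogate_mask_law <- function(d) {
  structure(list(
    d = d,
    cardinality_probs = rep(1 / (d + 1), d + 1),
    mask_prob = function(masks) {
      if (!is.matrix(masks)) masks <- matrix(masks, nrow = 1)
      1 / (choose(d, rowSums(masks)) * (d + 1))
    },
    scheme = "uniform_cardinality"),
    class = "kernel_weights")
}

#' Sample masks from the surrogate law
#'
#' Convenience wrapper around [sample_masks()] with the
#' `uniform_cardinality` scheme.
#'
#' @param n Number of masks.
#' @param d Number of patches.
#' @param seed Integer seed.
#' @return A `mask_batch`.
#' @export
sample_surrogate_masks <- function(n, d, seed = 1) {
  sample_masks(n, d, scheme = "uniform_cardinality", seed = seed)
}

#' Surrogate distillation objective
#'
#' `D_KL(teacher || student)` between the original classifier's prediction on
#' the clean image and the surrogate's prediction on the masked image:
#' non-negative and zero iff the distributions match.
#'
#' @param teacher_probs,student_probs Probability vectors of equal length.
#' @param tol Normalization tolerance.
#' @return Scalar KL divergence (nats).
#' @export
surrogate_objective <- function(teacher_probs, student_probs, tol = 1e-6) {
  if (length(teacher_probs) != length(student_probs) ||
      abs(sum(teacher_probs) - 1) > tol || abs(sum(student_probs) - 1) > tol ||
      any(teacher_probs < 0) || any(student_probs < 0)) {
    stop("inputs must be probability vectors of equal length", call. = FALSE)
  }
  pos <- teacher_probs > 0
  sum(teacher_probs[pos] * log(teacher_probs[pos] / student_probs[pos]))
}
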