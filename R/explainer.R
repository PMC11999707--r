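# Toy amortized Shapley explainer.  At full scale the explainer is a network
# emitting a d-patch Shapley map in one forward pass; here it is a per-patch
# affine model phi_i = a_i * s_i + b_i on a per-patch feature s (the patch
# mean intensity for image games), trained on the kernel-weighted squared
# error with masks drawn from psh.  Every forward pass ends with additive
# efficient normalization, so the efficiency side constraint holds by
# construction, during training and at inference alike.

#' Linear per-patch explainer
#'
#' @param d Number of patches.
#' @param init_scale Standard deviation of the random parameter init.
#' @param seed Seed for the init.
#' @return An `explainer_model` with fields `par` (`a`, `b`) and
#'   `forward(features, grand_value)` returning an efficiency-normalized
#'   attribution vector.
#' @export
linear_explainer <- function(d, init_scale = 0.1, seed = 1) {
  par <- with_seed(seed, list(a = stats::rnorm(d, sd = init_scale),
                              b = stats::rnorm(d, sd = init_scale)))
  model <- structure(list(d = as.integer(d), par = par), class = "explainer_model")
  model
}

#' Explainer forward pass (with efficiency projection)
#'
#' @param model An [linear_explainer()].
#' @param features Per-patch feature vector of length `d`.
#' @param grand_value The game's `v(1)`, the total the output must sum to.
#' @return Attribution vector with `sum == grand_value` (within 1e-12).
#' @export
explainer_forward <- function(model, features, grand_value) {
  raw <- model$par$a * features + model$par$b
  additive_efficient_normalization(raw, grand_value)
}

#' Train the toy explainer
#'
#' Minimizes the empirical version of the kernel-weighted objective: for
#' games `v` drawn from the training set and masks `m ~ psh`,
#' `(v(m) - m' phi_hat)^2` with `phi_hat` the projected forward output.
#' Optimized with Adam; the loss trace (one smoothed value per epoch) is
#' returned alongside the fitted model.
#'
#' @param dataset List of training cases, each a list with `game` (a
#'   [cooperative_game()]) and `features` (length-`d` numeric).
#' @param model An [linear_explainer()].
#' @param n_masks_per_step Masks sampled per game per epoch.
#' @param epochs Passes over the dataset.
#' @param lr Adam learning rate.
#' @param seed Seed for mask sampling.
#' @return List with `model` (trained), `loss_trace` (numeric per epoch).
#' @export
train_explainer <- function(dataset, model, n_masks_per_step = 32,
                            epochs = 150, lr = 0.05, seed = 1) {
  d <- model$d
  a <- model$par$a; b <- model$par$b
  ma <- va <- numeric(d); mb <- vb <- numeric(d)   # Adam moments
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  loss_trace <- numeric(epochs)
  # Precompute per-game grand values once.
  v1s <- vapply(dataset, function(case) grand_value(case$game), numeric(1))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ep_loss <- 0; ep_n <- 0
      for (gi in seq_along(dataset)) {
        case <- dataset[[gi]]
        kk <- 1:(d - 1)
        ks <- sample(kk, n_masks_per_step, replace = TRUE,
                     prob = 1 / (kk * (d - kk)))
        masks <- matrix(0, n_masks_per_step, d)
        for (j in seq_len(n_masks_per_step)) masks[j, sample.int(d, ks[j])] <- 1
        v <- game_values(case$game, masks)
        raw <- a * case$features + b
        phi <- additive_efficient_normalization(raw, v1s[gi])
        resid <- as.numeric(masks %*% phi) - v
        ep_loss <- ep_loss + sum(resid^2); ep_n <- ep_n + length(resid)
        # d loss / d phi, then through the projection (I - J/d) and the
        # affine parametrization.
        gphi <- 2 * as.numeric(t(masks) %*% resid) / n_masks_per_step
        graw <- gphi - mean(gphi)
        ga <- graw * case$features
        gb <- graw
        step <- step + 1
        ma <- beta1 * ma + (1 - beta1) * ga; va <- beta2 * va + (1 - beta2) * ga^2
        mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        a <- a - lr * (ma / corr1) / (sqrt(va / corr2) + eps)
        b <- b - lr * (mb / corr1) / (sqrt(vb / corr2) + eps)
      }
      loss_trace[ep] <- ep_loss / ep_n
      if (!is.finite(loss_trace[ep])) {
        stop("explainer training diverged (non-finite loss)", call. = FALSE)
      }
    }
  })
  model$par <- list(a = a, b = b)
  list(model = model, loss_trace = loss_trace)
}
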