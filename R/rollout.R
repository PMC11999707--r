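# Attention Rollout: importance of patch i as the total information flow
# from token i to the class token, i.e. the cls row of the layer-ordered
# product A_n ... A_1, optionally after residual correction (A + I,
# row-renormalized) of every layer.

#' Rollout configuration
#'
#' @param residual Add the identity to every attention matrix before the
#'   product (models the skip connection around each attention module).
#' @param renormalize Row-renormalize after adding the identity (default
#'   `TRUE` when `residual`; `(A + I)/2` for row-stochastic `A`).
#' @return A `rollout_config` object.
#' @export
rollout_config <- function(residual = FALSE, renormalize = residual) {
  if (renormalize && !residual) {
    stop("`renormalize` requires `residual = TRUE`", call. = FALSE)
  }
  structure(list(residual = residual, renormalize = renormalize),
            class = "rollout_config")
}

rollout_matrices <- function(stack, config) {
  lapply(stack, function(A) {
    if (config$residual) {
      A <- A + diag(nrow(A))
      if (config$renormalize) A <- A / rowSums(A)
    }
    A
  })
}

#' Attention Rollout attribution
#'
#' Multiplies the (optionally residual-corrected) per-layer attention
#' matrices in layer order and reads the class-token row: entry `i` is the
#' sum over all layered paths from input token `i` to the final class token
#' of the product of traversed attention weights.  The class-token column is
#' dropped from the returned map.  Without the residual the full token score
#' vector sums to 1 (a product of row-stochastic matrices is row-stochastic).
#'
#' @param stack An `attention_stack` (list of `(d+1) x (d+1)` row-stochastic
#'   matrices, class token first), e.g. from [attention_maps()].
#' @param config A [rollout_config()].
#' @return An [attribution_map()] of length `d`.
#' @export
rollout_attribution <- function(stack, config = rollout_config()) {
  stack <- validate_attention_stack(stack)
  mats <- rollout_matrices(stack, config)
  prod <- Reduce(`%*%`, rev(mats))         # A_n %*% ... %*% A_1
  scores <- prod[1, -1]
  attribution_map(scores, method = if (config$residual) "rollout-res" else "rollout")
}

#' Path-enumeration oracle for rollout
#'
#' Explicitly enumerates every layered path through the token graph and sums,
#' per source token, the products of traversed edge weights over all paths
#' ending at the class token.  Exponential in the number of layers; guarded
#' to desk scale.  Equals the matrix-product rollout exactly.
#'
#' @param stack List of `(d+1) x (d+1)` attention matrices (layer 1 first).
#' @param config A [rollout_config()].
#' @param max_paths Enumeration guard on `(d+1)^(n-1)` interior assignments.
#' @return Numeric vector of length `d + 1`: flow from every token (class
#'   token included, first) to the final class token.
#' @export
path_flow_oracle <- function(stack, config = rollout_config(),
                             max_paths = 2e5) {
  mats <- rollout_matrices(stack, config)
  n <- length(mats)
  n_tok <- nrow(mats[[1]])
  if (n_tok^(n - 1) > max_paths) {
    stop("path enumeration would exceed the size guard", call. = FALSE)
  }
  flows <- numeric(n_tok)
  interior <- if (n == 1) matrix(integer(0), nrow = 1)
              else as.matrix(expand.grid(rep(list(seq_len(n_tok)), n - 1)))
  for (src in seq_len(n_tok)) {
    total <- 0
    for (p in seq_len(nrow(interior))) {
      nodes <- c(src, interior[p, ], 1L)   # layer-0 token ... final cls token
      wprod <- 1
      for (l in seq_len(n)) wprod <- wprod * mats[[l]][nodes[l + 1], nodes[l]]
      total <- total + wprod
    }
    flows[src] <- total
  }
  flows
}
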