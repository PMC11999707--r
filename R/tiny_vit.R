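# Minimal vision transformer used as a differentiable reference model.
#
# Architecture per layer: multi-head self-attention with a residual
# connection, then a two-layer tanh MLP with a residual connection; a linear
# patch embedding with a prepended class token and additive positional
# embeddings in front, and a linear head on the class token behind.  Layer
# normalization is deliberately omitted: at desk scale the random
# initialization keeps activations bounded and the omission keeps the exact
# input-pixel backward pass short and auditable.

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# d x P matrix of flattened patches (column-major within a patch:
# rows, columns, then channels).  Inverse: unpatchify_gradient().
patchify <- function(image) {
  t(vapply(seq_len(image$d), function(i) as.vector(patch_pixels(image, i)),
           numeric(image$patch_size^2 * 3)))
}

unpatchify <- function(image, mat) {
  out <- array(0, dim(image$pixels))
  ps <- image$patch_size
  for (i in seq_len(image$d)) {
    ext <- patch_extent(image, i)
    out[ext$rows, ext$cols, ] <- array(mat[i, ], c(ps, ps, 3))
  }
  out
}

vit_init_params <- function(layers, heads, d, seed, patch_size, embed_dim,
                            mlp_dim, n_classes) {
  P <- patch_size^2 * 3
  with_seed(seed, {
    rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    list(
      layers = layers, heads = heads, d = d, patch_size = patch_size,
      embed_dim = embed_dim, mlp_dim = mlp_dim, n_classes = n_classes,
      Wp = rn(P, embed_dim, 1 / sqrt(P)), bp = stats::rnorm(embed_dim, sd = 0.1),
      cls = stats::rnorm(embed_dim, sd = 0.5),
      pos = rn(d + 1, embed_dim, 0.1),
      blocks = lapply(seq_len(layers), function(l) list(
        Wq = rn(embed_dim, embed_dim, 1 / sqrt(embed_dim)),
        Wk = rn(embed_dim, embed_dim, 1 / sqrt(embed_dim)),
        Wv = rn(embed_dim, embed_dim, 1 / sqrt(embed_dim)),
        Wo = rn(embed_dim, embed_dim, 1 / sqrt(embed_dim)),
        W1 = rn(embed_dim, mlp_dim, 1 / sqrt(embed_dim)),
        b1 = stats::rnorm(mlp_dim, sd = 0.1),
        W2 = rn(mlp_dim, embed_dim, 1 / sqrt(mlp_dim)),
        b2 = stats::rnorm(embed_dim, sd = 0.1)
      )),
      Wh = rn(embed_dim, n_classes, 1 / sqrt(embed_dim)),
      bh = stats::rnorm(n_classes, sd = 0.1)
    )
  })
}

head_cols <- function(params, k) {
  dk <- params$embed_dim %/% params$heads
  ((k - 1L) * dk + 1L):(k * dk)
}

# Forward pass from token embeddings E (d x embed_dim).  Returns logits,
# probabilities, the head-averaged attention stack, and (optionally) every
# intermediate needed by the backward pass.
vit_forward_tokens <- function(params, E, keep_cache = FALSE) {
  X <- rbind(params$cls, E) + params$pos
  dk <- params$embed_dim %/% params$heads
  cache <- if (keep_cache) list(X0 = X, blocks = vector("list", params$layers))
  attn <- vector("list", params$layers)
  for (l in seq_len(params$layers)) {
    b <- params$blocks[[l]]
    X_in <- X
    Q <- X %*% b$Wq; K <- X %*% b$Wk; V <- X %*% b$Wv
    A_heads <- vector("list", params$heads)
    Ocat <- matrix(0, nrow(X), params$embed_dim)
    for (k in seq_len(params$heads)) {
      ck <- head_cols(params, k)
      A_heads[[k]] <- softmax_rows(Q[, ck, drop = FALSE] %*%
                                     t(K[, ck, drop = FALSE]) / sqrt(dk))
      Ocat[, ck] <- A_heads[[k]] %*% V[, ck, drop = FALSE]
    }
    attn[[l]] <- Reduce(`+`, A_heads) / params$heads
    X <- X_in + Ocat %*% b$Wo
    X_mid <- X
    H <- tanh(X %*% b$W1 + matrix(b$b1, nrow(X), params$mlp_dim, byrow = TRUE))
    X <- X + H %*% b$W2 + matrix(b$b2, nrow(X), params$embed_dim, byrow = TRUE)
    if (keep_cache) {
      cache$blocks[[l]] <- list(X_in = X_in, Q = Q, K = K, V = V,
                                A_heads = A_heads, Ocat = Ocat,
                                X_mid = X_mid, H = H)
    }
  }
  logits <- drop(X[1, ] %*% params$Wh) + params$bh
  list(logits = logits, probs = softmax_vec(logits), attn = attn, cache = cache)
}

vit_forward <- function(params, image, keep_cache = FALSE) {
  stopifnot(image$d == params$d, image$patch_size == params$patch_size)
  E <- patchify(image) %*% params$Wp +
    matrix(params$bp, image$d, params$embed_dim, byrow = TRUE)
  vit_forward_tokens(params, E, keep_cache = keep_cache)
}

# Exact input-pixel gradient of one class score by reverse-mode
# differentiation through every block.
vit_input_gradient <- function(params, image, class_index, target = "logit") {
  fw <- vit_forward(params, image, keep_cache = TRUE)
  dlogits <- if (target == "logit") {
    as.numeric(seq_len(params$n_classes) == class_index)
  } else {
    p <- fw$probs
    p[class_index] * (as.numeric(seq_len(params$n_classes) == class_index) - p)
  }
  n_tok <- params$d + 1L
  dX <- matrix(0, n_tok, params$embed_dim)
  dX[1, ] <- as.numeric(params$Wh %*% dlogits)
  dk <- params$embed_dim %/% params$heads
  for (l in rev(seq_len(params$layers))) {
    b <- params$blocks[[l]]
    cb <- fw$cache$blocks[[l]]
    # MLP block: X_out = X_mid + tanh(X_mid W1 + b1) W2 + b2
    dpre <- (dX %*% t(b$W2)) * (1 - cb$H^2)
    dX <- dX + dpre %*% t(b$W1)
    # attention block: X_mid = X_in + [A_k V_k]_k Wo
    dOcat <- dX %*% t(b$Wo)
    dQ <- matrix(0, n_tok, params$embed_dim)
    dK <- matrix(0, n_tok, params$embed_dim)
    dV <- matrix(0, n_tok, params$embed_dim)
    for (k in seq_len(params$heads)) {
      ck <- head_cols(params, k)
      A <- cb$A_heads[[k]]
      dO <- dOcat[, ck, drop = FALSE]
      dA <- dO %*% t(cb$V[, ck, drop = FALSE])
      dV[, ck] <- t(A) %*% dO
      dS <- A * (dA - rowSums(dA * A))
      dQ[, ck] <- dS %*% cb$K[, ck, drop = FALSE] / sqrt(dk)
      dK[, ck] <- t(dS) %*% cb$Q[, ck, drop = FALSE] / sqrt(dk)
    }
    dX <- dX + dQ %*% t(b$Wq) + dK %*% t(b$Wk) + dV %*% t(b$Wv)
  }
  dE <- dX[-1, , drop = FALSE]           # positional/cls terms are constants
  unpatchify(image, dE %*% t(params$Wp))
}

vit_adapter_from_params <- function(params, name) {
  masked_tokens <- function(image, masks, fill) {
    Xp <- patchify(image)
    E_full <- Xp %*% params$Wp +
      matrix(params$bp, params$d, params$embed_dim, byrow = TRUE)
    E_fill <- drop(rep(fill, ncol(Xp)) %*% params$Wp) + params$bp
    t(apply(masks, 1, function(m) {
      E <- E_full
      if (any(m == 0)) E[m == 0, ] <- matrix(E_fill, sum(m == 0),
                                             params$embed_dim, byrow = TRUE)
      vit_forward_tokens(params, E)$probs
    }))
  }
  adapter <- classifier_adapter(
    name = name,
    n_classes = params$n_classes,
    predict_fn = function(image) vit_forward(params, image)$probs,
    logit_fn = function(image) vit_forward(params, image)$logits,
    gradient_fn = function(image, class_index, target) {
      vit_input_gradient(params, image, class_index, target)
    },
    attention_fn = function(image) vit_forward(params, image)$attn,
    masked_batch_fn = masked_tokens
  )
  adapter$params <- params
  adapter
}

#' Tiny randomly initialized vision transformer
#'
#' A fully self-contained transformer reference model exposing probabilities,
#' exact input gradients (reverse-mode, no finite differences) and
#' head-averaged attention matrices, so that every attribution method in the
#' package can be exercised without external weights.  Same seed, same
#' parameters, same outputs.
#'
#' @param layers Number of transformer blocks.
#' @param heads Number of attention heads (must divide `embed_dim`).
#' @param d Number of patches; must be a perfect square (square token grid).
#' @param seed Integer seed for the random initialization.
#' @param patch_size Patch side length in pixels.
#' @param embed_dim Token embedding dimension.
#' @param mlp_dim Hidden width of the per-block MLP.
#' @param n_classes Number of output classes.
#' @return A [classifier_adapter()] with capabilities probabilities,
#'   gradients and attentions.
#' @examples
#' vit <- make_tiny_vit(layers = 2, heads = 2, d = 4, seed = 1, patch_size = 4)
#' img <- patched_image(array(runif(8 * 8 * 3), c(8, 8, 3)), 4)
#' sum(predict_probs(vit, img))  # 1
#' @export
make_tiny_vit <- function(layers = 2, heads = 2, d = 16, seed = 1,
                          patch_size = 4, embed_dim = 16, mlp_dim = 32,
                          n_classes = 2) {
  if (sqrt(d) %% 1 != 0) stop("`d` must be a perfect square", call. = FALSE)
  if (embed_dim %% heads != 0) stop("`heads` must divide `embed_dim`", call. = FALSE)
  params <- vit_init_params(layers, heads, d, seed, patch_size, embed_dim,
                            mlp_dim, n_classes)
  vit_adapter_from_params(params, sprintf("tiny_vit(L%d,H%d,d%d,seed%d)",
                                          layers, heads, d, seed))
}

#' Hand-constructed color-attentive transformer
#'
#' A one-layer, one-head transformer whose weights are set analytically so the
#' class-2 score responds to the "purpleness" of patches (the chromatic
#' signature of the planted tumor texture in the synthetic generator): the
#' class token attends to patches in proportion to `exp(tau * purpleness)` and
#' reads out the attention-weighted purpleness, where purpleness of a mean
#' patch color is `(r + b) / 2 - g`.  Unlike the randomly initialized
#' transformer this model genuinely prefers planted signal patches, which
#' makes it the demonstration classifier for end-to-end benchmark runs while
#' still exposing the full transformer contract (probabilities, gradients,
#' attentions).
#'
#' @param d Number of patches (perfect square).
#' @param patch_size Patch side length in pixels.
#' @param tau Attention temperature on purpleness.
#' @param gain Logit gain on the attended purpleness.
#' @return A [classifier_adapter()] with all three capabilities.
#' @export
make_color_attentive_vit <- function(d = 9, patch_size = 8, tau = 8, gain = 6) {
  if (sqrt(d) %% 1 != 0) stop("`d` must be a perfect square", call. = FALSE)
  e <- 4L
  P <- patch_size^2 * 3
  zero <- function(nr, nc) matrix(0, nr, nc)
  # Wp column 1 computes the purpleness of the patch-mean color.
  u <- c(0.5, -1, 0.5)
  Wp <- zero(P, e)
  Wp[, 1] <- rep(u, each = patch_size^2) / patch_size^2
  Wq <- zero(e, e); Wq[2, 1] <- 2 * tau   # cls marker -> query axis 1
  Wk <- zero(e, e); Wk[1, 1] <- 1         # purpleness -> key axis 1
  Wv <- zero(e, e); Wv[1, 3] <- 1         # purpleness -> value axis 3
  Wh <- zero(e, 2); Wh[3, 2] <- gain
  params <- list(
    layers = 1L, heads = 1L, d = as.integer(d), patch_size = as.integer(patch_size),
    embed_dim = e, mlp_dim = 1L, n_classes = 2L,
    Wp = Wp, bp = rep(0, e),
    cls = c(0, 1, 0, 0),
    pos = zero(d + 1, e),
    blocks = list(list(Wq = Wq, Wk = Wk, Wv = Wv, Wo = diag(e),
                       W1 = zero(e, 1), b1 = 0, W2 = zero(1, e), b2 = rep(0, e))),
    Wh = Wh, bh = rep(0, 2)
  )
  # sqrt(dk) = 2 is absorbed into Wq, hence the factor 2 * tau above.
  vit_adapter_from_params(params, sprintf("color_attentive_vit(d%d)", d))
}
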