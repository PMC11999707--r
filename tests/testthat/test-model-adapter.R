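# The classifier adapter contract: normalized probabilities, masking
# semantics, attention stacks, and exact input gradients.

test_that("predictions are normalized and batch evaluation validates shapes", {
  img <- random_image(d = 4, seed = 1)
  lin <- make_linear_patch_scorer(runif(4), link = "sigmoid")
  p <- predict_probs(lin, img)
  expect_length(p, 2)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  zero <- patched_image(array(0, c(8, 8, 3)), 4)
  expect_equal(predict_probs(lin, zero), c(0.5, 0.5))  # sigma(0) = 1/2

  batch <- predict_probs(lin, list(img, img))
  expect_equal(dim(batch), c(2L, 2L))
  bad <- patched_image(array(0, c(4, 4, 3)), 4)
  expect_error(predict_probs(lin, list(img, bad)), "shape")
})

test_that("all-ones mask reproduces the unmasked prediction bit-identically", {
  img <- random_image(d = 4, seed = 2)
  vit <- make_tiny_vit(layers = 1, heads = 2, d = 4, seed = 5, patch_size = 4,
                       embed_dim = 8, mlp_dim = 8)
  expect_identical(masked_predict(vit, img, rep(1, 4)),
                   predict_probs(vit, img))
})

test_that("masked logit of the linear scorer is the sum of surviving contributions", {
  w <- c(0.4, -0.2, 0.7, 0.1)
  lin <- make_linear_patch_scorer(w, link = "identity")
  img <- block_image(c(0.2, 0.4, 0.6, 0.8))
  mask <- c(1, 0, 1, 0)
  p <- masked_predict(lin, img, mask, fill = 0)
  expect_equal(p[2], sum(w * c(0.2, 0, 0.6, 0)), tolerance = 1e-12)
  expect_error(masked_predict(lin, img, c(1, 0)), "mask length")
})

test_that("a fully masked image with black fill gives the baseline prediction", {
  img <- random_image(d = 4, seed = 3)
  vit <- make_tiny_vit(layers = 1, heads = 1, d = 4, seed = 9, patch_size = 4,
                       embed_dim = 8, mlp_dim = 8)
  black <- patched_image(array(0, dim(img$pixels)), img$patch_size)
  expect_equal(masked_predict(vit, img, rep(0, 4), fill = 0),
               predict_probs(vit, black), tolerance = 1e-12)
})

test_that("tiny ViT is deterministic and exposes a well-formed attention stack", {
  vit1 <- make_tiny_vit(layers = 4, heads = 2, d = 16, seed = 7)
  vit2 <- make_tiny_vit(layers = 4, heads = 2, d = 16, seed = 7)
  img <- random_image(d = 16, seed = 4)
  expect_identical(predict_probs(vit1, img), predict_probs(vit2, img))
  expect_identical(predict_probs(vit1, img), predict_probs(vit1, img))

  stack <- attention_maps(vit1, img)
  expect_length(stack, 4)                       # one matrix per layer
  expect_equal(dim(stack[[1]]), c(17L, 17L))    # d + 1 tokens including cls
  for (A in stack) {
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, 17), tolerance = 1e-5)
  }
})

test_that("head averaging of identical heads equals either head", {
  # 2 heads with identical weights per head-slice: force by tying Wq/Wk/Wv
  # columns across the two head column blocks.
  vit <- make_tiny_vit(layers = 1, heads = 2, d = 4, seed = 1, patch_size = 2,
                       embed_dim = 8, mlp_dim = 4)
  p <- vit$params
  for (nm in c("Wq", "Wk", "Wv")) {
    p$blocks[[1]][[nm]][, 5:8] <- p$blocks[[1]][[nm]][, 1:4]
  }
  tied <- patchattr:::vit_adapter_from_params(p, "tied")
  img <- random_image(d = 4, patch_size = 2, seed = 5)
  A_avg <- attention_maps(tied, img)[[1]]
  # recompute head 1 alone
  fw <- patchattr:::vit_forward(p, img, keep_cache = TRUE)
  A1 <- fw$cache$blocks[[1]]$A_heads[[1]]
  expect_equal(A_avg, A1, tolerance = 1e-12)
})

test_that("analytic input gradients match central finite differences", {
  vit <- make_tiny_vit(layers = 2, heads = 2, d = 4, seed = 3, patch_size = 4,
                       embed_dim = 8, mlp_dim = 16)
  img <- random_image(d = 4, seed = 6)
  for (target in c("logit", "probability")) {
    g <- input_gradient(vit, img, 2, target)
    h <- 1e-4
    idx <- patchattr:::with_seed(8, {
      cbind(sample(8, 10, TRUE), sample(8, 10, TRUE), sample(3, 10, TRUE))
    })
    for (r in seq_len(nrow(idx))) {
      p1 <- img$pixels; p2 <- img$pixels
      p1[idx[r, 1], idx[r, 2], idx[r, 3]] <- p1[idx[r, 1], idx[r, 2], idx[r, 3]] + h
      p2[idx[r, 1], idx[r, 2], idx[r, 3]] <- p2[idx[r, 1], idx[r, 2], idx[r, 3]] - h
      fval <- function(px) {
        im <- patched_image(px, 4)
        if (target == "logit") vit$logit_fn(im)[2] else predict_probs(vit, im)[2]
      }
      fd <- (fval(p1) - fval(p2)) / (2 * h)
      expect_equal(g[idx[r, 1], idx[r, 2], idx[r, 3]], fd,
                   tolerance = 1e-3 * max(abs(fd), 1e-6))
    }
  }
})

test_that("gradients of linear and constant classifiers have closed forms", {
  w <- c(1, -0.5, 0.25, 2)
  lin <- make_linear_patch_scorer(w, link = "identity")
  img <- block_image(c(0.1, 0.2, 0.3, 0.4), patch_size = 2)
  g <- input_gradient(lin, img, 2, "logit")
  for (i in 1:4) {
    ext <- patchattr:::patch_extent(img, i)
    expect_equal(unique(as.vector(g[ext$rows, ext$cols, ])),
                 w[i] / (2 * 2 * 3), tolerance = 1e-12)
  }
  gc <- input_gradient(constant_adapter(), img, 1, "probability")
  expect_true(all(gc == 0))
  expect_error(input_gradient(lin, img, 5), "class_index")
})

test_that("capability errors are raised for unsupported operations", {
  lin <- make_linear_patch_scorer(rep(1, 4))
  img <- block_image(rep(0.5, 4))
  expect_error(attention_maps(lin, img), "capability")
  nogrid <- classifier_adapter("p-only", 2, function(im) c(0.5, 0.5))
  expect_error(input_gradient(nogrid, img, 1), "capability")
})
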