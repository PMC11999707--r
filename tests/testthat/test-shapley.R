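# Shapley values: enumeration, kernel, constrained least squares, the image
# game, mask laws, and the distillation objective.

test_that("the two-player example enumerates to (1.5, 2.5)", {
  game <- cooperative_game(2, function(m) c(0, 1, 2, 4)[1 + m[1] + 2 * m[2]])
  res <- exact_shapley(game)
  expect_equal(res$phi, c(1.5, 2.5), tolerance = 1e-12)
  expect_equal(sum(res$phi), res$grand_value, tolerance = 1e-12)
})

test_that("symmetry and null-player axioms hold on constructed games", {
  sym <- cooperative_game(4, function(m) sum(m)^2 / 16)
  expect_equal(exact_shapley(sym)$phi, rep(1 / 4, 4), tolerance = 1e-12)

  dummy <- cooperative_game(4, function(m) m[1] * 0.5 + m[2] * m[3] * 0.25)
  expect_equal(exact_shapley(dummy)$phi[4], 0, tolerance = 1e-12)
})

test_that("Shapley values are linear in the game", {
  g1 <- random_game(5, seed = 1)
  g2 <- random_game(5, seed = 2)
  gsum <- cooperative_game(5, function(m) g1$evaluate(m) + g2$evaluate(m))
  expect_equal(exact_shapley(gsum)$phi,
               exact_shapley(g1)$phi + exact_shapley(g2)$phi,
               tolerance = 1e-10)
})

test_that("games violating v(0) = 0 are rejected; guard limits enumeration", {
  expect_error(cooperative_game(2, function(m) 1), "v\\(0\\)")
  expect_error(exact_shapley(random_game(6, 1), guard = 4L), "guard")
})

test_that("the Shapley kernel weights match factorial arithmetic", {
  kw <- shapley_kernel(3)
  masks <- patchattr:::enumerate_masks(3)
  p <- kw$mask_prob(masks)
  # d = 3: all six admissible masks equally weighted at 1/6
  card <- rowSums(masks)
  expect_equal(p[card %in% c(1, 2)], rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(p[card %in% c(0, 3)], c(0, 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  kw4 <- shapley_kernel(4)
  m1 <- c(1, 0, 0, 0); m2 <- c(1, 1, 0, 0)
  # per-mask weight ratio (1!1!)/(0!2!) = 1/2 for |m| = 2 vs |m| = 1
  expect_equal(kw4$mask_prob(m2) / kw4$mask_prob(m1), 1 / 2, tolerance = 1e-12)
  expect_error(shapley_kernel(1), "d >= 2")
})

test_that("additive efficient normalization is forced, idempotent, exact", {
  expect_equal(additive_efficient_normalization(c(1, 1), 4), c(2, 2))
  phi <- c(0.3, 0.5, 0.2)
  expect_equal(additive_efficient_normalization(phi, 1), phi)
  once <- additive_efficient_normalization(c(0.1, 0.9, 0.4), 2)
  expect_equal(additive_efficient_normalization(once, 2), once)
  expect_equal(sum(once), 2, tolerance = 1e-12)
})

test_that("constrained least squares on the full admissible design is exact", {
  for (seed in 1:5) {
    game <- random_game(8, seed = seed)
    expect_lt(max(abs(regression_shapley(game)$phi - exact_shapley(game)$phi)),
              1e-6)
  }
})

test_that("additive games are recovered exactly from any valid design", {
  w <- c(0.5, -0.2, 0.9, 0.1)
  game <- cooperative_game(4, function(m) sum(m * w))
  expect_equal(regression_shapley(game)$phi, w, tolerance = 1e-10)
  mb <- sample_masks(200, 4, "shapley", seed = 3)
  expect_equal(regression_shapley(game, mb)$phi, w, tolerance = 1e-10)
})

test_that("sampled-mask regression approaches the exact values", {
  game <- random_game(8, seed = 11)
  ex <- exact_shapley(game)$phi
  mb <- sample_masks(20000, 8, "shapley", seed = 5)
  est <- regression_shapley(game, mb)$phi
  # bootstrap standard errors of the estimator over mask resamples
  boots <- vapply(1:30, function(b) {
    idx <- patchattr:::with_seed(100 + b,
                                 sample.int(nrow(mb$masks), replace = TRUE))
    regression_shapley(game, mb$masks[idx, , drop = FALSE])$phi
  }, numeric(8))
  se <- apply(boots, 1, stats::sd)
  expect_true(all(abs(est - ex) < 3 * pmax(se, 1e-8)))
})

test_that("the image game subtracts its baseline and matches masked predictions", {
  img <- block_image(c(0.3, 0.6, 0.9, 0.15))
  lin <- make_linear_patch_scorer(c(0.5, -0.3, 0.8, 0.2), "sigmoid")
  game <- make_image_game(lin, img, 2)
  expect_equal(game$evaluate(rep(0, 4)), 0, tolerance = 1e-12)
  m <- c(1, 0, 1, 0)
  expect_equal(game$evaluate(m),
               masked_predict(lin, img, m)[2] -
                 masked_predict(lin, img, rep(0, 4))[2],
               tolerance = 1e-12)
  expect_equal(grand_value(game),
               predict_probs(lin, img)[2] -
                 masked_predict(lin, img, rep(0, 4))[2],
               tolerance = 1e-12)
  expect_error(make_image_game(lin, img, 3), "class_index")
})

test_that("constant classifiers induce the zero game", {
  img <- block_image(rep(0.5, 4))
  game <- make_image_game(constant_adapter(0.4), img, 2)
  expect_equal(exact_shapley(game)$phi, rep(0, 4), tolerance = 1e-12)
})

test_that("the surrogate mask law matches its closed form and normalizes", {
  law2 <- surrogate_mask_law(2)
  expect_equal(law2$mask_prob(c(0, 0)), 1 / 3, tolerance = 1e-12)
  expect_equal(law2$mask_prob(c(1, 0)), 1 / 6, tolerance = 1e-12)
  expect_equal(law2$mask_prob(c(0, 1)), 1 / 6, tolerance = 1e-12)
  expect_equal(law2$mask_prob(c(1, 1)), 1 / 3, tolerance = 1e-12)
  for (d in c(4, 8, 12)) {
    masks <- patchattr:::enumerate_masks(d)
    expect_equal(sum(surrogate_mask_law(d)$mask_prob(masks)), 1,
                 tolerance = 1e-9)
    expect_equal(sum(shapley_kernel(d)$mask_prob(masks)), 1,
                 tolerance = 1e-9)
  }
})

test_that("the surrogate sampler has uniform cardinalities", {
  mb <- sample_surrogate_masks(20000, 8, seed = 6)
  chi <- stats::chisq.test(table(factor(rowSums(mb$masks), levels = 0:8)))
  expect_gt(chi$p.value, 0.001)
})

test_that("the distillation objective is a valid KL divergence", {
  expect_equal(surrogate_objective(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(surrogate_objective(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-12)
  for (s in 1:10) {
    p <- patchattr:::with_seed(s, { x <- runif(3); x / sum(x) })
    q <- patchattr:::with_seed(s + 50, { x <- runif(3); x / sum(x) })
    expect_gte(surrogate_objective(p, q), 0)
  }
  expect_error(surrogate_objective(c(0.5, 0.6), c(0.5, 0.5)), "probability")
})
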