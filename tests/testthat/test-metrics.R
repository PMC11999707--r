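# Insertion/Deletion curves, aggregation, and Welch comparisons.

test_that("ranking is descending with deterministic tie-breaks", {
  expect_equal(rank_patches(c(0.1, 0.9, 0.5)), c(2L, 3L, 1L))
  expect_equal(rank_patches(rep(0.4, 5)), 1:5)
  v <- patchattr:::with_seed(1, runif(50))
  expect_equal(rank_patches(v), order(v, decreasing = TRUE))
  expect_error(rank_patches(c(1, NA, 2)), "NA")
})

test_that("the linear count game traces the hand-computed insertion ramp", {
  cnt <- count_adapter(4, scale = 0.25)
  img <- patched_image(array(0.9, c(8, 8, 3)), 4)
  cur <- insertion_curve(cnt, img, 2, 1:4)
  expect_equal(cur$points$probability, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(cur$auc, 0.5, tolerance = 1e-12)
})

test_that("indicator-game insertion/deletion AUCs match hand trapezoids", {
  ind <- indicator_adapter(key = 1, level = 0.25)
  img <- patched_image(array(0.9, c(8, 8, 3)), 4)
  first <- c(1, 2, 3, 4); last <- c(2, 3, 4, 1)
  ins_first <- insertion_curve(ind, img, 2, first)
  expect_equal(ins_first$points$probability, c(0, rep(0.25, 4)))
  expect_equal(ins_first$auc, 0.21875, tolerance = 1e-12)
  expect_equal(insertion_curve(ind, img, 2, last)$auc, 0.03125,
               tolerance = 1e-12)
  del_first <- deletion_curve(ind, img, 2, first)
  expect_equal(del_first$points$probability, c(0.25, rep(0, 4)))
  expect_equal(del_first$auc, 0.03125, tolerance = 1e-12)
})

test_that("a constant classifier yields flat curves with AUC = the constant", {
  img <- block_image(rep(0.5, 4))
  cur <- deletion_curve(constant_adapter(0.3), img, 2, 1:4)
  expect_equal(cur$auc, 0.3, tolerance = 1e-12)
  rb <- random_baseline(constant_adapter(0.3), img, 2, n_repeats = 5, seed = 1)
  expect_equal(rb$insertion_auc, 0.3, tolerance = 1e-12)
  expect_equal(rb$deletion_auc, 0.3, tolerance = 1e-12)
})

test_that("curve endpoints agree bitwise between insertion and deletion", {
  img <- random_image(d = 4, seed = 8)
  lin <- make_linear_patch_scorer(c(1, -0.4, 0.6, 0.2), "sigmoid")
  r <- rank_patches(c(0.5, 0.1, 0.9, 0.3))
  ins <- insertion_curve(lin, img, 2, r)$points$probability
  del <- deletion_curve(lin, img, 2, r)$points$probability
  expect_identical(ins[1], del[5])  # fully masked
  expect_identical(ins[5], del[1])  # full image
})

test_that("deletion under a ranking mirrors insertion with reversed points", {
  # for a set-function classifier, deleting the top-p patches leaves the
  # same present-set as inserting the bottom d-p patches
  ind <- indicator_adapter(key = 2, level = 0.25)
  img <- patched_image(array(0.9, c(8, 8, 3)), 4)
  r <- c(3, 2, 4, 1)
  del <- deletion_curve(ind, img, 2, r)$points$probability
  ins <- insertion_curve(ind, img, 2, rev(r))$points$probability
  expect_equal(del, rev(ins), tolerance = 1e-12)
})

test_that("the ground-truth ranking dominates 200 random rankings", {
  w <- patchattr:::with_seed(21, runif(8, 0.2, 2))
  lin <- make_linear_patch_scorer(w, "sigmoid")
  img <- block_image(rep(0.8, 8), cols = 4)
  gt <- order(w, decreasing = TRUE)
  gt_ins <- insertion_curve(lin, img, 2, gt)$auc
  gt_del <- deletion_curve(lin, img, 2, gt)$auc
  rankings <- patchattr:::with_seed(22, {
    lapply(1:200, function(i) sample.int(8))
  })
  for (r in rankings) {
    if (identical(as.integer(r), as.integer(gt))) next
    expect_gt(gt_ins, insertion_curve(lin, img, 2, r)$auc)
    expect_lt(gt_del, deletion_curve(lin, img, 2, r)$auc)
  }
})

test_that("random-baseline symmetry holds for an additive symmetric game", {
  lin <- make_linear_patch_scorer(rep(0.25, 4), "identity")
  img <- block_image(rep(0.8, 4))
  rb <- random_baseline(lin, img, 2, n_repeats = 200, seed = 30)
  se <- stats::sd(c(rb$insertion, rb$deletion)) / sqrt(200)
  expect_lt(abs(rb$insertion_auc - rb$deletion_auc), 3 * se + 1e-12)
})

test_that("random baseline for the indicator game averages the step curves", {
  # with the key patch uniform over positions 1..4, the mean insertion AUC
  # is the average of the four single-step trapezoids
  ind <- indicator_adapter(key = 1, level = 0.25)
  img <- patched_image(array(0.9, c(8, 8, 3)), 4)
  pos_auc <- vapply(1:4, function(pos) {
    r <- append(c(2L, 3L, 4L), 1L, after = pos - 1L)
    insertion_curve(ind, img, 2, r)$auc
  }, numeric(1))
  rb <- random_baseline(ind, img, 2, n_repeats = 400, seed = 31)
  se <- stats::sd(rb$insertion) / sqrt(400)
  expect_lt(abs(rb$insertion_auc - mean(pos_auc)), 3 * se)
})

test_that("aggregation modes weight slides as specified", {
  aucs <- data.frame(slide_id = c("A", "A", "B"), auc = c(0.2, 0.4, 0.9))
  expect_equal(aggregate_auc(aucs, "per_patch"), 0.5)
  expect_equal(aggregate_auc(aucs, "per_slide"), 0.6)  # mean(mean(A), mean(B))
  one <- data.frame(slide_id = "A", auc = c(0.3, 0.5))
  expect_equal(aggregate_auc(one, "per_patch"), aggregate_auc(one, "per_slide"))
  balanced <- data.frame(slide_id = c("A", "A", "B", "B"),
                         auc = c(0.1, 0.3, 0.6, 0.8))
  expect_equal(aggregate_auc(balanced, "per_patch"),
               aggregate_auc(balanced, "per_slide"))
  expect_error(aggregate_auc(balanced[0, ]), "no AUCs")
})

test_that("Welch matrix matches the textbook computation and is symmetric", {
  x <- patchattr:::with_seed(40, rnorm(12, mean = 0.5, sd = 0.1))
  y <- patchattr:::with_seed(41, rnorm(20, mean = 0.62, sd = 0.2))
  M <- welch_t_matrix(list(a = x, b = y))
  # independent computation: Welch statistic + Welch-Satterthwaite df
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  p_hand <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(M["a", "b"], p_hand, tolerance = 1e-6)
  expect_identical(M["a", "b"], M["b", "a"])
  expect_true(is.na(M["a", "a"]))

  ident <- welch_t_matrix(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident["a", "b"], 1)
  degenerate <- welch_t_matrix(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(degenerate["a", "b"], 1)
})
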