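# Insertion/Deletion faithfulness metrics: starting from the fully masked
# (resp. full) image, patches are revealed (resp. removed) in the order given
# by the attribution ranking, the class probability is recorded at every
# step, and the area under the resulting curve is the score.  Insertion:
# higher is better; Deletion: lower is better.

#' Rank patches by attribution score
#'
#' Descending score order; ties broken by ascending patch index, so the
#' ranking is deterministic.
#'
#' @param map An [attribution_map()] or a numeric vector.
#' @return Integer permutation of `1..d` (most important patch first).
#' @export
rank_patches <- function(map) {
  scores <- if (inherits(map, "attribution_map")) map$scores else as.numeric(map)
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  order(-scores, seq_along(scores))
}

curve_from_probs <- function(probs, d) {
  auc <- sum((probs[-1] + probs[-(d + 1)]) / 2) / d   # trapezoid over #p/d
  structure(list(points = data.frame(n_patches = 0:d, probability = probs),
                 auc = auc),
            class = "attribution_curve")
}

check_ranking <- function(ranking, d) {
  if (length(ranking) != d || !setequal(ranking, seq_len(d))) {
    stop("`ranking` must be a permutation of 1..d", call. = FALSE)
  }
  as.integer(ranking)
}

#' Insertion curve and AUC
#'
#' Point `#p` is the class probability on the image with the top-`#p` ranked
#' patches present and all others filled; point 0 is the fully masked image,
#' point `d` the full image.  AUC by the trapezoid rule over the revealed
#' patch fraction `#p / d` in `[0, 1]`.
#'
#' @param adapter A [classifier_adapter()].
#' @param image A [patched_image()].
#' @param class_index Target class.
#' @param ranking Permutation of `1..d` from [rank_patches()].
#' @param fill Fill value for absent patches.
#' @return An `attribution_curve`: list with `points` (data.frame) and `auc`.
#' @export
insertion_curve <- function(adapter, image, class_index, ranking, fill = 0) {
  d <- image$d
  ranking <- check_ranking(ranking, d)
  masks <- matrix(0, d + 1, d)
  for (p in seq_len(d)) masks[p + 1, ranking[seq_len(p)]] <- 1
  probs <- masked_predict_batch(adapter, image, masks, fill)[, class_index]
  curve_from_probs(probs, d)
}

#' Deletion curve and AUC
#'
#' Point `#p` is the class probability with the top-`#p` ranked patches
#' filled and all others present; point 0 is the full image, point `d` the
#' fully masked image.  Lower AUC is better.
#'
#' @inheritParams insertion_curve
#' @return An `attribution_curve`.
#' @export
deletion_curve <- function(adapter, image, class_index, ranking, fill = 0) {
  d <- image$d
  ranking <- check_ranking(ranking, d)
  masks <- matrix(1, d + 1, d)
  for (p in seq_len(d)) masks[p + 1, ranking[seq_len(p)]] <- 0
  probs <- masked_predict_batch(adapter, image, masks, fill)[, class_index]
  curve_from_probs(probs, d)
}

#' Random-ranking baseline
#'
#' Mean insertion and deletion AUC over uniformly random patch rankings; the
#' floor every attribution method must beat.
#'
#' @inheritParams insertion_curve
#' @param n_repeats Number of random rankings.
#' @param seed Integer seed.
#' @return List with `insertion_auc`, `deletion_auc` (means), and the
#'   per-repeat vectors `insertion`, `deletion`.
#' @export
random_baseline <- function(adapter, image, class_index, n_repeats = 20,
                            seed = 1, fill = 0) {
  stopifnot(n_repeats >= 1)
  rankings <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(i) sample.int(image$d))
  })
  ins <- vapply(rankings, function(r) {
    insertion_curve(adapter, image, class_index, r, fill)$auc
  }, numeric(1))
  del <- vapply(rankings, function(r) {
    deletion_curve(adapter, image, class_index, r, fill)$auc
  }, numeric(1))
  list(insertion_auc = mean(ins), deletion_auc = mean(del),
       insertion = ins, deletion = del)
}

#' Aggregate per-patch AUCs
#'
#' `per_patch`: grand mean over all patch AUCs.  `per_slide`: mean of
#' per-slide means, weighting each slide equally regardless of how many
#' patches it contributed (slides with many patches do not dominate).
#'
#' @param aucs Data frame with columns `slide_id` and `auc`.
#' @param mode `"per_patch"` or `"per_slide"`.
#' @return Scalar mean.
#' @export
aggregate_auc <- function(aucs, mode = c("per_patch", "per_slide")) {
  mode <- match.arg(mode)
  if (nrow(aucs) == 0) stop("no AUCs to aggregate", call. = FALSE)
  if (mode == "per_patch") {
    mean(aucs$auc)
  } else {
    mean(tapply(aucs$auc, aucs$slide_id, mean))
  }
}

#' Pairwise Welch t-test matrix
#'
#' Two-sided unequal-variance t-tests (Welch-Satterthwaite degrees of
#' freedom) between every pair of method populations.  No multiplicity
#' correction; diagonal is `NA`.  Degenerate pairs with zero variance in
#' both samples get `p = 1` when the means are equal and `p = 0` otherwise.
#'
#' @param populations Named list of numeric vectors (one per method), each of
#'   length `>= 2`.
#' @return Symmetric matrix of p-values with method names on both margins.
#' @export
welch_t_matrix <- function(populations) {
  stopifnot(length(populations) >= 2, !is.null(names(populations)))
  k <- length(populations)
  out <- matrix(NA_real_, k, k, dimnames = list(names(populations),
                                                names(populations)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- populations[[i]]; y <- populations[[j]]
      if (length(x) < 2 || length(y) < 2) {
        stop("each population needs at least 2 observations", call. = FALSE)
      }
      p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      } else {
        stats::t.test(x, y, var.equal = FALSE)$p.value
      }
      out[i, j] <- out[j, i] <- p
    }
  }
  out
}
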