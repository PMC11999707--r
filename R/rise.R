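# RISE: the importance of patch i is the conditional expectation
# E[f_y(x (*) M) | M_i = 1] of the class score under random patch masking,
# estimated by Monte Carlo as  sum_m f_y(x (*) m) m_i / sum_m m_i.
# Masks are patch-aligned binary vectors at token resolution; two mask laws
# are supported, independent Bernoulli(p) entries ("binomial") and a
# cardinality drawn uniformly on {0..d} followed by a uniform subset of that
# size ("uniform_cardinality").

#' Sample a batch of binary patch masks
#'
#' @param n Number of masks.
#' @param d Number of patches.
#' @param scheme `"binomial"` (i.i.d. Bernoulli(`p`) entries),
#'   `"uniform_cardinality"` (cardinality uniform on `0..d`, then a uniform
#'   subset of that cardinality) or `"shapley"` (the Shapley kernel law
#'   `psh`: cardinality `k` with probability proportional to `1/(k (d - k))`
#'   on `1..d-1`, then a uniform subset).
#' @param seed Integer seed; same seed, same batch.
#' @param p Inclusion probability for the binomial scheme.
#' @return A `mask_batch`: list with `masks` (`n x d` 0/1 matrix), `scheme`,
#'   `p`, `seed`.
#' @export
sample_masks <- function(n, d, scheme = c("binomial", "uniform_cardinality",
                                          "shapley"),
                         seed = 1, p = 0.5) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 1, d >= 1)
  if (scheme == "binomial" && (p <= 0 || p >= 1)) {
    stop("`p` must lie in (0, 1)", call. = FALSE)
  }
  masks <- with_seed(seed, {
    if (scheme == "binomial") {
      matrix(stats::rbinom(n * d, 1, p), nrow = n, ncol = d)
    } else {
      ks <- if (scheme == "uniform_cardinality") {
        sample(0:d, n, replace = TRUE)
      } else {
        if (d < 2) stop("shapley scheme needs d >= 2", call. = FALSE)
        kk <- 1:(d - 1)
        sample(kk, n, replace = TRUE, prob = 1 / (kk * (d - kk)))
      }
      m <- matrix(0L, nrow = n, ncol = d)
      for (j in seq_len(n)) {
        if (ks[j] > 0) m[j, sample.int(d, ks[j])] <- 1L
      }
      m
    }
  })
  storage.mode(masks) <- "numeric"
  structure(list(masks = masks, scheme = scheme,
                 p = if (scheme == "binomial") p else NA_real_, seed = seed),
            class = "mask_batch")
}

#' RISE configuration
#'
#' @param n_masks Monte-Carlo budget (masks per image).
#' @param scheme Mask law, `"binomial"` or `"uniform_cardinality"`.
#' @param p Bernoulli inclusion probability (binomial scheme).
#' @param masks_per_chunk Model-evaluation chunk size (throughput knob only:
#'   results are identical for any chunking of a fixed mask batch).
#' @param fill Fill value for masked patches.
#' @return A `rise_config` object.
#' @export
rise_config <- function(n_masks = 4000,
                        scheme = c("binomial", "uniform_cardinality"),
                        p = 0.5, masks_per_chunk = 512, fill = 0) {
  stopifnot(n_masks >= 1, masks_per_chunk >= 1)
  structure(list(n_masks = as.integer(n_masks), scheme = match.arg(scheme),
                 p = p, masks_per_chunk = as.integer(masks_per_chunk),
                 fill = fill),
            class = "rise_config")
}

# Per-patch conditional means over an explicit mask batch, plus the
# Monte-Carlo standard error of each conditional mean.
rise_from_masks <- function(adapter, image, class_index, masks, fill = 0,
                            masks_per_chunk = nrow(masks),
                            never_included = c("error", "zero")) {
  never_included <- match.arg(never_included)
  n <- nrow(masks)
  f <- numeric(n)
  for (start in seq(1, n, by = masks_per_chunk)) {
    idx <- start:min(start + masks_per_chunk - 1, n)
    f[idx] <- masked_predict_batch(adapter, image, masks[idx, , drop = FALSE],
                                   fill)[, class_index]
  }
  counts <- colSums(masks)
  if (any(counts == 0)) {
    if (never_included == "error") {
      stop("patch(es) ", paste(which(counts == 0), collapse = ", "),
           " never included in any mask; increase n_masks", call. = FALSE)
    }
    warning("patch(es) never included; scoring them 0", call. = FALSE)
  }
  scores <- se <- numeric(ncol(masks))
  for (i in seq_len(ncol(masks))) {
    if (counts[i] == 0) next
    fi <- f[masks[, i] == 1]
    scores[i] <- mean(fi)
    se[i] <- stats::sd(fi) / sqrt(length(fi))
  }
  list(scores = scores, se = se, n_evals = n)
}

#' RISE attribution by Monte-Carlo masking
#'
#' @param adapter A [classifier_adapter()].
#' @param image A [patched_image()].
#' @param class_index Target class.
#' @param config A [rise_config()].
#' @param seed Seed for the mask batch.
#' @param masks Optional pre-sampled [sample_masks()] batch overriding
#'   `config$n_masks`/`scheme`/`seed`.
#' @return An [attribution_map()]; Monte-Carlo standard errors of the
#'   per-patch conditional means are attached in `meta$se`.
#' @export
rise_attribution <- function(adapter, image, class_index,
                             config = rise_config(), seed = 1, masks = NULL) {
  if (is.null(masks)) {
    masks <- sample_masks(config$n_masks, image$d, config$scheme, seed,
                          config$p)
  }
  est <- rise_from_masks(adapter, image, class_index, masks$masks,
                         fill = config$fill,
                         masks_per_chunk = config$masks_per_chunk)
  attribution_map(est$scores,
                  method = paste0("rise-", if (masks$scheme == "binomial")
                    "binomial" else "uniform"),
                  meta = list(class_index = class_index, se = est$se,
                              n_masks = nrow(masks$masks),
                              scheme = masks$scheme))
}

# Exact mask-law probabilities over an enumerated mask matrix.
mask_law_probs <- function(masks, scheme, p = 0.5) {
  d <- ncol(masks)
  k <- rowSums(masks)
  switch(scheme,
    binomial = p^k * (1 - p)^(d - k),
    uniform_cardinality = 1 / ((d + 1) * choose(d, k)),
    stop("unknown scheme", call. = FALSE))
}

#' Exact RISE scores by exhaustive mask enumeration
#'
#' Computes `E[f_y(x (*) M) | M_i = 1]` exactly under the scheme's mask law
#' by summing over all `2^d` masks; the brute-force oracle the Monte-Carlo
#' estimator is tested against.
#'
#' @inheritParams rise_attribution
#' @param scheme `"binomial"` or `"uniform_cardinality"`.
#' @param p Bernoulli inclusion probability (binomial scheme).
#' @param fill Fill value for masked patches.
#' @param guard Enumeration guard on `d`.
#' @return An [attribution_map()].
#' @export
exact_rise <- function(adapter, image, class_index,
                       scheme = c("binomial", "uniform_cardinality"),
                       p = 0.5, fill = 0, guard = 14L) {
  scheme <- match.arg(scheme)
  masks <- enumerate_masks(image$d, guard)
  pm <- mask_law_probs(masks, scheme, p)
  f <- masked_predict_batch(adapter, image, masks, fill)[, class_index]
  scores <- vapply(seq_len(image$d), function(i) {
    inc <- masks[, i] == 1
    sum(f[inc] * pm[inc]) / sum(pm[inc])
  }, numeric(1))
  attribution_map(scores, method = paste0("exact-rise-", scheme),
                  meta = list(class_index = class_index, p = p))
}
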