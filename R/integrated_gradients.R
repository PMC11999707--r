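# Integrated Gradients: the path integral of the class-score gradient along
# the straight line gamma(t) = x' + t (x - x') from a baseline image x'
# (default: the black image) to the input, approximated by a Riemann sum.
# The per-pixel attribution (x - x') * mean-of-gradients is summed over the
# pixels and channels of each patch to give the per-patch map.

#' Integrated Gradients configuration
#'
#' @param steps Riemann steps `n >= 1`.  The default 64 trades accuracy for
#'   speed; the completeness gap shrinks as `n` grows.
#' @param rule `"midpoint"` (default; second-order accurate) or `"left"`
#'   (the textbook left Riemann sum).
#' @param baseline `NULL` for the black image, or a [patched_image()] of the
#'   same shape.
#' @param target Gradient target, `"logit"` (default) or `"probability"`.
#' @return An `ig_config` object.
#' @export
ig_config <- function(steps = 64, rule = c("midpoint", "left"),
                      baseline = NULL, target = c("logit", "probability")) {
  steps <- as.integer(steps)
  if (steps < 1L) stop("`steps` must be >= 1", call. = FALSE)
  structure(list(steps = steps, rule = match.arg(rule), baseline = baseline,
                 target = match.arg(target)),
            class = "ig_config")
}

#' Integrated Gradients attribution
#'
#' @param adapter A [classifier_adapter()] supporting gradients.
#' @param image A [patched_image()].
#' @param class_index Target class.
#' @param config An [ig_config()].
#' @return A list with `pixel_map` (`H x W x 3` signed attributions), `map`
#'   (an [attribution_map()] of per-patch sums) and `config`.
#' @export
integrated_gradients <- function(adapter, image, class_index,
                                 config = ig_config()) {
  require_capability(adapter, "gradients")
  x <- image$pixels
  xb <- if (is.null(config$baseline)) array(0, dim(x)) else config$baseline$pixels
  stopifnot(all(dim(xb) == dim(x)))
  n <- config$steps
  ts <- if (config$rule == "midpoint") (seq_len(n) - 0.5) / n else (seq_len(n) - 1) / n
  g_acc <- array(0, dim(x))
  for (t in ts) {
    xt <- patched_image(xb + t * (x - xb), image$patch_size)
    g_acc <- g_acc + input_gradient(adapter, xt, class_index, config$target)
  }
  pixel_map <- (x - xb) * g_acc / n
  scores <- vapply(seq_len(image$d), function(i) {
    ext <- patch_extent(image, i)
    sum(pixel_map[ext$rows, ext$cols, ])
  }, numeric(1))
  list(pixel_map = pixel_map,
       map = attribution_map(scores, method = "ig",
                             meta = list(class_index = class_index,
                                         steps = n, rule = config$rule)),
       config = config)
}

#' Completeness gap of an attribution
#'
#' `|sum_i score_i - (f(x) - f(x'))|`: zero in the exact path-integral limit
#' (and for any step count on linear models), so the gap diagnoses the
#' quality of the Riemann approximation.
#'
#' @param patch_scores Numeric vector of per-patch attributions.
#' @param f_x Class score at the input.
#' @param f_baseline Class score at the baseline.
#' @return Non-negative scalar.
#' @export
completeness_gap <- function(patch_scores, f_x, f_baseline) {
  abs(sum(patch_scores) - (f_x - f_baseline))
}

# Class score consistent with the gradient target, used by the completeness
# diagnostics: the adapter's logit when available/requested, else probability.
class_score <- function(adapter, image, class_index, target = "logit") {
  if (target == "logit" && !is.null(adapter$logit_fn)) {
    adapter$logit_fn(image)[class_index]
  } else {
    predict_probs(adapter, image)[class_index]
  }
}
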