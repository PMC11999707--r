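#' Classifier adapter
#'
#' The contract every attribution method consumes.  An adapter wraps a
#' classifier `f` as a set of closures so that methods never touch model
#' internals:
#'
#' * `predict_fn(image)` — class-probability vector of length `n_classes`,
#'   non-negative, summing to 1 (within 1e-6);
#' * `logit_fn(image)` — pre-softmax scores (optional; used as the gradient
#'   target for path-integral methods, where probability gradients saturate);
#' * `gradient_fn(image, class_index, target)` — gradient of the class score
#'   with respect to input pixels, a `H x W x 3` array (optional);
#' * `attention_fn(image)` — head-averaged per-layer attention matrices
#'   (optional, transformers only);
#' * `masked_batch_fn(image, masks, fill)` — vectorized evaluation of
#'   `f(x (*) m)` over a batch of masks, returning an `n_masks x n_classes`
#'   matrix (optional fast path; must agree with looped [masked_predict()]).
#'
#' @param name Adapter name (used in reports).
#' @param n_classes Number of classes `C >= 2`.
#' @param predict_fn,logit_fn,gradient_fn,attention_fn,masked_batch_fn See above.
#' @return An object of class `classifier_adapter`.
#' @export
classifier_adapter <- function(name, n_classes, predict_fn, logit_fn = NULL,
                               gradient_fn = NULL, attention_fn = NULL,
                               masked_batch_fn = NULL) {
  stopifnot(is.function(predict_fn), n_classes >= 2)
  structure(
    list(name = name, n_classes = as.integer(n_classes),
         predict_fn = predict_fn, logit_fn = logit_fn,
         gradient_fn = gradient_fn, attention_fn = attention_fn,
         masked_batch_fn = masked_batch_fn,
         capabilities = c("probabilities",
                          if (!is.null(gradient_fn)) "gradients",
                          if (!is.null(attention_fn)) "attentions")),
    class = "classifier_adapter"
  )
}

#' @export
print.classifier_adapter <- function(x, ...) {
  cat(sprintf("<classifier_adapter> %s: %d classes, capabilities: %s\n",
              x$name, x$n_classes, paste(x$capabilities, collapse = ", ")))
  invisible(x)
}

#' Does an adapter support a capability?
#' @param adapter A [classifier_adapter()].
#' @param capability One of `"probabilities"`, `"gradients"`, `"attentions"`.
#' @return Logical.
#' @export
has_capability <- function(adapter, capability) {
  capability %in% adapter$capabilities
}

require_capability <- function(adapter, capability) {
  if (!has_capability(adapter, capability)) {
    stop("adapter '", adapter$name, "' does not support capability '",
         capability, "'", call. = FALSE)
  }
}

#' Class probabilities for one image or a batch
#'
#' @param adapter A [classifier_adapter()].
#' @param images A [patched_image()] or a list of them (all the same shape).
#' @return A probability vector, or a matrix with one row per image.
#' @export
predict_probs <- function(adapter, images) {
  require_capability(adapter, "probabilities")
  single <- inherits(images, "patched_image")
  if (single) images <- list(images)
  dims <- vapply(images, function(im) dim(im$pixels), integer(3))
  if (length(images) > 1 && any(apply(dims, 1, function(x) length(unique(x))) != 1)) {
    stop("images in a batch must share a common shape", call. = FALSE)
  }
  out <- t(vapply(images, function(im) {
    p <- adapter$predict_fn(im)
    check_probs(p, adapter$n_classes)
    p
  }, numeric(adapter$n_classes)))
  if (single) out[1, ] else out
}

check_probs <- function(p, n_classes, tol = 1e-6) {
  if (length(p) != n_classes || anyNA(p)) {
    stop("prediction must be a length-", n_classes, " probability vector",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop("class probabilities sum to ", format(sum(p)), ", not 1", call. = FALSE)
  }
  invisible(p)
}

#' Prediction on a patch-masked image
#'
#' Evaluates `f(x (*) m)`: every patch with `mask == 0` is replaced by `fill`
#' before prediction.  The all-ones mask reproduces [predict_probs()]
#' bit-identically.
#'
#' @inheritParams predict_probs
#' @param image A [patched_image()].
#' @param mask Binary vector of length `d`.
#' @param fill Fill value in `[0, 1]` (default 0: a fully masked image is the
#'   black image, the baseline of the removal game).
#' @return Class-probability vector.
#' @export
masked_predict <- function(adapter, image, mask, fill = 0) {
  predict_probs(adapter, apply_mask(image, mask, fill))
}

# n_masks x n_classes probability matrix over a mask batch; uses the adapter's
# vectorized path when available, else a plain loop.  The two paths must agree.
masked_predict_batch <- function(adapter, image, masks, fill = 0) {
  if (!is.matrix(masks)) masks <- matrix(masks, nrow = 1)
  if (!is.null(adapter$masked_batch_fn)) {
    out <- adapter$masked_batch_fn(image, masks, fill)
  } else {
    out <- t(apply(masks, 1, function(m) masked_predict(adapter, image, m, fill)))
  }
  matrix(out, nrow = nrow(masks), ncol = adapter$n_classes)
}

#' Attention stack of a transformer adapter
#'
#' One head-averaged, row-stochastic `(d + 1) x (d + 1)` attention matrix per
#' layer.  The class token sits at index 1 (R convention); attribution maps
#' never include it.
#'
#' @inheritParams masked_predict
#' @return An `attention_stack`: a list of matrices with attribute `cls_index`.
#' @export
attention_maps <- function(adapter, image) {
  require_capability(adapter, "attentions")
  stack <- adapter$attention_fn(image)
  validate_attention_stack(stack)
}

validate_attention_stack <- function(stack, tol = 1e-5) {
  stopifnot(is.list(stack), length(stack) >= 1)
  n_tok <- nrow(stack[[1]])
  for (l in seq_along(stack)) {
    A <- stack[[l]]
    if (!is.matrix(A) || nrow(A) != n_tok || ncol(A) != n_tok) {
      stop("attention matrices must be square and share one token count",
           call. = FALSE)
    }
    if (any(A < -tol)) stop("attention entries must be non-negative", call. = FALSE)
    if (any(abs(rowSums(A) - 1) > tol)) {
      stop("attention rows must sum to 1 (layer ", l, ")", call. = FALSE)
    }
  }
  structure(stack, cls_index = 1L, class = "attention_stack")
}

#' Input-pixel gradient of a class score
#'
#' @inheritParams masked_predict
#' @param class_index Target class in `1..n_classes`.
#' @param target `"logit"` (default; pre-softmax score, the recommended
#'   integration target since probability gradients vanish under softmax
#'   saturation) or `"probability"`.
#' @return `H x W x 3` gradient array.
#' @export
input_gradient <- function(adapter, image, class_index, target = c("logit", "probability")) {
  require_capability(adapter, "gradients")
  target <- match.arg(target)
  if (class_index < 1 || class_index > adapter$n_classes) {
    stop("class_index out of range", call. = FALSE)
  }
  g <- adapter$gradient_fn(image, class_index, target)
  stopifnot(all(dim(g) == dim(image$pixels)))
  g
}
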