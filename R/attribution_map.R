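#' Attribution map
#'
#' One real importance score per patch, with method provenance.  Maps are
#' argsorted into a patch ranking by [rank_patches()] for the
#' insertion/deletion metrics.
#'
#' @param scores Finite numeric vector, one score per patch.
#' @param method Name of the producing method.
#' @param meta Optional named list of provenance (image id, class index, ...).
#' @return An object of class `attribution_map`.
#' @export
attribution_map <- function(scores, method = "unknown", meta = list()) {
  scores <- as.numeric(scores)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("attribution scores must be finite", call. = FALSE)
  }
  structure(list(scores = scores, method = method, d = length(scores),
                 meta = meta),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %s, d = %d\n", x$method, x$d))
  print(utils::head(x$scores, 10))
  invisible(x)
}
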