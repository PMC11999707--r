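# End-to-end benchmark: run every registered attribution method over a set
# of patch images, score each map with the Insertion/Deletion metrics,
# aggregate per patch and per slide, compare methods with Welch t-tests and
# (optionally) write CSV/JSON artifacts and heatmap overlays.

#' Names of the registered attribution methods
#' @return Character vector.
#' @export
attribution_methods <- function() {
  c("rollout", "rollout-res", "ig", "rise-binomial", "rise-uniform",
    "shapley-exact", "shapley-regression", "random")
}

#' Compute one attribution map by method name
#'
#' Dispatches to the method implementations with per-method options; the
#' entry point the CLI and the benchmark loop share.
#'
#' @param method One of [attribution_methods()].
#' @param adapter A [classifier_adapter()].
#' @param image A [patched_image()].
#' @param class_index Target class.
#' @param seed Seed for stochastic methods.
#' @param options Named list of per-method options (`ig_steps`,
#'   `rise_n_masks`, `rise_p`, `masks_per_chunk`, `shapley_n_masks`,
#'   `enumeration_guard`, `fill`).
#' @return An [attribution_map()].
#' @export
compute_attribution <- function(method, adapter, image, class_index,
                                seed = 1, options = list()) {
  opt <- function(name, default) if (!is.null(options[[name]])) options[[name]] else default
  fill <- opt("fill", 0)
  switch(method,
    "rollout" = rollout_attribution(attention_maps(adapter, image),
                                    rollout_config(residual = FALSE)),
    "rollout-res" = rollout_attribution(attention_maps(adapter, image),
                                        rollout_config(residual = TRUE)),
    "ig" = integrated_gradients(adapter, image, class_index,
                                ig_config(steps = opt("ig_steps", 64)))$map,
    "rise-binomial" = rise_attribution(adapter, image, class_index,
      rise_config(n_masks = opt("rise_n_masks", 4000), scheme = "binomial",
                  p = opt("rise_p", 0.5),
                  masks_per_chunk = opt("masks_per_chunk", 512), fill = fill),
      seed = seed),
    "rise-uniform" = rise_attribution(adapter, image, class_index,
      rise_config(n_masks = opt("rise_n_masks", 4000),
                  scheme = "uniform_cardinality",
                  masks_per_chunk = opt("masks_per_chunk", 512), fill = fill),
      seed = seed),
    "shapley-exact" = {
      res <- exact_shapley(make_image_game(adapter, image, class_index, fill),
                           guard = opt("enumeration_guard", 14L))
      attribution_map(res$phi, "shapley-exact",
                      meta = list(class_index = class_index))
    },
    "shapley-regression" = {
      game <- make_image_game(adapter, image, class_index, fill)
      masks <- sample_masks(opt("shapley_n_masks", 2000), image$d,
                            scheme = "shapley", seed = seed)
      res <- regression_shapley(game, masks)
      attribution_map(res$phi, "shapley-regression",
                      meta = list(class_index = class_index))
    },
    "random" = with_seed(seed, {
      attribution_map(stats::runif(image$d), "random")
    }),
    stop("unknown attribution method '", method, "'", call. = FALSE)
  )
}

#' Benchmark run configuration
#'
#' @param slides Input slides: a list of [synthetic_slide_spec()] objects
#'   (generated at run time), or a list of lists with fields `slide_id` and
#'   `images` (pre-built [patched_image()]s).
#' @param model A [classifier_adapter()], or a model spec list with a `type`
#'   field (`"linear"`, `"tiny_vit"`, `"color_attentive"`) and its
#'   parameters, resolved by [model_from_spec()].
#' @param methods Subset of [attribution_methods()].
#' @param metrics Subset of `c("insertion", "deletion")`.
#' @param class_index Target class for attribution and metrics.
#' @param n_random_repeats Repeats for the random-ranking baseline entry.
#' @param seed Master seed; every stochastic step derives its own seed from it.
#' @param fill Mask fill value.
#' @param options Per-method options (see [compute_attribution()]).
#' @param output_dir Directory for CSV/JSON/heatmap artifacts, or `NULL`.
#' @param render Write heatmap overlay PNGs (requires `output_dir`).
#' @return A `run_config` object.
#' @export
run_config <- function(slides, model, methods = c("shapley-exact", "random"),
                       metrics = c("insertion", "deletion"), class_index = 2,
                       n_random_repeats = 20, seed = 1, fill = 0,
                       options = list(), output_dir = NULL, render = FALSE) {
  stopifnot(length(methods) >= 1, length(metrics) >= 1)
  bad <- setdiff(methods, attribution_methods())
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stopifnot(all(metrics %in% c("insertion", "deletion")))
  structure(list(slides = slides, model = model, methods = methods,
                 metrics = metrics, class_index = class_index,
                 n_random_repeats = n_random_repeats, seed = as.integer(seed),
                 fill = fill, options = options, output_dir = output_dir,
                 render = render),
            class = "run_config")
}

#' Build a classifier adapter from a declarative spec
#'
#' @param spec A [classifier_adapter()] (returned as is) or a named list:
#'   `type = "linear"` (`weights`, `link`), `type = "tiny_vit"` (`layers`,
#'   `heads`, `d`, `seed`, `patch_size`, ...), or `type = "color_attentive"`
#'   (`d`, `patch_size`, `tau`, `gain`).
#' @return A [classifier_adapter()].
#' @export
model_from_spec <- function(spec) {
  if (inherits(spec, "classifier_adapter")) return(spec)
  stopifnot(is.list(spec), !is.null(spec$type))
  args <- spec[setdiff(names(spec), "type")]
  switch(spec$type,
    linear = do.call(make_linear_patch_scorer, args),
    tiny_vit = do.call(make_tiny_vit, args),
    color_attentive = do.call(make_color_attentive_vit, args),
    stop("unknown model type '", spec$type, "'", call. = FALSE))
}

# Small deterministic per-cell seed derivation (kept below 2^31).
derive_seed <- function(master, ...) {
  parts <- c(...)
  s <- as.double(master)
  for (p in parts) s <- (s * 7919 + as.double(p) * 104729 + 1) %% 2147483629
  as.integer(s) + 1L
}

resolve_slides <- function(slides) {
  lapply(seq_along(slides), function(si) {
    sl <- slides[[si]]
    if (inherits(sl, "synthetic_slide_spec")) {
      gen <- generate_pseudo_slide(sl)
      list(slide_id = sprintf("synthetic_%02d", si), images = list(gen$image),
           ground_truth = list(gen$ground_truth))
    } else {
      stopifnot(!is.null(sl$images))
      if (is.null(sl$slide_id)) sl$slide_id <- sprintf("slide_%02d", si)
      sl
    }
  })
}

#' Run the attribution benchmark
#'
#' For every image and configured method, computes the attribution map, ranks
#' the patches and evaluates the configured metrics; aggregates AUCs per
#' patch and per slide; compares methods pairwise with Welch t-tests on the
#' per-patch AUC populations.  A method failing on an image (e.g. a missing
#' adapter capability) is recorded as a failed cell with its reason and the
#' run continues.  Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return A `benchmark_report`: list with `cells` (per image x method x
#'   metric data.frame: `slide_id`, `patch_id`, `method`, `metric`, `auc`,
#'   `status`, `reason`), `maps` (the attribution maps), `summary`
#'   (data.frame over method x metric x aggregation), `welch` (list of
#'   p-value matrices per metric), `provenance`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  adapter <- model_from_spec(config$model)
  slides <- resolve_slides(config$slides)
  cells <- list(); maps <- list(); score_rows <- list()
  for (si in seq_along(slides)) {
    sl <- slides[[si]]
    for (pi in seq_along(sl$images)) {
      image <- sl$images[[pi]]
      for (mi in seq_along(config$methods)) {
        method <- config$methods[mi]
        cell_seed <- derive_seed(config$seed, si, pi, mi)
        map <- tryCatch(
          compute_attribution(method, adapter, image, config$class_index,
                              seed = cell_seed, options = config$options),
          error = function(e) conditionMessage(e))
        if (is.character(map)) {
          for (metric in config$metrics) {
            cells[[length(cells) + 1L]] <- data.frame(
              slide_id = sl$slide_id, patch_id = pi - 1L, method = method,
              metric = metric, auc = NA_real_, status = "failed", reason = map)
          }
          next
        }
        key <- sprintf("%s/%d/%s", sl$slide_id, pi - 1L, method)
        maps[[key]] <- map
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          slide_id = sl$slide_id, patch_id = pi - 1L, method = method,
          patch = seq_len(image$d) - 1L, score = map$scores)
        ranking <- rank_patches(map)
        for (metric in config$metrics) {
          curve <- if (metric == "insertion") {
            insertion_curve(adapter, image, config$class_index, ranking,
                            config$fill)
          } else {
            deletion_curve(adapter, image, config$class_index, ranking,
                           config$fill)
          }
          cells[[length(cells) + 1L]] <- data.frame(
            slide_id = sl$slide_id, patch_id = pi - 1L, method = method,
            metric = metric, auc = curve$auc, status = "ok", reason = "")
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  scores <- if (length(score_rows)) do.call(rbind, score_rows) else NULL
  ok <- cells[cells$status == "ok", ]
  summary_rows <- list()
  for (method in unique(ok$method)) {
    for (metric in config$metrics) {
      sub <- ok[ok$method == method & ok$metric == metric, ]
      if (nrow(sub) == 0) next
      for (mode in c("per_patch", "per_slide")) {
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          method = method, metric = metric, aggregation = mode,
          mean_auc = aggregate_auc(sub, mode), n = nrow(sub))
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  welch <- list()
  for (metric in config$metrics) {
    pops <- lapply(split(ok[ok$metric == metric, ],
                         ok[ok$metric == metric, "method"]),
                   function(df) df$auc)
    pops <- pops[vapply(pops, length, integer(1)) >= 2]
    if (length(pops) >= 2) welch[[metric]] <- welch_t_matrix(pops)
  }
  report <- structure(
    list(cells = cells, scores = scores, maps = maps, summary = summary,
         welch = welch,
         provenance = list(seed = config$seed, methods = config$methods,
                           metrics = config$metrics, model = adapter$name,
                           n_slides = length(slides))),
    class = "benchmark_report")
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
    if (config$render) {
      for (si in seq_along(slides)) {
        sl <- slides[[si]]
        for (pi in seq_along(sl$images)) {
          for (method in config$methods) {
            key <- sprintf("%s/%d/%s", sl$slide_id, pi - 1L, method)
            if (is.null(maps[[key]])) next
            ov <- render_heatmap(sl$images[[pi]], maps[[key]])
            write_image(ov, file.path(config$output_dir,
                                      sprintf("heatmap_%s_%d_%s.png",
                                              sl$slide_id, pi - 1L, method)))
          }
        }
      }
    }
  }
  report
}

#' Write benchmark artifacts
#'
#' `metrics.csv` (one row per image x method x metric), `scores.csv` (raw,
#' unnormalized per-patch scores), `summary.json` (aggregated means and
#' Welch p-value matrices, plus provenance).
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cells, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(report$scores)) {
    utils::write.csv(report$scores, file.path(dir, "scores.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(summary = report$summary,
         welch = lapply(report$welch, function(m) {
           list(methods = rownames(m), p_values = unname(m))
         }),
         provenance = report$provenance),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Render an attribution heatmap overlay
#'
#' Scores are min-max normalized per image (a constant map sits at 0.5),
#' mapped through a diverging blue-to-red colormap at patch resolution and
#' alpha-blended over the image.  Affine transformations of the scores leave
#' the overlay unchanged.
#'
#' @param image A [patched_image()].
#' @param map An [attribution_map()] of matching length.
#' @param alpha Blend weight in `[0, 1]`; 0 returns the image unchanged.
#' @param colors Diverging palette endpoints/midpoint for
#'   [grDevices::colorRampPalette()].
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
render_heatmap <- function(image, map, alpha = 0.5,
                           colors = c("#2166AC", "#F7F7F7", "#B2182B")) {
  stopifnot(map$d == image$d, alpha >= 0, alpha <= 1)
  s <- map$scores
  rng <- range(s)
  z <- if (rng[1] == rng[2]) rep(0.5, length(s)) else (s - rng[1]) / diff(rng)
  pal <- grDevices::colorRampPalette(colors)(256)
  cols <- grDevices::col2rgb(pal[pmin(255, floor(z * 255)) + 1]) / 255
  overlay <- array(0, dim(image$pixels))
  for (i in seq_len(image$d)) {
    ext <- patch_extent(image, i)
    for (ch in 1:3) overlay[ext$rows, ext$cols, ch] <- cols[ch, i]
  }
  (1 - alpha) * image$pixels + alpha * overlay
}
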