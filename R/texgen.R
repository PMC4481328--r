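# Dataset assembly: parameter sets, single height maps, linear sweeps and
# multi-model datasets.

#' Construct a validated parameter set for a procedural model
#'
#' @param model_id Identifier of a registered model (see
#'   \code{\link{texture_models}}).
#' @param values Named numeric vector of parameter values; every declared
#'   parameter of the model must be present and lie within its closed range.
#' @param seed Non-negative integer seed for the sample's private RNG stream.
#' @return An object of class \code{"texspace_params"}.
#' @examples
#' param_set("perlin", c(frequency = 6), seed = 1)
#' @export
param_set <- function(model_id, values, seed = 0L) {
  m <- .get_model(model_id)
  values <- unlist(values)
  missing_p <- setdiff(names(m$params), names(values))
  if (length(missing_p)) {
    stop("missing parameter(s) for '", model_id, "': ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  for (p in names(m$params)) {
    rng <- m$params[[p]]
    v <- values[[p]]
    if (!is.finite(v) || v < rng[1] || v > rng[2]) {
      stop(sprintf("parameter '%s' = %g outside declared range [%g, %g] for model '%s'",
                   p, v, rng[1], rng[2], model_id), call. = FALSE)
    }
  }
  if (length(seed) != 1 || !is.finite(seed) || seed < 0) {
    stop("seed must be a single non-negative integer", call. = FALSE)
  }
  structure(list(model_id = model_id,
                 values = values[names(m$params)],
                 seed = as.integer(seed)),
            class = "texspace_params")
}

#' @export
print.texspace_params <- function(x, ...) {
  cat("<texspace_params> ", x$model_id, "  seed ", x$seed, "\n  ",
      paste(sprintf("%s = %g", names(x$values), x$values), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Generate one procedural height map
#'
#' Runs the registered generator for \code{params$model_id} under a private
#' RNG stream derived from \code{params$seed} and min-max normalizes the
#' result to \eqn{[0, 1]} (a degenerate constant field maps to all 0.5).
#' Generation is deterministic: the same \code{(params, size)} always yields
#' a bit-identical grid.
#'
#' @param params A \code{\link{param_set}} object.
#' @param size Pixels per side of the square grid (default 512, minimum 16).
#' @return An object of class \code{"texspace_heightmap"}: list with
#'   \code{heights} (size x size matrix in \eqn{[0,1]}), \code{size}, and
#'   \code{provenance} (the parameter set).
#' @examples
#' hm <- generate_height_map(param_set("perlin", c(frequency = 4), 1), size = 32)
#' range(hm$heights)
#' @export
generate_height_map <- function(params, size = 512L) {
  if (!inherits(params, "texspace_params")) {
    params <- do.call(param_set, params)
  }
  size <- as.integer(size)
  if (size < 16L) stop("size must be at least 16 pixels", call. = FALSE)
  m <- .get_model(params$model_id)
  if (!is.null(m$spacing_param) && params$values[[m$spacing_param]] >= size) {
    stop(sprintf("model '%s': %s (%g) must be smaller than the image size (%d)",
                 params$model_id, m$spacing_param,
                 params$values[[m$spacing_param]], size), call. = FALSE)
  }
  fn <- get(m$fn, envir = asNamespace("texspace"))
  raw <- .with_seed(params$seed, fn(size, params$values))
  if (!all(is.finite(raw))) {
    stop("generator produced non-finite values for model '", params$model_id,
         "'", call. = FALSE)
  }
  structure(list(heights = .minmax01(raw), size = size, provenance = params),
            class = "texspace_heightmap")
}

#' @export
print.texspace_heightmap <- function(x, ...) {
  cat("<texspace_heightmap> ", x$size, "x", x$size, " model '",
      x$provenance$model_id, "' seed ", x$provenance$seed, "\n", sep = "")
  invisible(x)
}

#' Linear parameter sweep for one model
#'
#' Produces \code{n} parameter sets in which every declared parameter is
#' swept jointly and linearly across its closed range: the i-th set takes the
#' i-th of \code{n} evenly spaced values (both endpoints included; a single
#' sample takes the midpoint). Per-sample seeds are derived deterministically
#' from \code{master_seed}, the model id and the sweep index via a
#' splitmix-style hash.
#'
#' @param model_id Registered model identifier.
#' @param n Number of samples (\eqn{\ge} 1).
#' @param master_seed Master seed for the seed fan-out.
#' @return List of \code{n} \code{\link{param_set}} objects, with a
#'   \code{"sweep_position"} attribute on each (normalized position in
#'   \eqn{[0,1]} along the sweep).
#' @examples
#' parameter_sweep("perlin", 3)
#' @export
parameter_sweep <- function(model_id, n, master_seed = 1L) {
  m <- .get_model(model_id)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1", call. = FALSE)
  pos <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
  lapply(seq_len(n), function(i) {
    vals <- vapply(m$params, function(rng) rng[1] + pos[i] * (rng[2] - rng[1]),
                   numeric(1))
    ps <- param_set(model_id, vals,
                    seed = .hash_seed(master_seed, model_id, i))
    attr(ps, "sweep_position") <- pos[i]
    ps
  })
}

#' Assemble a multi-model texture dataset
#'
#' Builds the dataset in registry order: for each requested model a linear
#' \code{\link{parameter_sweep}} of the requested count, in sweep order.
#' With the default configuration (\code{\link{default_model_counts}}) the
#' dataset has 450 samples across all 23 models. Set
#' \code{materialize = FALSE} to build the manifest (labels, parameter sets,
#' sweep positions) without computing the height-map grids; all downstream
#' perceptual simulation depends only on the manifest.
#'
#' @param per_model_counts Named integer vector mapping model ids to sample
#'   counts (all \eqn{\ge} 1, at least 2 models). Models with a single sample
#'   trigger a warning (pairs are needed for within-model similarity).
#' @param size Pixels per side for generated maps.
#' @param master_seed Master seed fanned out to all samples.
#' @param materialize Compute height maps (\code{TRUE}) or manifest only.
#' @return Object of class \code{"texspace_dataset"}: \code{samples} (list of
#'   height maps or \code{NULL}), \code{labels} (model id per sample),
#'   \code{manifest} (list of parameter sets), \code{sweep_position},
#'   \code{size}, \code{master_seed}.
#' @examples
#' ds <- build_dataset(c(perlin = 3, cellular = 3), size = 16,
#'                     materialize = FALSE)
#' ds$labels
#' @export
build_dataset <- function(per_model_counts, size = 512L, master_seed = 1L,
                          materialize = TRUE) {
  if (length(per_model_counts) == 0) stop("empty configuration", call. = FALSE)
  ids <- names(per_model_counts)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("per_model_counts must be a named vector of model ids", call. = FALSE)
  }
  for (id in ids) .get_model(id)  # pre-flight: reject unregistered models
  if (length(ids) < 2) stop("at least 2 models are required", call. = FALSE)
  counts <- as.integer(per_model_counts)
  if (any(is.na(counts) | counts < 1L)) {
    stop("all per-model counts must be at least 1", call. = FALSE)
  }
  if (any(counts < 2L)) {
    warning("model(s) with a single sample: ",
            paste(ids[counts < 2L], collapse = ", "),
            " (within-model similarity needs at least 2)", call. = FALSE)
  }
  # registry order, then sweep order within model
  ord <- order(match(ids, names(.registry$models)))
  ids <- ids[ord]
  counts <- counts[ord]

  manifest <- list()
  labels <- character(0)
  sweep_pos <- numeric(0)
  for (j in seq_along(ids)) {
    sw <- parameter_sweep(ids[j], counts[j], master_seed = master_seed)
    manifest <- c(manifest, sw)
    labels <- c(labels, rep(ids[j], counts[j]))
    sweep_pos <- c(sweep_pos, vapply(sw, attr, 0, "sweep_position"))
  }
  samples <- NULL
  if (materialize) {
    samples <- lapply(manifest, generate_height_map, size = size)
  }
  structure(list(samples = samples, labels = labels, manifest = manifest,
                 sweep_position = sweep_pos, size = as.integer(size),
                 master_seed = master_seed),
            class = "texspace_dataset")
}

#' @export
print.texspace_dataset <- function(x, ...) {
  cat("<texspace_dataset> ", length(x$labels), " samples, ",
      length(unique(x$labels)), " models, ", x$size, "x", x$size,
      if (is.null(x$samples)) " (manifest only)" else "", "\n", sep = "")
  tab <- table(factor(x$labels, levels = unique(x$labels)))
  print(tab)
  invisible(x)
}
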