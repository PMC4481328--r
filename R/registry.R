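# Registry of the 23 procedural texture model families. Order matters: it is
# the order the models are listed in, dataset assembly follows it, and the
# numeric labels elsewhere in the package (e.g. merged-class reports) refer
# to positions in this registry.

.registry <- local({
  e <- new.env(parent = emptyenv())
  mk <- function(id, fn, params, count, spacing_param = NULL) {
    list(model_id = id, fn = fn, params = params, count = count,
         spacing_param = spacing_param)
  }
  models <- list(
    mk("ca_forest_fire", ".gen_ca_forest_fire", list(p_grow = c(0.05, 0.5)), 20L),
    mk("ca_surface_tension", ".gen_ca_surface_tension", list(density = c(0.35, 0.65)), 20L),
    mk("ca_excitable_media", ".gen_ca_excitable", list(refractory = c(2, 8)), 20L),
    mk("cellular", ".gen_cellular", list(n_features = c(10, 60), shape = c(0, 1)), 20L),
    mk("folding_texton", ".gen_folding_texton",
       list(spacing = c(12, 40), fold = c(1, 4)), 20L, "spacing"),
    mk("folding_cellular", ".gen_folding_cellular",
       list(n_features = c(10, 60), fold = c(1, 4)), 20L),
    mk("folding_fractal", ".gen_folding_fractal",
       list(beta = c(1.5, 3), fold = c(1, 4)), 20L),
    mk("folding_perlin", ".gen_folding_perlin",
       list(frequency = c(2, 10), fold = c(1, 4)), 20L),
    mk("fractal_1overf", ".gen_fractal_1overf", list(beta = c(1, 3)), 20L),
    mk("fractal_fourier", ".gen_fractal_fourier", list(beta = c(0, 3)), 20L),
    mk("fusion_cellular_texton", ".gen_fusion_cellular_texton",
       list(weight = c(0.2, 0.8)), 20L),
    mk("fusion_perlin_cellular", ".gen_fusion_perlin_cellular",
       list(weight = c(0.2, 0.8)), 20L),
    mk("fusion_perlin_texton", ".gen_fusion_perlin_texton",
       list(weight = c(0.2, 0.8)), 20L),
    mk("islamic_patterns", ".gen_islamic_patterns", list(n_points = c(4, 9)), 19L),
    mk("matrix_transformation", ".gen_matrix_transformation",
       list(frequency = c(4, 16)), 19L),
    mk("perlin", ".gen_perlin", list(frequency = c(2, 12)), 19L),
    mk("reaction_diffusion", ".gen_reaction_diffusion",
       list(feed = c(0.030, 0.054)), 19L),
    mk("texton_addition", ".gen_texton_addition", list(radius = c(2, 8)), 19L),
    mk("texton_probability_map", ".gen_texton_probability_map",
       list(n_points = c(50, 400)), 19L),
    mk("texton_random_grid", ".gen_texton_random_grid",
       list(spacing = c(12, 40)), 19L, "spacing"),
    mk("texton_random_walk", ".gen_texton_random_walk",
       list(n_steps = c(100, 600)), 19L),
    mk("texton_regular", ".gen_texton_regular", list(spacing = c(8, 40)), 19L, "spacing"),
    mk("wavelet_noise", ".gen_wavelet", list(n_bands = c(2, 5)), 19L)
  )
  names(models) <- vapply(models, `[[`, "", "model_id")
  e$models <- models
  e
})

.get_model <- function(model_id) {
  m <- .registry$models[[model_id]]
  if (is.null(m)) {
    stop("unknown model_id: '", model_id, "'. See texture_models().",
         call. = FALSE)
  }
  m
}

#' List the registered procedural texture models
#'
#' The registry covers 23 procedural model families: cellular automata
#' (forest fire, surface tension, excitable media), cellular (nearest
#' feature point) textures, four Folding and three Fusion compositions,
#' isotropic and axis-anisotropic spectral-synthesis fractals, a star-motif
#' wallpaper family, a fabric-weave family, Perlin gradient noise, Gray-Scott
#' reaction-diffusion, five texton placement/addition families, and wavelet
#' noise. Each model declares closed ranges for its sweepable parameters and
#' a default sample count; the default counts over all 23 models total 450.
#'
#' @return A data frame with one row per model: \code{model_id},
#'   \code{parameters} (comma-separated \code{name [lo, hi]} declarations)
#'   and \code{default_count}.
#' @examples
#' texture_models()
#' @export
texture_models <- function() {
  ms <- .registry$models
  data.frame(
    model_id = vapply(ms, `[[`, "", "model_id"),
    parameters = vapply(ms, function(m) {
      paste(sprintf("%s [%g, %g]", names(m$params),
                    vapply(m$params, `[`, 0, 1),
                    vapply(m$params, `[`, 0, 2)),
            collapse = ", ")
    }, ""),
    default_count = vapply(ms, `[[`, 0L, "count"),
    row.names = NULL
  )
}

#' Default per-model sample counts for the full dataset
#'
#' @return Named integer vector over all registered models, summing to 450.
#' @export
default_model_counts <- function() {
  vapply(.registry$models, `[[`, 0L, "count")
}
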