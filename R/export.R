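# File export: images (PNG, ASCII PGM), matrices (CSV), grouping records
# (JSON), dendrogram (Newick), and the run manifest.

#' Write a height map as a 16-bit ASCII PGM
#'
#' Plain-text P2 format with maxval 65535; pixel = round(65535 * height).
#'
#' @param hm A \code{"texspace_heightmap"} or numeric matrix in \eqn{[0,1]}.
#' @param path Output file path.
#' @export
write_pgm <- function(hm, path) {
  h <- if (inherits(hm, "texspace_heightmap")) hm$heights else as.matrix(hm)
  v <- round(65535 * h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), "65535"), con)
  # one image row per line
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a P2 ASCII PGM back into a matrix in [0, 1]
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file", call. = FALSE)
  w <- as.integer(toks[2])
  h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxv
}

#' Write a rendered image (or height map) as an 8-bit grayscale PNG
#'
#' Pixel values quantize as \code{round(255 * intensity)}; the analysis
#' itself always uses the real-valued grids.
#'
#' @param img A \code{"texspace_render"}, \code{"texspace_heightmap"} or
#'   numeric matrix in \eqn{[0,1]}.
#' @param path Output file path.
#' @export
write_png_gray <- function(img, path) {
  m <- if (inherits(img, "texspace_render")) img$intensities
       else if (inherits(img, "texspace_heightmap")) img$heights
       else as.matrix(img)
  png::writePNG(round(255 * m) / 255, path)
  invisible(path)
}

.write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m)
  if (is.null(rownames(m))) rownames(df) <- seq_len(nrow(m))
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Export all artifacts of a fitted pipeline
#'
#' Writes the similarity and feature matrices, embedding coordinates,
#' residual-variance curve, correlation table, dendrogram (Newick +
#' merge-table CSV), class maps, grouping records (JSON, with the feature
#' schema embedded), evaluation report (JSON), and - when the fit
#' materialized images - height maps (16-bit ASCII PGM), renders (8-bit
#' PNG) and the sample manifest (JSON).
#'
#' @param fit A fitted \code{"texspace"}.
#' @param directory Output directory (created if missing).
#' @return Data frame manifest of written files (invisibly).
#' @export
export_artifacts <- function(fit, directory) {
  if (!inherits(fit, "texspace")) stop("fit must be a texspace object",
                                       call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(directory, x)

  .write_matrix_csv(fit$S, fp("similarity.csv"))
  .write_matrix_csv(fit$S_mod, fp("model_similarity.csv"))
  .write_matrix_csv(fit$F_tex, fp("sample_features.csv"))
  .write_matrix_csv(fit$F_mod, fp("model_features.csv"))
  .write_matrix_csv(fit$coords, fp("pts_coords.csv"))
  .write_matrix_csv(fit$correlations, fp("axis_feature_correlations.csv"))
  .write_matrix_csv(cbind(dimension = seq_along(fit$rv_curve),
                          residual_variance = fit$rv_curve),
                    fp("residual_variance.csv"))
  .write_matrix_csv(fit$biplot$models, fp("biplot_models.csv"))
  .write_matrix_csv(fit$biplot$features, fp("biplot_features.csv"))

  hc <- fit$dendrogram$hclust
  ape::write.tree(ape::as.phylo(hc), fp("dendrogram.nwk"))
  utils::write.csv(data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                              height = hc$height),
                   fp("dendrogram_merges.csv"), row.names = FALSE)
  utils::write.csv(data.frame(model = names(fit$class_map),
                              class = as.integer(fit$class_map),
                              major_cluster = as.integer(
                                fit$major_clusters[names(fit$class_map)])),
                   fp("class_map.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(feature_schema = feature_schema(),
         records = lapply(fit$records, function(r) {
           list(subject = r$subject, groups = r$groups, merges = r$merges)
         })),
    fp("grouping_records.json"), auto_unbox = TRUE)

  utils::write.csv(as.data.frame.matrix(fit$loo$space$confusion),
                   fp("confusion_space.csv"))
  utils::write.csv(as.data.frame.matrix(fit$loo$scales$confusion),
                   fp("confusion_scales.csv"))
  jsonlite::write_json(default_subset_definitions(fit$dataset$labels),
                       fp("subset_definitions.json"))

  jsonlite::write_json(
    list(seed = fit$config$master_seed,
         n_samples = length(fit$dataset$labels),
         dim_selected = fit$dim_selected,
         residual_variance = fit$rv_curve,
         loo_accuracy = list(space = fit$loo$space$accuracy,
                             scales = fit$loo$scales$accuracy),
         consistency = as.list(fit$consistency),
         regression = fit$regressors$report,
         singleton_classes = fit$loo$space$singleton_classes),
    fp("report.json"), auto_unbox = TRUE, digits = NA)

  if (!is.null(fit$dataset$samples)) {
    imgdir <- fp("images")
    dir.create(imgdir, showWarnings = FALSE)
    for (i in seq_along(fit$dataset$samples)) {
      base <- sprintf("%03d_%s", i, fit$dataset$labels[i])
      write_pgm(fit$dataset$samples[[i]],
                file.path(imgdir, paste0(base, "_height.pgm")))
      if (!is.null(fit$renders)) {
        write_png_gray(fit$renders[[i]],
                       file.path(imgdir, paste0(base, "_render.png")))
      }
    }
    jsonlite::write_json(
      lapply(seq_along(fit$dataset$manifest), function(i) {
        ps <- fit$dataset$manifest[[i]]
        list(index = i, model_id = ps$model_id,
             parameters = as.list(ps$values), seed = ps$seed)
      }),
      fp("sample_manifest.json"), auto_unbox = TRUE)
  }

  files <- list.files(directory, recursive = TRUE, full.names = TRUE)
  invisible(data.frame(file = files, bytes = file.size(files)))
}
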