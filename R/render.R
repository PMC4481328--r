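# Lambertian rendering of height maps under slant/tilt illumination.
# Local shading only: no cast shadows or inter-reflections. Downstream
# analysis consumes images only through the synthetic observer, so global
# illumination is deliberately out of scope.

#' Illumination and shading configuration
#'
#' @param slant Illumination zenith angle in degrees (\eqn{0 \le} slant
#'   \eqn{< 90}); default 45.
#' @param tilt Illumination azimuth in degrees (\eqn{[0, 360)}); default 135.
#' @param albedo Constant diffuse reflectance in (0, 1].
#' @param height_scale Multiplier relating height units to pixel spacing
#'   before differentiation (the relief amplitude; default 1).
#' @return Object of class \code{"texspace_light"}.
#' @export
light_config <- function(slant = 45, tilt = 135, albedo = 1, height_scale = 1) {
  if (slant < 0 || slant >= 90) stop("slant must be in [0, 90)", call. = FALSE)
  tilt <- tilt %% 360
  if (albedo <= 0 || albedo > 1) stop("albedo must be in (0, 1]", call. = FALSE)
  if (height_scale <= 0) stop("height_scale must be positive", call. = FALSE)
  structure(list(slant = slant, tilt = tilt, albedo = albedo,
                 height_scale = height_scale),
            class = "texspace_light")
}

#' Unit surface normals of a height map
#'
#' Normals are computed per pixel as
#' \code{normalize(-dh/dx * height_scale, -dh/dy * height_scale, 1)} with
#' central differences; border pixels use replicated edges. The x axis runs
#' along columns, the y axis along rows.
#'
#' @param hm A \code{"texspace_heightmap"} or a plain numeric matrix.
#' @param height_scale Height-to-pixel scaling applied to the gradients.
#' @return Array \code{size x size x 3} of unit normal components (x, y, z).
#' @export
surface_normals <- function(hm, height_scale = 1) {
  h <- if (inherits(hm, "texspace_heightmap")) hm$heights else as.matrix(hm)
  n <- nrow(h)
  p <- ncol(h)
  # replicated-edge central differences
  xr <- h[, c(2:p, p), drop = FALSE]
  xl <- h[, c(1, 1:(p - 1)), drop = FALSE]
  dx <- (xr - xl) / 2
  yd <- h[c(2:n, n), , drop = FALSE]
  yu <- h[c(1, 1:(n - 1)), , drop = FALSE]
  dy <- (yd - yu) / 2
  nx <- -dx * height_scale
  ny <- -dy * height_scale
  nz <- matrix(1, n, p)
  len <- sqrt(nx^2 + ny^2 + nz^2)
  out <- array(0, c(n, p, 3))
  out[, , 1] <- nx / len
  out[, , 2] <- ny / len
  out[, , 3] <- nz / len
  out
}

#' Render a height map under Lambertian shading
#'
#' Intensity is \code{albedo * max(0, n . l)} per pixel, with the light
#' direction \code{l = (sin(slant) cos(tilt), sin(slant) sin(tilt),
#' cos(slant))}. Facets turned away from the light clamp to 0 (attached
#' shadow); no cast shadows are simulated.
#'
#' @param hm A \code{"texspace_heightmap"} or numeric matrix.
#' @param light A \code{\link{light_config}}.
#' @return Object of class \code{"texspace_render"}: list with
#'   \code{intensities} (matrix in \eqn{[0,1]}) and \code{light}.
#' @examples
#' flat <- matrix(0.5, 16, 16)
#' img <- render_lambertian(flat, light_config(slant = 45))
#' img$intensities[1, 1]  # cos(45 deg)
#' @export
render_lambertian <- function(hm, light = light_config()) {
  if (!inherits(light, "texspace_light")) stop("invalid light config", call. = FALSE)
  nr <- surface_normals(hm, light$height_scale)
  sr <- light$slant * pi / 180
  tr <- light$tilt * pi / 180
  l <- c(sin(sr) * cos(tr), sin(sr) * sin(tr), cos(sr))
  dotp <- nr[, , 1] * l[1] + nr[, , 2] * l[2] + nr[, , 3] * l[3]
  intens <- pmax(light$albedo * dotp, 0)  # attached-shadow clamp
  structure(list(intensities = pmin(intens, 1), light = light),
            class = "texspace_render")
}

#' @export
print.texspace_render <- function(x, ...) {
  cat("<texspace_render> ", nrow(x$intensities), "x", ncol(x$intensities),
      sprintf(" slant %g tilt %g albedo %g\n", x$light$slant, x$light$tilt,
              x$light$albedo), sep = "")
  invisible(x)
}
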