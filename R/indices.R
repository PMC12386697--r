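index_plane <- function(name, values, valid) {
  values[!valid] <- NA_real_
  structure(list(name = name, values = values, valid = valid),
            class = "index_plane")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("input grids have different shapes", call. = FALSE)
}

#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - R) / (NIR + R)`, a measure of vegetation vigor: dense
#' canopies reflect strongly in the NIR and absorb red light, pushing the
#' index toward 1; bare or impervious surfaces sit near or below 0.
#' Pixels where the denominator is zero are masked rather than propagated
#' as NaN.
#'
#' @param nir,red Numeric matrices of equal shape (reflectance).
#' @return An `index_plane` with elements `values` (NA where undefined)
#'   and `valid`.
#' @export
ndvi <- function(nir, red) {
  check_same_shape(nir, red)
  den <- nir + red
  valid <- is.finite(den) & den != 0
  v <- matrix(NA_real_, nrow(nir), ncol(nir))
  v[valid] <- (nir[valid] - red[valid]) / den[valid]
  index_plane("NDVI", v, valid)
}

#' Soil-adjusted vegetation index
#'
#' `SAVI = (NIR - R) * (1 + L) / (NIR + R + L)` with the soil brightness
#' correction factor `L = 0.5`.  The additive `L` damps the influence of
#' bright soil backgrounds, which makes the index more reliable than NDVI
#' over sparsely vegetated ground.  Unlike NDVI, SAVI is not invariant to
#' rescaling both bands.
#'
#' @param nir,red Numeric matrices of equal shape.
#' @param L Soil brightness correction factor (default 0.5).
#' @return An `index_plane`.
#' @export
savi <- function(nir, red, L = 0.5) {
  check_same_shape(nir, red)
  den <- nir + red + L
  valid <- is.finite(den) & den != 0
  v <- matrix(NA_real_, nrow(nir), ncol(nir))
  v[valid] <- (nir[valid] - red[valid]) * (1 + L) / den[valid]
  index_plane("SAVI", v, valid)
}

#' Plant pigment ratio index
#'
#' `PPR = (Green - Blue) / (Green + Blue)`, tracking the relative level of
#' chlorophyll against other pigments as a proxy for vegetation health.
#' Zero-denominator pixels are masked.
#'
#' @param green,blue Numeric matrices of equal shape.
#' @return An `index_plane`.
#' @export
ppr <- function(green, blue) {
  check_same_shape(green, blue)
  den <- green + blue
  valid <- is.finite(den) & den != 0
  v <- matrix(NA_real_, nrow(green), ncol(green))
  v[valid] <- (green[valid] - blue[valid]) / den[valid]
  index_plane("PPR", v, valid)
}

#' Compute the three vegetation-index planes of a scene
#'
#' @param scene A [reflectance_scene()].
#' @return Named list of `index_plane` objects (`NDVI`, `SAVI`, `PPR`);
#'   scene nodata pixels are masked in each plane.
#' @export
compute_indices <- function(scene) {
  b <- scene$bands
  planes <- list(NDVI = ndvi(b$nir, b$red), SAVI = savi(b$nir, b$red),
                 PPR = ppr(b$green, b$blue))
  valid <- scene_valid(scene)
  for (nm in names(planes)) {
    planes[[nm]]$valid <- planes[[nm]]$valid & valid
    planes[[nm]]$values[!planes[[nm]]$valid] <- NA_real_
  }
  planes
}

#' Export an index plane as a grayscale TIFF
#' @param plane An `index_plane`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_plane <- function(plane, path)
  write_plane(plane$values, path, name = plane$name)
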