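#' Construct a five-band reflectance scene
#'
#' A scene holds the five canonical surface-reflectance bands (blue, green,
#' red, red-edge, NIR) as numeric matrices on a common pixel grid, plus a
#' validity mask and an optional affine georeference.  Reflectance is
#' unitless and expected to lie in \[0, 1\]; values are passed through
#' unclipped, and values outside \[-0.05, 1.5\] (tolerated radiometric
#' artifacts) only raise a warning with their count.
#'
#' @param bands Named list of numeric matrices; names must cover
#'   `c("blue", "green", "red", "rededge", "nir")` and all matrices must
#'   share one dimension.
#' @param nodata_mask Optional logical matrix, `TRUE` marking invalid
#'   pixels.  Non-finite band values are always added to the mask.
#' @param transform Optional affine georeference
#'   `list(x0, dx, y0, dy)`: the center of pixel (row r, col c) sits at
#'   world coordinates `(x0 + (c - 0.5) * dx, y0 + (r - 0.5) * dy)`.
#'   `NULL` means geometry coordinates are interpreted directly in that
#'   pixel space (`x` along columns, `y` along rows, origin at the
#'   top-left corner of the grid).
#' @param crs Optional CRS identifier string, carried through unchecked.
#'
#' @return An object of class `reflectance_scene` with elements `bands`,
#'   `height`, `width`, `nodata_mask`, `transform`, `crs`.
#' @export
reflectance_scene <- function(bands, nodata_mask = NULL, transform = NULL,
                              crs = NULL) {
  missing_b <- setdiff(BAND_NAMES, names(bands))
  if (length(missing_b) > 0)
    stop("missing band(s): ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  bands <- bands[BAND_NAMES]
  dims <- vapply(bands, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("band shapes differ", call. = FALSE)
  h <- unname(dims[1, 1]); w <- unname(dims[2, 1])
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, h, w)
  if (!all(dim(nodata_mask) == c(h, w)))
    stop("nodata_mask shape differs from bands", call. = FALSE)
  for (b in BAND_NAMES) nodata_mask <- nodata_mask | !is.finite(bands[[b]])
  n_out <- sum(vapply(bands, function(m) {
    v <- m[!nodata_mask]
    sum(v < -0.05 | v > 1.5)
  }, numeric(1)))
  if (n_out > 0)
    warning(sprintf("%d valid reflectance value(s) outside [-0.05, 1.5]",
                    n_out), call. = FALSE)
  structure(list(bands = bands, height = h, width = w,
                 nodata_mask = nodata_mask, transform = transform,
                 crs = crs),
            class = "reflectance_scene")
}

#' @export
print.reflectance_scene <- function(x, ...) {
  cat(sprintf("<reflectance_scene> %d x %d px, 5 bands, %d nodata px\n",
              x$height, x$width, sum(x$nodata_mask)))
  invisible(x)
}

#' Valid-pixel mask of a scene
#' @param scene A [reflectance_scene()].
#' @return Logical matrix, `TRUE` where all bands are valid.
#' @export
scene_valid <- function(scene) !scene$nodata_mask

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write a scene to a multi-directory TIFF with a JSON sidecar
#'
#' Bands are stored as five 32-bit grayscale TIFF directories plus a sixth
#' validity-mask directory.  Because TIFF storage here is \[0, 1\]-scaled,
#' each band is min-max encoded and the per-band offsets/gains are recorded
#' in a sidecar (`<path>.aux.json`) together with the band order, the
#' affine transform, and the CRS, so that [read_scene()] restores values
#' exactly to 32-bit storage precision.
#'
#' @param scene A [reflectance_scene()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  enc <- vector("list", 6)
  lohi <- matrix(0, 5, 2, dimnames = list(BAND_NAMES, c("lo", "hi")))
  valid <- scene_valid(scene)
  for (i in seq_along(BAND_NAMES)) {
    m <- scene$bands[[BAND_NAMES[i]]]
    v <- m[valid]
    lo <- if (length(v)) min(v) else 0
    hi <- if (length(v)) max(v) else 1
    if (hi <= lo) hi <- lo + 1
    lohi[i, ] <- c(lo, hi)
    e <- (m - lo) / (hi - lo)
    e[!valid] <- 0
    enc[[i]] <- e
  }
  enc[[6]] <- matrix(as.numeric(valid), scene$height, scene$width)
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(format = "rifasel-scene-1", bands = BAND_NAMES,
               lo = as.list(setNames(lohi[, "lo"], BAND_NAMES)),
               hi = as.list(setNames(lohi[, "hi"], BAND_NAMES)),
               transform = scene$transform, crs = scene$crs)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multiband reflectance raster
#'
#' Reads a TIFF whose directories are the spectral bands.  If a
#' `<path>.aux.json` sidecar written by [write_scene()] is present, band
#' scaling, the validity mask, the transform and the CRS are restored from
#' it; otherwise directories are taken at face value and `band_map` assigns
#' the five canonical names to directory indices.
#'
#' @param path TIFF file path.
#' @param band_map Named integer vector mapping each of
#'   `c("blue","green","red","rededge","nir")` to a 1-based band
#'   (directory) index.  Ignored when a sidecar is present.
#' @return A [reflectance_scene()].
#' @export
read_scene <- function(path,
                       band_map = c(blue = 1, green = 2, red = 3,
                                    rededge = 4, nir = 5)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dirs <- tiff::readTIFF(path, all = TRUE)
  if (is.array(dirs) || is.matrix(dirs)) dirs <- list(dirs)
  dirs <- lapply(dirs, function(d) if (length(dim(d)) == 3) d[, , 1] else d)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (length(dirs) < 6)
      stop("sidecar present but raster lacks the mask directory",
           call. = FALSE)
    valid <- dirs[[6]] > 0.5
    bands <- list()
    for (i in seq_along(BAND_NAMES)) {
      b <- BAND_NAMES[i]
      m <- dirs[[i]] * (meta$hi[[b]] - meta$lo[[b]]) + meta$lo[[b]]
      m[!valid] <- NA_real_
      bands[[b]] <- m
    }
    tr <- meta$transform
    if (!is.null(tr)) tr <- as.list(tr)
    return(reflectance_scene(bands, nodata_mask = !valid, transform = tr,
                             crs = meta$crs))
  }
  missing_b <- setdiff(BAND_NAMES, names(band_map))
  if (length(missing_b) > 0)
    stop("band_map misses band(s): ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  if (any(band_map < 1 | band_map > length(dirs)))
    stop(sprintf("band_map index out of range: raster has %d band(s)",
                 length(dirs)), call. = FALSE)
  shapes <- vapply(dirs, function(d) dim(d)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("band shapes differ in raster file", call. = FALSE)
  bands <- lapply(BAND_NAMES, function(b) dirs[[band_map[[b]]]])
  names(bands) <- BAND_NAMES
  reflectance_scene(bands)
}

#' Write a single feature plane as a grayscale TIFF
#'
#' Min-max encoded like [write_scene()], with a sidecar recording the
#' scaling; `NA` pixels are stored as invalid in a mask directory.
#'
#' @param values Numeric matrix (NA = masked).
#' @param path Output path.
#' @param name Plane name recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_plane <- function(values, path, name = "plane") {
  valid <- is.finite(values)
  v <- values[valid]
  lo <- if (length(v)) min(v) else 0
  hi <- if (length(v)) max(v) else 1
  if (hi <= lo) hi <- lo + 1
  e <- (values - lo) / (hi - lo)
  e[!valid] <- 0
  tiff::writeTIFF(list(e, matrix(as.numeric(valid), nrow(values),
                                 ncol(values))),
                  path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(format = "rifasel-plane-1", name = name,
                            lo = lo, hi = hi),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
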