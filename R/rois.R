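#' Construct a set of labeled regions of interest
#'
#' Each ROI is a set of pixels (column-major cell indices into the scene
#' grid) carrying one of the six surface-class codes: 1 = RIFA mound,
#' 2 = bare soil, 3 = water-containing soil, 4 = asphalt, 5 = cement,
#' 6 = grass.  ROIs may overlap; overlapping pixels belong to every ROI
#' that covers them.
#'
#' @param rois List of `list(id, class_id, cells)` entries.
#' @param height,width Scene grid dimensions the cell indices refer to.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois, height, width) {
  ids <- vapply(rois, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) stop("ROI ids are not unique", call. = FALSE)
  for (r in rois) {
    if (is.null(r$class_id) || !r$class_id %in% 1:6)
      stop("ROI class_id missing or outside 1..6", call. = FALSE)
    if (length(r$cells) < 1)
      stop("ROI ", r$id, " covers no pixels", call. = FALSE)
    if (any(r$cells < 1 | r$cells > height * width))
      stop("ROI ", r$id, " has cells outside the scene grid",
           call. = FALSE)
  }
  structure(list(rois = rois, height = height, width = width),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cls <- vapply(x$rois, function(r) r$class_id, numeric(1))
  cat(sprintf("<roi_set> %d ROIs on %d x %d grid; classes: %s\n",
              length(x$rois), x$height, x$width,
              paste(sprintf("%s=%d", CLASS_LABELS[sort(unique(cls))],
                            table(factor(cls, levels = 1:6))[sort(unique(cls))]),
                    collapse = ", ")))
  invisible(x)
}

# World -> pixel-space coordinates under the scene transform (or identity).
# Pixel space puts the center of pixel (row r, col c) at (c - 0.5, r - 0.5).
world_to_pixel <- function(xy, transform) {
  if (is.null(transform)) return(xy)
  cbind((xy[, 1] - transform$x0) / transform$dx,
        (xy[, 2] - transform$y0) / transform$dy)
}

# Rasterize a polygon (list of rings, each an n x 2 matrix of (x, y) in
# pixel space) onto an h x w grid using the pixel-center even-odd rule.
# Returns column-major cell indices.
polygon_cells <- function(rings, height, width) {
  # pixel c is a candidate iff its center c - 0.5 falls in the x range
  allxy <- do.call(rbind, rings)
  cmin <- max(1L, ceiling(min(allxy[, 1]) + 0.5))
  cmax <- min(width, floor(max(allxy[, 1]) + 0.5))
  rmin <- max(1L, ceiling(min(allxy[, 2]) + 0.5))
  rmax <- min(height, floor(max(allxy[, 2]) + 0.5))
  if (cmin > cmax || rmin > rmax) return(integer(0))
  cc <- rep(cmin:cmax, each = rmax - rmin + 1)
  rr <- rep(rmin:rmax, times = cmax - cmin + 1)
  px <- cc - 0.5
  py <- rr - 0.5
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    hit <- pracma::inpolygon(px, py, ring[, 1], ring[, 2],
                             boundary = FALSE)
    inside <- xor(inside, hit)  # even-odd: holes toggle coverage off
  }
  sort((cc[inside] - 1L) * height + rr[inside])
}

geom_rings <- function(geometry) {
  ring_mat <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  if (geometry$type == "Polygon") {
    lapply(geometry$coordinates, ring_mat)
  } else if (geometry$type == "MultiPolygon") {
    unlist(lapply(geometry$coordinates,
                  function(poly) lapply(poly, ring_mat)),
           recursive = FALSE)
  } else {
    stop("unsupported geometry type: ", geometry$type, call. = FALSE)
  }
}

#' Read labeled ROI polygons from GeoJSON and rasterize them onto a scene
#'
#' Features must be Polygon or MultiPolygon geometries with an integer
#' property `class_id` in 1..6.  Geometries are rasterized with the
#' pixel-center rule (a pixel is covered when its center falls strictly
#' inside the polygon, holes handled even-odd).  ROIs that cover no valid
#' scene pixel are dropped with a warning.
#'
#' @param path GeoJSON file path.
#' @param scene The [reflectance_scene()] providing the grid and the
#'   (optional) affine transform used to interpret polygon coordinates.
#' @return A [roi_set()].
#' @export
read_rois <- function(path, scene) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  valid <- scene_valid(scene)
  rois <- list()
  dropped <- 0L
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    cl <- f$properties$class_id
    if (is.null(cl) || !(is.numeric(cl) && cl %in% 1:6))
      stop("feature ", k, ": property 'class_id' missing or outside 1..6",
           call. = FALSE)
    id <- f$properties$id
    if (is.null(id)) id <- f$id
    if (is.null(id)) id <- sprintf("roi_%03d", k)
    rings <- lapply(geom_rings(f$geometry), world_to_pixel,
                    transform = scene$transform)
    cells <- polygon_cells(rings, scene$height, scene$width)
    cells <- cells[valid[cells]]
    if (length(cells) == 0) {
      dropped <- dropped + 1L
      next
    }
    rois[[length(rois) + 1L]] <-
      list(id = as.character(id), class_id = as.integer(cl), cells = cells)
  }
  if (dropped > 0)
    warning(sprintf("%d ROI(s) covered no valid pixel and were dropped",
                    dropped), call. = FALSE)
  if (length(rois) == 0) stop("no usable ROI in ", path, call. = FALSE)
  roi_set(rois, scene$height, scene$width)
}

#' Write a ROI set to GeoJSON
#'
#' Each ROI is written as a MultiPolygon made of its unit pixel squares in
#' pixel space (or world space when the scene has a transform), so that
#' re-rasterizing the written outlines reproduces the original masks.
#'
#' @param rois A [roi_set()].
#' @param path Output GeoJSON path.
#' @param transform Optional affine transform (as in
#'   [reflectance_scene()]) used to express coordinates in world space.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path, transform = NULL) {
  h <- rois$height
  to_world <- function(x, y) {
    if (is.null(transform)) return(cbind(x, y))
    cbind(transform$x0 + x * transform$dx, transform$y0 + y * transform$dy)
  }
  feats <- lapply(rois$rois, function(r) {
    rr <- ((r$cells - 1L) %% h) + 1L
    cc <- ((r$cells - 1L) %/% h) + 1L
    polys <- lapply(seq_along(rr), function(i) {
      x0 <- cc[i] - 1; x1 <- cc[i]; y0 <- rr[i] - 1; y1 <- rr[i]
      corners <- to_world(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
      list(lapply(seq_len(5), function(j)
        c(corners[j, 1], corners[j, 2])))
    })
    list(type = "Feature",
         properties = list(id = r$id, class_id = r$class_id),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
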