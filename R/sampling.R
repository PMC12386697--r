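#' Assemble the full 38-plane feature stack of a scene
#'
#' Bands, vegetation indices, and GLCM texture planes as one named list of
#' matrices in the canonical [feature_names()] order, each `NA` where
#' masked.
#'
#' @param scene A [reflectance_scene()].
#' @param spec A [glcm_spec()] for the texture planes.
#' @return Named list of 38 matrices.
#' @export
feature_stack <- function(scene, spec = glcm_spec()) {
  valid <- scene_valid(scene)
  stack <- list()
  for (b in BAND_NAMES) {
    m <- scene$bands[[b]]
    m[!valid] <- NA_real_
    stack[[b]] <- m
  }
  for (p in compute_indices(scene)) stack[[p$name]] <- p$values
  stack <- c(stack, texture_planes(scene, spec))
  stack[feature_names()]
}

new_feature_table <- function(df, scale, dropped = 0L, provenance = list()) {
  structure(df, class = c("feature_table", "data.frame"),
            scale = scale,
            features = setdiff(names(df), c("unit_id", "roi_id",
                                            "class_id")),
            dropped_units = dropped, provenance = provenance)
}

#' Feature column names of a feature table
#' @param table A `feature_table`.
#' @return Character vector.
#' @export
feature_columns <- function(table) attr(table, "features")

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table scale=%s> %d units x %d features, %d dropped\n",
              attr(x, "scale"), nrow(x), length(feature_columns(x)),
              attr(x, "dropped_units")))
  invisible(as.data.frame(x))
}

#' Pixel-level labeled feature table
#'
#' One row per ROI pixel at which every feature plane is defined; pixels
#' where any plane is masked (scene nodata, index-denominator zeros, or
#' texture window borders) are dropped and counted.
#'
#' @param stack A [feature_stack()].
#' @param rois A [roi_set()].
#' @return A `feature_table` with columns `unit_id`, `roi_id`,
#'   `class_id`, and the 38 features; attribute `dropped_units` holds the
#'   number of excluded pixels.
#' @export
pixel_table <- function(stack, rois) {
  feats <- names(stack)
  ok_plane <- Reduce(`&`, lapply(stack, is.finite))
  rows <- list()
  dropped <- 0L
  for (r in rois$rois) {
    cells <- r$cells[ok_plane[r$cells]]
    dropped <- dropped + (length(r$cells) - length(cells))
    if (length(cells) == 0) next
    df <- data.frame(unit_id = sprintf("%s_px%d", r$id, cells),
                     roi_id = r$id, class_id = r$class_id,
                     stringsAsFactors = FALSE)
    for (f in feats) df[[f]] <- stack[[f]][cells]
    rows[[length(rows) + 1L]] <- df
  }
  if (length(rows) == 0)
    stop("no ROI pixel with complete features", call. = FALSE)
  new_feature_table(do.call(rbind, rows), "pixel", dropped)
}

#' Object-level labeled feature table
#'
#' One row per ROI; every feature is the arithmetic mean of the per-pixel
#' plane over the ROI's usable pixels (the exact pixel set that
#' [pixel_table()] retains, so each object row equals the mean of its
#' pixel rows).  ROIs with no usable pixel are dropped with a warning.
#'
#' @inheritParams pixel_table
#' @return A `feature_table` with one row per retained ROI.
#' @export
object_table <- function(stack, rois) {
  feats <- names(stack)
  ok_plane <- Reduce(`&`, lapply(stack, is.finite))
  rows <- list()
  dropped_rois <- 0L
  for (r in rois$rois) {
    cells <- r$cells[ok_plane[r$cells]]
    if (length(cells) == 0) {
      dropped_rois <- dropped_rois + 1L
      next
    }
    df <- data.frame(unit_id = r$id, roi_id = r$id, class_id = r$class_id,
                     stringsAsFactors = FALSE)
    for (f in feats) df[[f]] <- mean(stack[[f]][cells])
    rows[[length(rows) + 1L]] <- df
  }
  if (dropped_rois > 0)
    warning(sprintf("%d ROI(s) without usable pixels dropped",
                    dropped_rois), call. = FALSE)
  if (length(rows) == 0)
    stop("no ROI with usable pixels", call. = FALSE)
  new_feature_table(do.call(rbind, rows), "object", dropped_rois)
}

#' Write a feature table as CSV with a JSON sidecar
#'
#' The sidecar records the analysis scale, feature order, drop count, and
#' provenance so a table can be audited without re-running extraction.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(
    list(format = "rifasel-table-1", scale = attr(table, "scale"),
         features = feature_columns(table),
         dropped_units = attr(table, "dropped_units"),
         provenance = attr(table, "provenance")),
    paste0(path, ".aux.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".aux.json"),
                              simplifyVector = TRUE)
  ft <- new_feature_table(df, meta$scale, meta$dropped_units)
  attr(ft, "features") <- meta$features
  ft
}
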