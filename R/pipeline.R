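#' Assemble (or load) a pipeline configuration
#'
#' A pipeline config gathers every knob of the workflow: the scene source
#' (either a synthetic [scene_config()] or paths to a raster + GeoJSON
#' ROIs with a band map), the GLCM spec, the two redundancy thresholds,
#' the RFE spec, the MIC parameters, the normalization mode, `top_k`, and
#' the master seed.  Configs round-trip losslessly through YAML.
#'
#' @param scene Either a list of [scene_config()] arguments (synthetic
#'   input) or `list(raster = <path>, rois = <path>)` for file input.
#' @param band_map Named band-index map used when reading raster files.
#' @param glcm List of [glcm_spec()] arguments.
#' @param pearson_threshold,mic_threshold Redundancy thresholds, both
#'   0.7 by default (the conventional strong-correlation cutoff).
#' @param rfe List of [rfe_spec()] arguments (seed is derived from the
#'   master seed when not given).
#' @param mic_params List with `alpha` and `c` for [mic()].
#' @param normalization `"minmax"` or `"zscore"`.
#' @param top_k Per-method top-k size for the report.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = list(), band_map = c(blue = 1,
                                                         green = 2,
                                                         red = 3,
                                                         rededge = 4,
                                                         nir = 5),
                            glcm = list(), pearson_threshold = 0.7,
                            mic_threshold = 0.7, rfe = list(),
                            mic_params = list(alpha = 0.6, c = 15),
                            normalization = "minmax", top_k = 10,
                            seed = 1) {
  if (pearson_threshold <= 0 || pearson_threshold > 1 ||
      mic_threshold <= 0 || mic_threshold > 1)
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  structure(list(scene = scene, band_map = band_map, glcm = glcm,
                 pearson_threshold = pearson_threshold,
                 mic_threshold = mic_threshold, rfe = rfe,
                 mic_params = mic_params, normalization = normalization,
                 top_k = top_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$band_map <- unlist(y$band_map)
  do.call(pipeline_config, y)
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.matrix(x)) as.data.frame(x) else x), path)
  invisible(path)
}

#' Run the feature-selection pipeline
#'
#' Chains the full workflow: obtain a scene (simulate from a
#' [scene_config()] or read raster + ROI files), build the 38-plane
#' feature stack, extract pixel- and object-level tables, run the linear
#' (ANOVA F + Pearson) and nonlinear (RFE + MIC) selection routes on both
#' scales, and integrate the four configurations into a comparison
#' report.  With `out_dir` set, every stage artifact is written (scene
#' TIFF + ROI GeoJSON, table CSVs, selection JSONs, report JSON/CSV) plus
#' a manifest with the config, seed, package version, and artifact
#' checksums, so any artifact can be regenerated from the manifest alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param stage Run the chain up to this stage: `"simulate"`,
#'   `"features"`, `"sample"`, `"select"`, or `"all"`/`"compare"`
#'   (default).
#' @return List with `scene`, `rois`, `truth` (synthetic input only),
#'   `stack`, `tables`, `selections`, `report` (stages past the
#'   requested one are `NULL`).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stage = c("all", "compare", "select", "sample",
                                   "features", "simulate")) {
  stage <- match.arg(stage)
  rank_of <- c(simulate = 1, features = 2, sample = 3, select = 4,
               compare = 5, all = 5)
  upto <- rank_of[[stage]]
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if (!is.null(config$scene$raster)) {
    res$scene <- read_scene(config$scene$raster, config$band_map)
    res$rois <- read_rois(config$scene$rois, res$scene)
  } else {
    args <- config$scene
    if (is.null(args$seed)) args$seed <- config$seed
    sim <- make_scene(do.call(scene_config, args))
    res$scene <- sim$scene
    res$rois <- sim$rois
    res$truth <- sim$truth
    if (!is.null(out_dir)) {
      write_scene(res$scene, file.path(out_dir, "scene.tif"))
      write_rois(res$rois, file.path(out_dir, "rois.geojson"))
    }
  }
  if (upto < 2) return(res)

  spec <- do.call(glcm_spec, config$glcm)
  res$stack <- feature_stack(res$scene, spec)
  if (upto < 3) return(res)

  res$tables <- list(pixel = pixel_table(res$stack, res$rois),
                     object = object_table(res$stack, res$rois))
  if (!is.null(out_dir))
    for (sc in names(res$tables))
      write_feature_table(res$tables[[sc]],
                          file.path(out_dir, paste0(sc, "_table.csv")))
  if (upto < 4) return(res)

  rfe_args <- config$rfe
  sels <- list()
  for (sc in names(res$tables)) {
    tb <- res$tables[[sc]]
    f <- anova_f(tb)
    sels[[paste0("linear_", sc)]] <-
      pearson_filter(tb, f, config$pearson_threshold)
    ra <- rfe_args
    if (is.null(ra$seed))
      ra$seed <- config$seed + 1000L * match(sc, names(res$tables))
    rr <- rfe_rank(tb, do.call(rfe_spec, ra))
    sels[[paste0("nonlinear_", sc)]] <-
      mic_filter(tb, rr$scores, config$mic_threshold,
                 alpha = config$mic_params$alpha, c = config$mic_params$c)
  }
  res$selections <- sels
  if (!is.null(out_dir))
    for (nm in names(sels))
      write_selection_result(sels[[nm]],
                             file.path(out_dir, paste0(nm, ".json")))
  if (upto < 5) return(res)

  res$report <- build_report(sels, normalization = config$normalization,
                             top_k = config$top_k)
  if (!is.null(out_dir)) {
    write_report(res$report, file.path(out_dir, "report"))
    write_manifest(config, out_dir)
  }
  res
}

write_manifest <- function(config, out_dir) {
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  sums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(sums) <- files
  cfg <- lapply(unclass(config), function(x)
    if (is.matrix(x)) as.data.frame(x) else x)
  jsonlite::write_json(
    list(package = "rifasel",
         version = as.character(utils::packageVersion("rifasel")),
         seed = config$seed, config = cfg, checksums = sums),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
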