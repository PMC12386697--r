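# Default per-class band medians (reflectance).  Blue/green/red/NIR for
# mounds, asphalt, cement, and grass follow the pixel-level medians
# reported for the study site; bare-soil, water-soil, and cement reds are
# back-solved so the class NDVI medians (-0.123, ~0.11, -0.016) come out
# at their reported values, and grass red is back-solved from the grass
# NDVI median of 0.636.  Red-edge medians are not available per class and
# are synthetic: interpolated midway between red and NIR.
default_class_medians <- function() {
  m <- rbind(
    mound      = c(blue = 0.012, green = 0.023, red = 0.018,
                   rededge = NA, nir = 0.0428),
    bare_soil  = c(0.035, 0.050, 0.055063, NA, 0.0430),
    water_soil = c(0.020, 0.030, 0.028, NA, 0.0350),
    asphalt    = c(0.030, 0.065, 0.061, NA, 0.0569),
    cement     = c(0.045, 0.055, 0.049561, NA, 0.0480),
    grass      = c(0.008, 0.016, 0.019802, NA, 0.0890))
  m[, "rededge"] <- (m[, "red"] + m[, "nir"]) / 2
  m
}

#' Configuration of the synthetic multispectral scene generator
#'
#' The generator emulates the structure of the study imagery: a five-band
#' reflectance scene whose background is partitioned into vertical strips
#' of the five non-mound surface classes (bare soil, water-containing
#' soil, asphalt, cement, grass), with compact circular fire-ant mounds
#' planted on top.  Per-pixel values are
#' `median * (1 + tex_frac * T) + sd_iid * Z` where `T` is a smoothed
#' (spatially correlated) unit-variance noise field with class-specific
#' correlation length, `Z` is i.i.d. standard normal, and `sd_iid`
#' combines a brightness-proportional component with the absolute sensor
#' `noise_floor` in quadrature.  All noise terms are symmetric with zero
#' median, so every class keeps its configured band median, while rough
#' classes (mounds, grass) show higher local texture than smooth ones
#' (asphalt, cement).  The brightness-proportional spread is set so a
#' bright class's interquartile range is about `spread_frac` of its
#' median; dim bands are floor-dominated.
#'
#' @param height,width Scene size in pixels.
#' @param class_medians 6 x 5 matrix of per-class band medians (rows =
#'   classes 1..6, columns = blue/green/red/rededge/nir).
#' @param spread_frac Baseline IQR as a fraction of the class median
#'   (default 0.3).
#' @param band_spread_mult Per-band multiplier on `spread_frac`
#'   (length 5, blue/green/red/rededge/nir).  The default widens the
#'   visible bands and narrows red-edge/NIR, reproducing the structure
#'   of the study imagery where mounds and soils show high variability
#'   in the RGB bands while the NIR signal is comparatively stable.
#' @param tex_frac Per-class fraction of the median given to the
#'   spatially correlated component (length 6).
#' @param tex_length Per-class box-blur half-width of the correlated
#'   field (length 6; smaller = rougher texture).
#' @param n_mounds Number of planted mounds.
#' @param mound_radius Integer range of mound radii in pixels.
#' @param n_bg_rois Background ROI patches per non-mound class.
#' @param bg_roi_size Side length of background ROI patches.
#' @param noise_floor Absolute per-pixel reflectance noise standard
#'   deviation (default 0.01, a typical radiometric accuracy for UAV
#'   surface-reflectance products), emulating the sensor noise floor
#'   that affects every band regardless of brightness.  Without it,
#'   purely proportional noise would make the dimmest bands
#'   unrealistically clean.
#' @param seed Mandatory random seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height = 70, width = 70,
                         class_medians = default_class_medians(),
                         spread_frac = 0.3,
                         band_spread_mult = c(blue = 1.4, green = 1.4,
                                              red = 1.4, rededge = 0.85,
                                              nir = 0.7),
                         tex_frac = c(0.18, 0.12, 0.12, 0.04, 0.04, 0.18),
                         tex_length = c(1, 2, 2, 3, 3, 1),
                         n_mounds = 10, mound_radius = c(2, 3),
                         n_bg_rois = 6, bg_roi_size = 3,
                         noise_floor = 0.01, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (any(class_medians < 0 | class_medians > 1))
    stop("class medians must lie in [0, 1]", call. = FALSE)
  if (min(mound_radius) < 1) stop("mound radius must be >= 1 px",
                                  call. = FALSE)
  # per-class x per-band sd fractions: IQR -> sd, minus the share taken
  # by the spatially correlated component
  total_frac <- outer(rep(1, 6), band_spread_mult) * spread_frac /
    (2 * stats::qnorm(0.75))
  iid_frac <- sqrt(pmax(total_frac^2 - tex_frac^2, 1e-6))
  dimnames(iid_frac) <- list(CLASS_LABELS, BAND_NAMES)
  structure(list(height = height, width = width,
                 class_medians = class_medians,
                 spread_frac = spread_frac,
                 band_spread_mult = band_spread_mult,
                 tex_frac = tex_frac,
                 iid_frac = iid_frac, tex_length = tex_length,
                 n_mounds = n_mounds, mound_radius = mound_radius,
                 n_bg_rois = n_bg_rois, bg_roi_size = bg_roi_size,
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "scene_config")
}

# Toroidal box blur of half-width L; returns a unit-variance field.
smooth_field <- function(h, w, L) {
  z <- matrix(rnorm(h * w), h, w)
  if (L < 1) return(z)
  acc <- matrix(0, h, w)
  for (dy in -L:L) for (dx in -L:L) {
    rows <- ((seq_len(h) - 1 + dy) %% h) + 1
    cols <- ((seq_len(w) - 1 + dx) %% w) + 1
    acc <- acc + z[rows, cols]
  }
  acc / (2 * L + 1)  # mean of k^2 iid terms has sd 1/k
}

disk_cells <- function(r0, c0, radius, h, w) {
  rr <- max(1, r0 - radius):min(h, r0 + radius)
  cc <- max(1, c0 - radius):min(w, c0 + radius)
  grid <- expand.grid(r = rr, c = cc)
  keep <- (grid$r - r0)^2 + (grid$c - c0)^2 <= radius^2
  (grid$c[keep] - 1L) * h + grid$r[keep]
}

#' Generate a synthetic labeled multispectral scene
#'
#' @param cfg A [scene_config()].
#' @return List with `scene` (a [reflectance_scene()]), `rois` (a
#'   [roi_set()]: one ROI per mound plus `n_bg_rois` square patches per
#'   background class), and `truth` (class map, planted mound table, and
#'   the config).
#' @export
make_scene <- function(cfg) {
  set.seed(cfg$seed)
  h <- cfg$height; w <- cfg$width
  class_map <- matrix(0L, h, w)
  strip <- ceiling(w / 5)
  for (k in 1:5)
    class_map[, ((k - 1) * strip + 1):min(k * strip, w)] <- k + 1L

  # plant non-overlapping circular mounds, keeping disks off the border
  mounds <- data.frame(row = integer(0), col = integer(0),
                       radius = integer(0))
  tries <- 0L
  while (nrow(mounds) < cfg$n_mounds) {
    if (tries > 200L * cfg$n_mounds)
      stop("could not place mounds without overlap", call. = FALSE)
    tries <- tries + 1L
    r <- sample(cfg$mound_radius[1]:cfg$mound_radius[2], 1)
    cr <- sample((r + 2):(h - r - 1), 1)
    cc <- sample((r + 2):(w - r - 1), 1)
    if (nrow(mounds) > 0 &&
        any(sqrt((mounds$row - cr)^2 + (mounds$col - cc)^2) <=
            mounds$radius + r + 1)) next
    mounds <- rbind(mounds, data.frame(row = cr, col = cc, radius = r))
  }
  mound_cells <- lapply(seq_len(nrow(mounds)), function(i)
    disk_cells(mounds$row[i], mounds$col[i], mounds$radius[i], h, w))
  for (cells in mound_cells) class_map[cells] <- 1L

  # per-class correlated fields, then per-band values
  tex_fields <- lapply(1:6, function(k)
    smooth_field(h, w, cfg$tex_length[k]))
  med <- cfg$class_medians
  bands <- list()
  for (bi in seq_along(BAND_NAMES)) {
    b <- BAND_NAMES[bi]
    med_map <- matrix(med[class_map, b], h, w)
    tex_map <- matrix(cfg$tex_frac[class_map], h, w)
    iid_map <- matrix(cfg$iid_frac[class_map, b], h, w)
    tfield <- matrix(0, h, w)
    for (k in 1:6) {
      sel <- class_map == k
      tfield[sel] <- tex_fields[[k]][sel]
    }
    iid_sd <- sqrt((med_map * iid_map)^2 + cfg$noise_floor^2)
    bands[[b]] <- med_map * (1 + tex_map * tfield) +
      iid_sd * matrix(rnorm(h * w), h, w)
    # fresh correlated fields per band so bands are not perfectly coupled
    tex_fields <- lapply(1:6, function(k)
      smooth_field(h, w, cfg$tex_length[k]))
  }
  scene <- suppressWarnings(reflectance_scene(bands))

  rois <- list()
  for (i in seq_len(nrow(mounds)))
    rois[[length(rois) + 1L]] <- list(id = sprintf("mound_%02d", i),
                                      class_id = 1L,
                                      cells = mound_cells[[i]])
  s <- cfg$bg_roi_size
  occupied <- matrix(FALSE, h, w)
  for (cells in mound_cells) occupied[cells] <- TRUE
  for (k in 2:6) {
    placed <- 0L
    tries <- 0L
    while (placed < cfg$n_bg_rois && tries < 500L) {
      tries <- tries + 1L
      r0 <- sample(2:(h - s), 1)
      c0 <- sample(2:(w - s), 1)
      rr <- r0:(r0 + s - 1); cc <- c0:(c0 + s - 1)
      block <- class_map[rr, cc]
      if (any(block != k) || any(occupied[rr, cc])) next
      occupied[rr, cc] <- TRUE
      placed <- placed + 1L
      cells <- as.vector(outer((cc - 1L) * h, rr, "+"))
      rois[[length(rois) + 1L]] <-
        list(id = sprintf("%s_%02d", CLASS_LABELS[k], placed),
             class_id = as.integer(k), cells = sort(cells))
    }
    if (placed < cfg$n_bg_rois)
      warning(sprintf("placed only %d/%d ROIs for class %s", placed,
                      cfg$n_bg_rois, CLASS_LABELS[k]), call. = FALSE)
  }
  list(scene = scene, rois = roi_set(rois, h, w),
       truth = list(class_map = class_map, mounds = mounds, config = cfg))
}

#' Configuration of the synthetic tabular generator
#'
#' Builds labeled feature tables with known ground truth for validating
#' the selection framework: informative features carry class-dependent
#' means, redundant features are noisy linear copies or noisy monotone
#' (exponential) transforms of an informative parent, and noise features
#' are class-independent.
#'
#' @param n_per_class Rows per class (>= 2).
#' @param n_classes Number of classes.
#' @param k_informative Number of informative features (>= 1 for
#'   recovery scenarios).
#' @param k_redundant Number of redundant features; odd-numbered ones are
#'   linear copies, even-numbered ones monotone transforms, parents cycle
#'   through the informative features.
#' @param k_noise Number of pure-noise features.
#' @param effect_size Distance between adjacent class means in
#'   within-class standard deviations (default 1.5).
#' @param redundancy Correlation strength between a redundant feature and
#'   its (possibly transformed) parent (default 0.95).
#' @param seed Mandatory random seed.
#' @return An object of class `table_config`.
#' @export
table_config <- function(n_per_class = 40, n_classes = 3,
                         k_informative = 3, k_redundant = 2, k_noise = 5,
                         effect_size = 1.5, redundancy = 0.95, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_per_class < 2) stop("n_per_class must be >= 2", call. = FALSE)
  if (any(c(k_informative, k_redundant, k_noise) < 0))
    stop("feature counts must be >= 0", call. = FALSE)
  structure(list(n_per_class = n_per_class, n_classes = n_classes,
                 k_informative = k_informative,
                 k_redundant = k_redundant, k_noise = k_noise,
                 effect_size = effect_size, redundancy = redundancy,
                 seed = as.integer(seed)),
            class = "table_config")
}

#' Generate a synthetic labeled feature table with planted structure
#'
#' @param cfg A [table_config()].
#' @return List with `table` (a `feature_table`, scale `"synthetic"`) and
#'   `truth` (a data.frame labeling each column informative / redundant /
#'   noise, with parent and redundancy type).
#' @export
make_table <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_per_class * cfg$n_classes
  cls <- rep(seq_len(cfg$n_classes), each = cfg$n_per_class)
  centered <- cls - mean(cls)
  df <- data.frame(unit_id = sprintf("u%04d", seq_len(n)),
                   roi_id = NA_character_, class_id = cls,
                   stringsAsFactors = FALSE)
  truth <- data.frame(feature = character(0), role = character(0),
                      parent = character(0), type = character(0))
  inf_names <- character(0)
  for (j in seq_len(cfg$k_informative)) {
    nm <- sprintf("inf%d", j)
    df[[nm]] <- cfg$effect_size * centered + rnorm(n)
    inf_names <- c(inf_names, nm)
    truth <- rbind(truth, data.frame(feature = nm, role = "informative",
                                     parent = NA, type = NA))
  }
  for (j in seq_len(cfg$k_redundant)) {
    parent <- inf_names[((j - 1) %% max(1, cfg$k_informative)) + 1]
    ps <- as.vector(scale(df[[parent]]))
    type <- if (j %% 2 == 1) "linear" else "monotone"
    nm <- sprintf("red%d", j)
    if (type == "linear") {
      # redundancy = target Pearson correlation with the parent
      df[[nm]] <- cfg$redundancy * ps +
        sqrt(1 - cfg$redundancy^2) * rnorm(n)
    } else {
      # monotone transform kept near-functional: MIC needs a much
      # tighter relationship than |r| to exceed the same threshold, so
      # redundancy here sets 1 - (noise sd / signal sd)
      base <- as.vector(scale(exp(1.5 * ps)))
      df[[nm]] <- base + (1 - cfg$redundancy) * rnorm(n)
    }
    truth <- rbind(truth, data.frame(feature = nm, role = "redundant",
                                     parent = parent, type = type))
  }
  for (j in seq_len(cfg$k_noise)) {
    nm <- sprintf("noise%d", j)
    df[[nm]] <- rnorm(n)
    truth <- rbind(truth, data.frame(feature = nm, role = "noise",
                                     parent = NA, type = NA))
  }
  list(table = new_feature_table(df, "synthetic"), truth = truth)
}
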