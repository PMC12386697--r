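#' Specification of the gray-level co-occurrence computation
#'
#' Controls how reflectance bands are quantized and how pixel pairs are
#' counted.  The defaults — a 3x3 window, the four standard displacement
#' directions averaged, symmetric counting, 64 gray levels, and per-band
#' min-max quantization over valid pixels — are common co-occurrence
#' settings; all are adjustable here and through the pipeline config.
#'
#' @param levels Number of gray levels Ng (>= 2).
#' @param window Odd sliding-window side length in pixels (>= 3).
#' @param offsets Integer matrix with columns (dx, dy): displacement in
#'   columns and rows.  Each offset's co-occurrence matrix is normalized
#'   separately and the matrices are averaged.
#' @param symmetric Count each pair in both orders (default TRUE).
#' @param quantization `"minmax"` (linear binning between the band's
#'   valid min and max) or `"fixed"` (linear binning over `fixed_range`).
#' @param fixed_range Range used by `"fixed"` quantization.
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(levels = 64, window = 3,
                      offsets = cbind(dx = c(1, 0, 1, 1),
                                      dy = c(0, 1, 1, -1)),
                      symmetric = TRUE,
                      quantization = c("minmax", "fixed"),
                      fixed_range = c(0, 1)) {
  quantization <- match.arg(quantization)
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  if (window < 3 || window %% 2 == 0)
    stop("window must be odd and >= 3", call. = FALSE)
  if (nrow(offsets) == 0 || any(offsets[, 1] == 0 & offsets[, 2] == 0))
    stop("offsets must be non-empty and nonzero", call. = FALSE)
  structure(list(levels = as.integer(levels), window = as.integer(window),
                 offsets = offsets, symmetric = symmetric,
                 quantization = quantization, fixed_range = fixed_range),
            class = "glcm_spec")
}

#' Quantize a band to integer gray levels
#'
#' Linear binning to `0 .. Ng-1`; monotone, with the maximum valid value
#' mapped to `Ng - 1`.  A constant band under min-max quantization maps to
#' all zeros with a warning.
#'
#' @param band Numeric matrix.
#' @param spec A [glcm_spec()].
#' @param valid Optional logical matrix of valid pixels.
#' @return Integer matrix in `0 .. Ng-1` (`NA` where invalid).
#' @export
quantize <- function(band, spec, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(band)
  v <- band[valid]
  rng <- if (spec$quantization == "minmax") range(v) else spec$fixed_range
  q <- matrix(NA_integer_, nrow(band), ncol(band))
  if (diff(rng) <= 0) {
    if (spec$quantization == "minmax")
      warning("constant band: all pixels quantized to level 0",
              call. = FALSE)
    q[valid] <- 0L
    return(q)
  }
  z <- floor((band[valid] - rng[1]) / diff(rng) * spec$levels)
  z <- pmin(pmax(z, 0), spec$levels - 1)
  q[valid] <- as.integer(z)
  q
}

#' Gray-level co-occurrence matrix of a single quantized window
#'
#' Counts pixel pairs at each displacement offset, normalizes each
#' offset's counts to sum to one, and averages the normalized matrices.
#' With `symmetric = TRUE` every pair is counted in both orders.
#'
#' @param window_q Integer matrix of quantized gray levels (`NA` allowed;
#'   pairs touching `NA` are skipped).
#' @param spec A [glcm_spec()].
#' @return `Ng x Ng` matrix `g` with `sum(g) == 1`, or all-`NA` matrix if
#'   no offset yields a valid pair.
#' @export
glcm <- function(window_q, spec) {
  ng <- spec$levels
  acc <- matrix(0, ng, ng)
  used <- 0L
  nr <- nrow(window_q); nc <- ncol(window_q)
  for (o in seq_len(nrow(spec$offsets))) {
    dx <- spec$offsets[o, 1]; dy <- spec$offsets[o, 2]
    r1 <- max(1, 1 - dy):min(nr, nr - dy)
    c1 <- max(1, 1 - dx):min(nc, nc - dx)
    if (length(r1) == 0 || length(c1) == 0) next
    a <- window_q[r1, c1, drop = FALSE]
    b <- window_q[r1 + dy, c1 + dx, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    code <- a[ok] * ng + b[ok] + 1
    if (spec$symmetric) code <- c(code, b[ok] * ng + a[ok] + 1)
    cnt <- tabulate(code, nbins = ng * ng)
    acc <- acc + matrix(cnt / sum(cnt), ng, ng, byrow = TRUE)
    used <- used + 1L
  }
  if (used == 0L) return(matrix(NA_real_, ng, ng))
  acc / used
}

#' The six GLCM texture measures of a normalized co-occurrence matrix
#'
#' For `g(i, j)` with gray levels `i, j = 0 .. Ng-1`:
#' homogeneity `sum g / (1 + (i - j)^2)`; contrast `sum (i - j)^2 g`;
#' dissimilarity `sum |i - j| g`; entropy `-sum g ln g` (with
#' `0 ln 0 := 0`); second moment (angular second moment) `sum g^2`;
#' correlation `sum (i - mu)(j - mu) g / sigma^2` where `mu` and `sigma^2`
#' are the mean and variance of the GLCM marginal distribution.  For
#' non-symmetric matrices the row and column marginals are used on their
#' respective axes, which reduces to the single-`mu` form whenever `g` is
#' symmetric (the default counting mode).  A degenerate matrix with zero
#' marginal variance has correlation 1 by convention, the limit of a
#' perfectly dependent distribution — this keeps flat surfaces such as
#' cement or asphalt from producing NaNs.
#'
#' @param g Normalized co-occurrence matrix (`sum(g) == 1`).
#' @return Named numeric vector with elements `homogeneity`, `contrast`,
#'   `dissimilarity`, `entropy`, `second_moment`, `correlation`.
#' @export
texture_metrics <- function(g) {
  if (abs(sum(g) - 1) > 1e-8)
    stop("co-occurrence matrix is not normalized", call. = FALSE)
  ng <- nrow(g)
  lev <- 0:(ng - 1)
  di <- outer(lev, lev, "-")
  pos <- g > 0
  pi_ <- rowSums(g); pj_ <- colSums(g)
  mui <- sum(lev * pi_); muj <- sum(lev * pj_)
  vi <- sum((lev - mui)^2 * pi_); vj <- sum((lev - muj)^2 * pj_)
  corr <- if (vi <= 1e-12 || vj <= 1e-12) 1 else
    sum(outer(lev - mui, lev - muj) * g) / sqrt(vi * vj)
  c(homogeneity = sum(g / (1 + di^2)),
    contrast = sum(di^2 * g),
    dissimilarity = sum(abs(di) * g),
    entropy = -sum(g[pos] * log(g[pos])),
    second_moment = sum(g^2),
    correlation = corr)
}

#' Sliding-window GLCM texture planes for all five bands
#'
#' For each band and each of the six texture measures, computes the
#' metric of the co-occurrence matrix of the window centered on every
#' pixel (30 planes in total).  Bands are quantized once, globally over
#' their valid pixels.  Pixels whose window leaves the scene or touches a
#' nodata pixel are masked.
#'
#' @param scene A [reflectance_scene()].
#' @param spec A [glcm_spec()].
#' @return Named list of 30 numeric matrices (`<band>_<metric>`), `NA`
#'   where masked.
#' @export
texture_planes <- function(scene, spec = glcm_spec()) {
  if (spec$window > scene$height || spec$window > scene$width)
    stop("window larger than scene", call. = FALSE)
  valid <- scene_valid(scene)
  out <- list()
  for (b in BAND_NAMES) {
    q <- quantize(scene$bands[[b]], spec, valid)
    qi <- q
    qi[is.na(qi)] <- 0L
    planes <- glcm_planes_cpp(qi, valid, spec$levels, spec$offsets,
                              spec$window, spec$symmetric)
    for (m in GLCM_METRICS) out[[paste(b, m, sep = "_")]] <- planes[[m]]
  }
  out
}
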