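test_that("quantization bins linearly, monotonically, and flags degeneracy", {
  sp <- glcm_spec(levels = 2)
  q <- quantize(matrix(c(0, 0.5, 1), 1, 3), sp)
  expect_equal(as.vector(q), c(0L, 1L, 1L))
  expect_warning(qc <- quantize(matrix(0.4, 3, 3), sp), "constant")
  expect_true(all(qc == 0L))
  # 256 levels over exact 0..255/255 values: identity mapping
  sp256 <- glcm_spec(levels = 256)
  vals <- matrix((0:255) / 255, 16, 16)
  expect_equal(as.vector(quantize(vals, sp256)), 0:255)
  # monotone
  set.seed(3)
  x <- sort(runif(50))
  qx <- quantize(matrix(x, 1), glcm_spec(levels = 7))
  expect_true(all(diff(as.vector(qx)) >= 0))
})

test_that("single-window GLCMs match hand enumeration", {
  spc <- glcm_spec(levels = 2, offsets = cbind(1, 0))
  g_const <- glcm(matrix(1L, 2, 2), spc)
  expect_equal(sum(g_const), 1)
  expect_equal(g_const[2, 2], 1)  # single nonzero entry
  g_chk <- glcm(matrix(c(0L, 1L, 1L, 0L), 2, 2), spc)
  expect_equal(g_chk[1, 2], 0.5)
  expect_equal(g_chk[2, 1], 0.5)
  expect_equal(g_chk[1, 1] + g_chk[2, 2], 0)
  # normalization holds for arbitrary windows and offset sets
  set.seed(5)
  for (i in 1:5) {
    w <- matrix(sample(0:3, 25, replace = TRUE), 5, 5)
    g <- glcm(w, glcm_spec(levels = 4))
    expect_equal(sum(g), 1, tolerance = 1e-12)
  }
})

test_that("texture metrics reproduce degenerate and checkerboard values", {
  g1 <- matrix(0, 3, 3); g1[2, 2] <- 1
  m <- texture_metrics(g1)
  expect_equal(unname(m[c("contrast", "dissimilarity", "entropy")]),
               c(0, 0, 0))
  expect_equal(unname(m[c("homogeneity", "second_moment", "correlation")]),
               c(1, 1, 1))
  g2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  m2 <- texture_metrics(g2)
  expect_equal(unname(m2["contrast"]), 1)
  expect_equal(unname(m2["dissimilarity"]), 1)
  expect_equal(unname(m2["homogeneity"]), 0.5)
  expect_equal(unname(m2["second_moment"]), 0.5)
  expect_equal(unname(m2["entropy"]), log(2))
  expect_error(texture_metrics(matrix(0.3, 2, 2)), "not normalized")
})

test_that("metrics agree with a naive double-loop oracle on random matrices", {
  set.seed(9)
  for (i in 1:20) {
    ng <- sample(2:6, 1)
    g <- matrix(runif(ng * ng), ng, ng)
    g <- (g + t(g)) / 2
    g <- g / sum(g)
    expect_equal(texture_metrics(g), naive_metrics(g), tolerance = 1e-12)
  }
})

test_that("sliding-window planes match the per-window reference path", {
  sc <- tiny_scene(10, 10, seed = 21)
  sp <- glcm_spec(levels = 5, window = 3)
  planes <- texture_planes(sc, sp)
  expect_length(planes, 30)
  q <- quantize(sc$bands$green, sp)
  h <- sp$window %/% 2
  for (r in c(2, 5, 9)) for (cl in c(2, 6, 9)) {
    win <- q[(r - h):(r + h), (cl - h):(cl + h)]
    ref <- texture_metrics(glcm(win, sp))
    for (m in names(ref))
      expect_equal(planes[[paste0("green_", m)]][r, cl], unname(ref[m]),
                   tolerance = 1e-10)
  }
  # borders are masked
  expect_true(all(is.na(planes$green_contrast[1, ])))
  expect_true(all(is.na(planes$green_contrast[, 10])))
})

test_that("plane values satisfy the metric range invariants", {
  sc <- tiny_scene(14, 14, seed = 33)
  planes <- texture_planes(sc, glcm_spec(levels = 8))
  for (b in rifasel:::BAND_NAMES) {
    v <- function(m) {
      x <- planes[[paste(b, m, sep = "_")]]
      x[is.finite(x)]
    }
    expect_true(all(v("contrast") >= 0))
    expect_true(all(v("dissimilarity") >= 0))
    expect_true(all(v("homogeneity") > 0 & v("homogeneity") <= 1))
    expect_true(all(v("second_moment") > 0 & v("second_moment") <= 1))
    expect_true(all(v("entropy") >= 0 & v("entropy") <= 2 * log(8)))
    expect_true(all(v("correlation") >= -1 - 1e-12 &
                      v("correlation") <= 1 + 1e-12))
  }
})

test_that("constant scenes have zero interior contrast; variance raises it", {
  b <- lapply(1:5, function(i) matrix(0.2, 9, 9))
  names(b) <- rifasel:::BAND_NAMES
  sc <- reflectance_scene(b)
  planes <- suppressWarnings(texture_planes(sc, glcm_spec(levels = 4)))
  inner <- planes$red_contrast[2:8, 2:8]
  expect_true(all(inner == 0))
  # planted high-variance patch: mean contrast inside > outside
  set.seed(2)
  b2 <- b
  b2$red[3:6, 3:6] <- 0.2 + runif(16, -0.15, 0.15)
  sc2 <- reflectance_scene(b2)
  p2 <- suppressWarnings(texture_planes(sc2, glcm_spec(levels = 16)))
  con <- p2$red_contrast
  inside <- con[4:5, 4:5]
  outside <- con[8, 2:8]
  expect_gt(mean(inside), mean(outside))
})

test_that("four-direction metrics are invariant under 90-degree rotation", {
  sc <- tiny_scene(9, 9, seed = 13)
  sp <- glcm_spec(levels = 6, window = 3)
  planes <- texture_planes(sc, sp)
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE])
  scr <- reflectance_scene(lapply(sc$bands, rot))
  planes_r <- texture_planes(scr, sp)
  for (m in c("contrast", "entropy", "homogeneity", "second_moment"))
    expect_equal(planes_r[[paste0("blue_", m)]],
                 rot(planes[[paste0("blue_", m)]]), tolerance = 1e-10)
})

test_that("rising noise amplitude never lowers expected contrast", {
  amps <- c(0, 0.03, 0.08, 0.15)
  mean_con <- vapply(amps, function(a) {
    vals <- vapply(1:6, function(s) {
      set.seed(100 + s)
      b <- lapply(1:5, function(i) matrix(0.4, 9, 9))
      names(b) <- rifasel:::BAND_NAMES
      b$nir <- b$nir + matrix(rnorm(81, 0, a + 1e-9), 9, 9)
      p <- suppressWarnings(texture_planes(
        reflectance_scene(b), glcm_spec(levels = 8, quantization = "fixed",
                                        fixed_range = c(0, 1))))
      mean(p$nir_contrast, na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_con) >= 0))
})

test_that("spec validation rejects malformed GLCM settings", {
  expect_error(glcm_spec(levels = 1), "levels")
  expect_error(glcm_spec(window = 4), "window")
  expect_error(glcm_spec(offsets = cbind(0, 0)), "nonzero")
  b <- lapply(1:5, function(i) matrix(0.2, 2, 2))
  names(b) <- rifasel:::BAND_NAMES
  expect_error(texture_planes(reflectance_scene(b), glcm_spec(window = 5)),
               "window larger")
})
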