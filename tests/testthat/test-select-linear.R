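test_that("the worked two-class example gives F = 8", {
  tb <- manual_table(data.frame(f = c(0, 1, 2, 3)), c(1, 1, 2, 2))
  expect_equal(unname(anova_f(tb)["f"]), 8)
})

test_that("degenerate features get their sentinel scores", {
  tb <- manual_table(data.frame(flat = rep(0.5, 6),
                                sep = c(0, 0, 0, 1, 1, 1)),
                     rep(1:2, each = 3))
  f <- anova_f(tb)
  expect_equal(unname(f["flat"]), 0)     # no between-class variance
  expect_equal(unname(f["sep"]), Inf)    # zero within, nonzero between
  expect_error(anova_f(manual_table(data.frame(f = 1:3), c(1, 1, 2))),
               ">= 2 rows")
  expect_error(anova_f(manual_table(data.frame(f = 1:4), rep(1, 4))),
               ">= 2 classes")
})

test_that("F-scores match the aov oracle across seeded draws", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(c(12, 20, 30), 1)
    k <- sample(2:4, 1)
    cls <- sample(rep(1:k, length.out = n))
    x <- rnorm(n) + 0.5 * cls
    tb <- manual_table(data.frame(f = x), cls)
    expect_equal(unname(anova_f(tb)["f"]), oracle_f(x, cls),
                 tolerance = 1e-9)
  }
})

test_that("a correlated lower-scored feature is dropped and logged", {
  e <- orthonormal_basis(60, 2, seed = 8)
  A <- e[, 1]
  B <- 0.9 * e[, 1] + sqrt(1 - 0.81) * e[, 2]
  tb <- manual_table(data.frame(A = A, B = B), rep(1:2, 30))
  res <- pearson_filter(tb, c(A = 10, B = 5), threshold = 0.7)
  expect_equal(res$retained, "A")
  expect_equal(res$drop_log$dropped, "B")
  expect_equal(res$drop_log$kept, "A")
  expect_equal(res$drop_log$association, 0.9, tolerance = 1e-9)
})

test_that("greedy order resolves correlation chains by score", {
  # r(A,B) = 0.8, r(B,C) = 0.75, r(A,C) = 0.28: feasible analogue of a
  # chain where only B correlates strongly with both ends
  e <- orthonormal_basis(80, 3, seed = 15)
  A <- e[, 1]
  B <- 0.8 * e[, 1] + 0.6 * e[, 2]
  b2 <- (0.75 - 0.8 * 0.28) / 0.6
  C <- 0.28 * e[, 1] + b2 * e[, 2] + sqrt(1 - 0.28^2 - b2^2) * e[, 3]
  tb <- manual_table(data.frame(A = A, B = B, C = C), rep(1:2, 40))
  X <- as.matrix(as.data.frame(tb)[, c("A", "B", "C")])
  expect_equal(abs(cor(X))["A", "B"], 0.8, tolerance = 1e-9)
  expect_equal(abs(cor(X))["B", "C"], 0.75, tolerance = 1e-9)
  res <- pearson_filter(tb, c(A = 10, B = 5, C = 7), threshold = 0.7)
  # visit order A, C, B: A kept, C kept (r = 0.28), B dropped against A
  expect_setequal(res$retained, c("A", "C"))
  expect_equal(res$drop_log$dropped, "B")
})

test_that("uncorrelated features all survive; threshold 1 is a no-op", {
  set.seed(30)
  tb <- manual_table(as.data.frame(matrix(rnorm(200), 50, 4,
                                          dimnames = list(NULL,
                                                          letters[1:4]))),
                     rep(1:2, 25))
  f <- anova_f(tb)
  res <- pearson_filter(tb, f, threshold = 0.7)
  expect_setequal(res$retained, letters[1:4])
  e <- orthonormal_basis(40, 2, seed = 2)
  tb2 <- manual_table(data.frame(A = e[, 1],
                                 B = 0.99 * e[, 1] +
                                   sqrt(1 - 0.99^2) * e[, 2]),
                      rep(1:2, 20))
  res2 <- pearson_filter(tb2, c(A = 3, B = 1), threshold = 1)
  expect_setequal(res2$retained, c("A", "B"))
})

test_that("no retained pair exceeds the threshold, and tightening is monotone", {
  set.seed(77)
  for (i in 1:10) {
    n <- 60; p <- 8
    base <- matrix(rnorm(n * 3), n, 3)
    X <- base[, sample(1:3, p, replace = TRUE)] +
      matrix(rnorm(n * p, 0, 0.4), n, p)
    colnames(X) <- paste0("f", 1:p)
    tb <- manual_table(as.data.frame(X), rep(1:2, n / 2))
    f <- anova_f(tb)
    sizes <- vapply(c(0.9, 0.7, 0.5, 0.3), function(th) {
      res <- pearson_filter(tb, f, threshold = th)
      R <- abs(cor(X[, res$retained, drop = FALSE]))
      diag(R) <- 0
      expect_lte(max(R), th)
      expect_true(all(res$drop_log$association > th))
      expect_setequal(c(res$retained, res$drop_log$dropped), colnames(X))
      length(res$retained)
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("column order only matters for ties", {
  set.seed(55)
  X <- matrix(rnorm(300), 60, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  X[, 2] <- X[, 1] * 0.95 + rnorm(60, 0, 0.2)
  cls <- rep(1:2, 30)
  X[cls == 2, ] <- X[cls == 2, ] + 0.8
  tb <- manual_table(as.data.frame(X), cls)
  f <- anova_f(tb)
  perm <- c(4, 2, 5, 1, 3)
  tbp <- manual_table(as.data.frame(X[, perm]), cls)
  res1 <- pearson_filter(tb, f, 0.7)
  res2 <- pearson_filter(tbp, f[perm], 0.7)
  expect_setequal(res1$retained, res2$retained)
})

test_that("selection results serialize losslessly, Inf included", {
  tb <- manual_table(data.frame(flat = rep(0.5, 6),
                                sep = c(0, 0, 0, 1, 1, 1),
                                ok = c(0.1, 0.4, 0.2, 0.9, 1.1, 1.4)),
                     rep(1:2, each = 3))
  res <- pearson_filter(tb, anova_f(tb), 0.7)
  path <- tempfile(fileext = ".json")
  write_selection_result(res, path)
  back <- read_selection_result(path)
  expect_equal(back$scores, res$scores)
  expect_equal(back$retained, res$retained)
  expect_equal(back$ranking, res$ranking)
  expect_equal(back$threshold, res$threshold)
})
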