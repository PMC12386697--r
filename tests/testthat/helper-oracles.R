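# Independent oracles used across the suite.  These deliberately use
# naive enumeration / textbook formulas, not the package's own code paths.

# Naive GLCM of a quantized window: enumerate every pixel pair per offset,
# normalize per offset, average the normalized matrices.
naive_glcm <- function(win, ng, offsets, symmetric = TRUE) {
  nr <- nrow(win); nc <- ncol(win)
  mats <- list()
  for (o in seq_len(nrow(offsets))) {
    dx <- offsets[o, 1]; dy <- offsets[o, 2]
    g <- matrix(0, ng, ng)
    for (r in 1:nr) for (cl in 1:nc) {
      r2 <- r + dy; c2 <- cl + dx
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        a <- win[r, cl] + 1; b <- win[r2, c2] + 1
        g[a, b] <- g[a, b] + 1
        if (symmetric) g[b, a] <- g[b, a] + 1
      }
    }
    if (sum(g) > 0) mats[[length(mats) + 1]] <- g / sum(g)
  }
  if (length(mats) == 0) return(NULL)
  Reduce(`+`, mats) / length(mats)
}

# Naive double-loop evaluation of the six texture measures.
naive_metrics <- function(g) {
  ng <- nrow(g)
  hom <- con <- dis <- ent <- asm <- 0
  pi_ <- rowSums(g); pj_ <- colSums(g)
  mui <- sum((0:(ng - 1)) * pi_); muj <- sum((0:(ng - 1)) * pj_)
  vi <- sum(((0:(ng - 1)) - mui)^2 * pi_)
  vj <- sum(((0:(ng - 1)) - muj)^2 * pj_)
  corr <- 0
  for (i in 0:(ng - 1)) for (j in 0:(ng - 1)) {
    v <- g[i + 1, j + 1]
    hom <- hom + v / (1 + (i - j)^2)
    con <- con + (i - j)^2 * v
    dis <- dis + abs(i - j) * v
    if (v > 0) ent <- ent - v * log(v)
    asm <- asm + v^2
    corr <- corr + (i - mui) * (j - muj) * v
  }
  corr <- if (vi <= 1e-12 || vj <= 1e-12) 1 else corr / sqrt(vi * vj)
  c(homogeneity = hom, contrast = con, dissimilarity = dis, entropy = ent,
    second_moment = asm, correlation = corr)
}

# Textbook one-way F via aov (independent of the package's matrix algebra).
oracle_f <- function(x, cls) {
  summary(stats::aov(x ~ factor(cls)))[[1]][["F value"]][1]
}

# Mass equipartition of a sorted vector, mirroring the documented rule the
# MIC statistic is defined over (ties stay together, greedy bin closure).
oracle_equipartition <- function(ys, q) {
  n <- length(ys)
  row <- integer(n)
  rowsize <- n / q
  i <- 1; h <- 0; curr <- 0
  while (i <= n) {
    s <- 1
    while (i + s <= n && ys[i + s] == ys[i]) s <- s + 1
    if (h != 0 && curr < q - 1 &&
        abs(h + s - rowsize) >= abs(h - rowsize)) {
      curr <- curr + 1
      h <- 0
      rowsize <- (n - i + 1) / (q - curr)
    }
    row[i:(i + s - 1)] <- curr
    i <- i + s
    h <- h + s
  }
  row
}

# Exhaustive MIC over the searched grid family: one axis equipartitioned,
# every subset of cut positions on the other axis enumerated.  Exact for
# small n (no superclump cap active).
oracle_mic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(4, floor(n^alpha))
  best <- 0
  one_orientation <- function(x, y) {
    ordx <- order(x)
    ys <- sort(y)
    for (q in 2:max(2, B %/% 2)) {
      pmax <- B %/% q
      if (pmax < 2) next
      rowOfSorted <- oracle_equipartition(ys, q)
      rowOf <- rowOfSorted[match(y, ys)]
      rows_x <- rowOf[ordx]                  # row label in x order
      hr <- table(rows_x)
      HR <- -sum((hr / n) * log(hr / n))
      if (HR <= 0) next
      for (p in 2:pmax) {
        for (cuts in utils::combn(n - 1, p - 1, simplify = FALSE)) {
          colid <- findInterval(seq_len(n), c(cuts + 0.5)) # 0..p-1
          tab <- table(colid, rows_x)
          pj <- tab / n
          pc <- rowSums(pj); pr <- colSums(pj)
          nz <- pj > 0
          I <- sum(pj[nz] * log(pj[nz] /
                                  (outer(pc, pr)[nz])))
          v <- I / log(min(p, q))
          if (v > best) best <<- v
        }
      }
    }
  }
  one_orientation(x, y)
  one_orientation(y, x)
  min(best, 1)
}

# Small deterministic scene for structural tests.
tiny_scene <- function(h = 12, w = 12, seed = 1) {
  set.seed(seed)
  bands <- lapply(seq_along(rifasel:::BAND_NAMES), function(i)
    matrix(runif(h * w, 0.01, 0.2), h, w))
  names(bands) <- rifasel:::BAND_NAMES
  reflectance_scene(bands)
}

# Feature table built directly from columns (for the selection tests).
manual_table <- function(df, class_id) {
  out <- data.frame(unit_id = sprintf("u%03d", seq_len(nrow(df))),
                    roi_id = NA_character_, class_id = class_id)
  out <- cbind(out, df)
  structure(out, class = c("feature_table", "data.frame"),
            scale = "manual", features = names(df), dropped_units = 0L,
            provenance = list())
}

# Vectors with exact empirical correlations, built from an orthonormal
# basis of centered columns.
orthonormal_basis <- function(n, k, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * k), n, k)
  m <- scale(m, center = TRUE, scale = FALSE)
  qr.Q(qr(m))
}
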