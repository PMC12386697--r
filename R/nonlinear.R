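#' Specification of the random-forest RFE run
#'
#' @param n_trees Trees per forest fit (default 500).
#' @param step Features removed per elimination round (default 1).
#' @param seed Base random seed; round `i` uses `seed + i` so the whole
#'   ranking is reproducible bit for bit.
#' @param max_depth Optional tree depth limit (`NULL` = unlimited).
#' @return An object of class `rfe_spec`.
#' @export
rfe_spec <- function(n_trees = 500, step = 1, seed = 1, max_depth = NULL) {
  if (n_trees < 1 || step < 1) stop("n_trees and step must be >= 1",
                                    call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), step = as.integer(step),
                 seed = as.integer(seed), max_depth = max_depth),
            class = "rfe_spec")
}

#' Random-forest recursive-feature-elimination ranking
#'
#' Iteratively fits a classification random forest on the surviving
#' features, records impurity (Gini) importances, removes the
#' lowest-importance feature(s), and repeats until none remain.  Each
#' feature's reported score is its importance in the round before its
#' removal, and the ranking is the reverse elimination order — a stable
#' global ranking.  No feature is discarded by this operation itself;
#' redundancy pruning happens downstream in [mic_filter()].
#'
#' @param table A `feature_table` with >= 2 classes and >= 10 rows.
#' @param spec An [rfe_spec()].
#' @return List with `scores` (named importances at elimination time) and
#'   `ranking` (features, best first).
#' @export
rfe_rank <- function(table, spec = rfe_spec()) {
  cls <- factor(table$class_id)
  if (nlevels(cls) < 2) stop("need >= 2 classes", call. = FALSE)
  if (nrow(table) < 10) stop("need >= 10 rows", call. = FALSE)
  feats <- feature_columns(table)
  df <- as.data.frame(table)[, feats, drop = FALSE]
  df$.class <- cls
  surviving <- feats
  elim <- character(0)
  scores <- setNames(numeric(length(feats)), feats)
  round_i <- 0L
  while (length(surviving) > 0) {
    round_i <- round_i + 1L
    fit <- ranger::ranger(
      dependent.variable.name = ".class",
      data = df[, c(surviving, ".class"), drop = FALSE],
      num.trees = spec$n_trees, importance = "impurity",
      max.depth = if (is.null(spec$max_depth)) NULL else spec$max_depth,
      seed = spec$seed + round_i, num.threads = 1, verbose = FALSE)
    imp <- fit$variable.importance[surviving]
    n_drop <- min(spec$step, length(surviving))
    # lowest-importance features go first; ties resolved by column order
    drop_now <- surviving[order(imp, match(surviving, feats))][seq_len(n_drop)]
    scores[drop_now] <- imp[drop_now]
    elim <- c(elim, drop_now)
    surviving <- setdiff(surviving, drop_now)
  }
  list(scores = scores, ranking = rev(elim))
}

#' Maximal information coefficient of two numeric vectors
#'
#' The MINE approximation of MIC: over all grid shapes `p x q` with
#' `p * q <= n^alpha`, one axis is mass-equipartitioned and the cut
#' points of the other are optimized by dynamic programming over clump
#' boundaries (the clump count is capped at `c * p`); both orientations
#' are searched and the maximum normalized mutual information
#' `I / ln(min(p, q))` is returned.  The statistic is 1 for any noiseless
#' functional relationship and 0 for a constant vector by convention.
#'
#' @param x,y Numeric vectors of equal length (>= 20), finite.
#' @param alpha Grid-size exponent of the `B(n) = n^alpha` bound
#'   (default 0.6).
#' @param c Clump factor: at most `c * p` clumps are considered when
#'   optimizing a `p`-column axis (default 15).
#' @return MIC in `[0, 1]`.
#' @export
mic <- function(x, y, alpha = 0.6, c = 15) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 20) stop("need n >= 20", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  mic_cpp(as.numeric(x), as.numeric(y), alpha, c)
}

#' Pairwise MIC matrix of a feature table
#'
#' @param table A `feature_table`.
#' @inheritParams mic
#' @return Symmetric matrix of MIC values with unit diagonal.
#' @export
mic_matrix <- function(table, alpha = 0.6, c = 15) {
  feats <- feature_columns(table)
  X <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  M <- mic_matrix_cpp(X, alpha, c)
  dimnames(M) <- list(feats, feats)
  M
}

#' Nonlinear-route redundancy removal: MIC filtering of RFE-ranked
#' features
#'
#' Same greedy scheme as [pearson_filter()], but association is the
#' maximal information coefficient, which flags monotone and other
#' nonlinear redundancies that Pearson correlation can miss: features are
#' visited in descending RFE-importance order and dropped when their MIC
#' with any retained feature exceeds the threshold.
#'
#' @param table The `feature_table` the importances were computed on.
#' @param importances Named RFE importance scores covering every feature
#'   column (from [rfe_rank()]).
#' @param threshold MIC threshold (default 0.7, the conventional
#'   strong-dependence cutoff mirroring `|r| > 0.7`).
#' @inheritParams mic
#' @return A `selection_result` with `route = "nonlinear"`; no retained
#'   pair has MIC above the threshold.
#' @export
mic_filter <- function(table, importances, threshold = 0.7, alpha = 0.6,
                       c = 15) {
  feats <- feature_columns(table)
  if (!all(feats %in% names(importances)))
    stop("importances must cover all feature columns", call. = FALSE)
  X <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  const <- apply(X, 2, function(v) sd(v) == 0 || !is.finite(sd(v)))
  M <- mic_matrix(table, alpha = alpha, c = c)
  attr(M, "constant") <- const
  greedy_filter(M, importances, feats, threshold, "nonlinear",
                sprintf("MIC > %.2f with higher-scored feature", threshold))
}
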