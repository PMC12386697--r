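#' One-way ANOVA F-score of every feature against the class label
#'
#' For each feature, `F = (SSB / (k - 1)) / (SSW / (N - k))` across the
#' `k` class labels — the ratio of between-class to within-class variance
#' used purely as a ranking statistic (no p-values).  A feature with zero
#' within-class variance but nonzero between-class variance receives an
#' `Inf` sentinel and ranks first; a feature identical in all rows scores
#' 0.
#'
#' @param table A `feature_table` (needs >= 2 classes, each with >= 2
#'   rows).
#' @return Named numeric vector of F-scores, one per feature column.
#' @export
anova_f <- function(table) {
  cls <- table$class_id
  tab <- table(cls)
  if (length(tab) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(tab < 2)) stop("every class needs >= 2 rows", call. = FALSE)
  feats <- feature_columns(table)
  X <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  n <- nrow(X); k <- length(tab)
  g <- factor(cls)
  grand <- colMeans(X)
  means <- rowsum(X, g) / as.vector(tab)
  ssb <- colSums(as.vector(tab) * (sweep(means, 2, grand))^2)
  ssw <- colSums((X - means[g, , drop = FALSE])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb <= 1e-24] <- 0
  setNames(f, feats)
}

# Order features by descending score; ties (and infinities among
# themselves) resolved by the fixed feature-column order.
score_order <- function(scores, feats) {
  s <- scores[feats]
  feats[order(-s, seq_along(feats))]
}

new_selection_result <- function(route, scores, ranking, drop_log,
                                 retained, threshold, extra = list()) {
  structure(c(list(route = route, scores = scores, ranking = ranking,
                   drop_log = drop_log, retained = retained,
                   threshold = threshold), extra),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result route=%s> %d/%d features retained (threshold %.2f)\n",
              x$route, length(x$retained), length(x$scores), x$threshold))
  invisible(x)
}

# Shared greedy redundancy filter: walk features in descending-score
# order; drop a candidate whose association with any already-retained
# feature exceeds the threshold, logging the retained partner with the
# strongest association.  Constant features have undefined association
# (treated as 0) and are retained only with a positive score.
greedy_filter <- function(assoc, scores, feats, threshold, route, rule) {
  ord <- score_order(scores, feats)
  retained <- character(0)
  log_rows <- list()
  for (f in ord) {
    if (isTRUE(attr(assoc, "constant")[f])) {
      if (scores[[f]] > 0) retained <- c(retained, f)
      else log_rows[[length(log_rows) + 1L]] <-
          data.frame(kept = NA_character_, dropped = f, association = NA_real_,
                     rule = "constant feature with non-positive score")
      next
    }
    a <- assoc[f, retained]
    a[!is.finite(a)] <- 0
    if (length(a) > 0 && max(a) > threshold) {
      partner <- retained[which.max(a)]
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(kept = partner, dropped = f, association = max(a),
                   rule = rule)
    } else {
      retained <- c(retained, f)
    }
  }
  drop_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(kept = character(0), dropped = character(0),
               association = numeric(0), rule = character(0))
  new_selection_result(route, scores[feats], ord, drop_log, retained,
                       threshold)
}

#' Linear-route redundancy removal: Pearson filtering of F-ranked features
#'
#' Features are visited in descending F-score order (ties broken by the
#' fixed column order); a candidate correlated at `|r| >` `threshold`
#' with any already-retained feature is dropped, and the drop log records
#' the retained partner.  The greedy keep-best order resolves transitive
#' correlation clusters deterministically while keeping the
#' highest-scoring member of each cluster.
#'
#' @param table The `feature_table` the scores were computed on (the
#'   correlations are computed on this same table).
#' @param scores Named scores covering every feature column (e.g. from
#'   [anova_f()]).
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return A `selection_result` with `route = "linear"`: per-feature
#'   scores, the ranking, a drop log of `(kept, dropped, association,
#'   rule)`, and the retained feature set.  No retained pair has
#'   `|r| >` `threshold`.
#' @export
pearson_filter <- function(table, scores, threshold = 0.7) {
  feats <- feature_columns(table)
  if (!all(feats %in% names(scores)))
    stop("scores must cover all feature columns", call. = FALSE)
  X <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  const <- apply(X, 2, function(v) sd(v) == 0 || !is.finite(sd(v)))
  r <- suppressWarnings(abs(cor(X)))
  attr(r, "constant") <- const
  greedy_filter(r, scores, feats, threshold, "linear",
                sprintf("|r| > %.2f with higher-scored feature", threshold))
}

#' Serialize a selection result to JSON
#' @param result A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  out <- list(route = result$route,
              scores = as.list(result$scores),
              ranking = result$ranking,
              drop_log = result$drop_log,
              retained = result$retained,
              threshold = result$threshold)
  # Inf sentinels are not representable in JSON numbers; tag them
  out$scores <- lapply(out$scores, function(s)
    if (is.infinite(s)) "Inf" else s)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a selection result written by [write_selection_result()]
#' @param path JSON path.
#' @return A `selection_result`.
#' @export
read_selection_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scores <- vapply(x$scores, function(s)
    if (identical(s, "Inf")) Inf else as.numeric(s), numeric(1))
  drop_log <- as.data.frame(x$drop_log)
  if (nrow(drop_log) == 0)
    drop_log <- data.frame(kept = character(0), dropped = character(0),
                           association = numeric(0), rule = character(0))
  new_selection_result(x$route, scores, x$ranking, drop_log,
                       as.character(x$retained), x$threshold)
}
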