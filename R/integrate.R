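REPORT_METHODS <- c("linear_pixel", "linear_object", "nonlinear_pixel",
                    "nonlinear_object")

#' Union of the feature sets retained by the two routes
#'
#' @param linear,nonlinear `selection_result`s computed on the same
#'   feature table (identical feature universes).
#' @return Character vector: the merged retained set, in canonical
#'   feature order, duplicates removed.
#' @export
merge_routes <- function(linear, nonlinear) {
  if (!setequal(names(linear$scores), names(nonlinear$scores)))
    stop("results come from different feature universes", call. = FALSE)
  u <- union(linear$retained, nonlinear$retained)
  u[order(match(u, names(linear$scores)))]
}

#' Build the four-configuration comparison report
#'
#' Takes the four method-by-scale selection results (linear/pixel,
#' linear/object, nonlinear/pixel, nonlinear/object), normalizes each
#' method's scores independently, and assembles the cross-method summary:
#' the normalized-importance matrix behind the heatmap, per-method
#' retention flags, each feature's retention frequency (count / 4, a
#' stability proxy), the unweighted average of the four normalized
#' scores, and the per-method top-k retained features.
#'
#' `Inf` F-score sentinels are mapped to the method's finite maximum
#' before scaling, so they normalize to 1.  With min-max normalization a
#' method whose scores are all equal normalizes to all 1.
#'
#' @param results Named list with exactly the elements `linear_pixel`,
#'   `linear_object`, `nonlinear_pixel`, `nonlinear_object`.
#' @param normalization `"minmax"` (default; heatmap-style scores in
#'   \[0, 1\]) or `"zscore"`.
#' @param top_k Number of top retained features reported per method
#'   (default 10).
#' @return An object of class `comparison_report` with elements
#'   `methods`, `norm_importance` (method x feature), `retained_flags`,
#'   `retention_frequency`, `avg_importance`, `top_k`, `merged`.
#' @export
build_report <- function(results, normalization = c("minmax", "zscore"),
                         top_k = 10) {
  normalization <- match.arg(normalization)
  if (!all(REPORT_METHODS %in% names(results)))
    stop("results must contain the four configurations: ",
         paste(REPORT_METHODS, collapse = ", "), call. = FALSE)
  results <- results[REPORT_METHODS]
  feats <- names(results[[1]]$scores)
  for (m in REPORT_METHODS)
    if (!setequal(names(results[[m]]$scores), feats))
      stop("feature universes differ between configurations",
           call. = FALSE)
  norm1 <- function(s) {
    s <- s[feats]
    fin <- is.finite(s)
    if (!any(fin)) return(setNames(rep(1, length(s)), feats))
    s[!fin] <- max(s[fin])
    if (normalization == "minmax") {
      rng <- range(s)
      if (diff(rng) == 0) return(setNames(rep(1, length(s)), feats))
      (s - rng[1]) / diff(rng)
    } else {
      if (sd(s) == 0) return(setNames(rep(0, length(s)), feats))
      (s - mean(s)) / sd(s)
    }
  }
  norm_imp <- do.call(rbind, lapply(results, function(r) norm1(r$scores)))
  rownames(norm_imp) <- REPORT_METHODS
  flags <- do.call(rbind, lapply(results, function(r)
    setNames(feats %in% r$retained, feats)))
  rownames(flags) <- REPORT_METHODS
  freq <- colMeans(flags)
  avg <- colMeans(norm_imp)
  topk <- lapply(results, function(r) {
    ord <- score_order(r$scores, feats)
    ret <- ord[ord %in% r$retained]
    utils::head(ret, top_k)
  })
  merged <- list(
    pixel = merge_routes(results$linear_pixel, results$nonlinear_pixel),
    object = merge_routes(results$linear_object,
                          results$nonlinear_object))
  structure(list(methods = REPORT_METHODS, norm_importance = norm_imp,
                 retained_flags = flags, retention_frequency = freq,
                 avg_importance = avg, top_k = topk, merged = merged,
                 normalization = normalization),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> 4 methods x", ncol(x$norm_importance),
      "features\n")
  top <- sort(x$avg_importance, decreasing = TRUE)
  cat("top averaged features:",
      paste(sprintf("%s (%.2f)", names(top)[1:5], top[1:5]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a comparison report as JSON plus CSV matrices
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(t(report$norm_importance),
            file.path(dir, "normalized_importance.csv"))
  write.csv(t(report$retained_flags),
            file.path(dir, "retained_flags.csv"))
  jsonlite::write_json(
    list(methods = report$methods,
         retention_frequency = as.list(report$retention_frequency),
         avg_importance = as.list(report$avg_importance),
         top_k = report$top_k, merged = report$merged,
         normalization = report$normalization),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Plot the report: importance heatmap and retention-vs-importance
#' scatter
#'
#' Requires ggplot2 (Suggests); returns a list of two ggplot objects.
#'
#' @param report A `comparison_report`.
#' @return List with `heatmap` and `scatter` ggplot objects.
#' @export
plot_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ni <- report$norm_importance
  dfh <- data.frame(method = rep(rownames(ni), ncol(ni)),
                    feature = rep(colnames(ni), each = nrow(ni)),
                    value = as.vector(ni),
                    retained = as.vector(report$retained_flags))
  dfh$feature <- factor(dfh$feature, levels = colnames(ni))
  heatmap <- ggplot2::ggplot(dfh, ggplot2::aes(
    x = .data$method, y = .data$feature, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$retained, "*", "")), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "normalized\nimportance") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8)
  dfs <- data.frame(feature = names(report$avg_importance),
                    avg = report$avg_importance,
                    freq = report$retention_frequency)
  scatter <- ggplot2::ggplot(dfs, ggplot2::aes(
    x = .data$avg, y = .data$freq, label = .data$feature)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 2.5) +
    ggplot2::labs(x = "average normalized importance",
                  y = "retention frequency") +
    ggplot2::theme_minimal()
  list(heatmap = heatmap, scatter = scatter)
}
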