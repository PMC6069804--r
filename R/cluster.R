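#' Correlation distance between outcomes
#'
#' D_jk = sqrt(1 - R_jk^2), where R_jk is the sample Pearson correlation of
#' the two log-concentration columns over pairwise-complete subjects. The
#' distance is blind to the sign of the correlation, so strongly positively
#' and strongly negatively coupled metabolites are both "close".
#'
#' @param log_outcomes numeric matrix, subjects x outcomes, of
#'   log concentrations (column names are the outcome ids).
#' @return symmetric outcome x outcome distance matrix with zero diagonal.
#' @export
correlation_distance <- function(log_outcomes) {
  log_outcomes <- as.matrix(log_outcomes)
  if (ncol(log_outcomes) < 2L) stop("need at least 2 outcomes")
  if (nrow(log_outcomes) < 3L) stop("need at least 3 subjects")
  v <- apply(log_outcomes, 2, stats::var, na.rm = TRUE)
  if (any(!is.finite(v)) || any(v == 0)) {
    bad <- colnames(log_outcomes)[!is.finite(v) | v == 0]
    stop("zero-variance outcome(s): ", paste(bad, collapse = ", "))
  }
  R <- stats::cor(log_outcomes, use = "pairwise.complete.obs")
  D <- 1 - R^2
  D[D < 0] <- 0
  D <- sqrt(D)
  diag(D) <- 0
  D
}

#' Ward clustering of outcomes at a chosen number of clusters
#'
#' Agglomerative hierarchical clustering of the precomputed correlation
#' distances with the squared-update Ward criterion (`hclust` method
#' `"ward.D2"`), cut to exactly `k` clusters. Only the partition (not the
#' merge heights) feeds the downstream enrichment analysis. Optional manual
#' overrides reassign named outcomes after the cut, mirroring the occasional
#' curation of a metabolite whose correlation pattern straddles clusters.
#'
#' @param distance matrix from [correlation_distance()].
#' @param k number of clusters, 1 <= k <= number of outcomes.
#' @param overrides optional named integer vector: outcome id -> cluster
#'   label to force after cutting.
#' @return list of class `cluster_assignment`: `labels` (named integer
#'   vector outcome -> cluster in 1..k), `k`, `tree` (the `hclust` object),
#'   `order` (leaf order, for heatmap-style displays).
#' @export
ward_cluster <- function(distance, k, overrides = NULL) {
  distance <- as.matrix(distance)
  n <- ncol(distance)
  if (k < 1 || k > n) stop("k must lie in 1..", n)
  hc <- stats::hclust(stats::as.dist(distance), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(labels))
    if (length(unknown)) stop("override for unknown outcome(s): ",
                              paste(unknown, collapse = ", "))
    labels[names(overrides)] <- as.integer(overrides)
  }
  structure(list(labels = labels, k = as.integer(k), tree = hc,
                 order = hc$order),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Ward clustering:", length(x$labels), "outcomes in", x$k, "clusters\n")
  print(table(x$labels))
  invisible(x)
}
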