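#' Signed significance summary of per-outcome MR results
#'
#' For each outcome the signed score is sign(estimate) * (-log10 p); an
#' outcome is flagged significant when p <= alpha (two-sided, unadjusted —
#' with many strongly correlated outcomes a family-wise adjustment would be
#' neither interpretable nor intended here). Underflowed p-values are
#' clamped to the smallest positive double.
#'
#' @param mr_results data.frame with one row per outcome and columns
#'   `outcome_id`, `estimate`, `p`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame `outcome_id`, `sign`, `p`, `signed_score`,
#'   `significant`.
#' @export
signed_significance <- function(mr_results, alpha = 0.05) {
  stopifnot(all(c("outcome_id", "estimate", "p") %in% names(mr_results)))
  if (anyDuplicated(mr_results$outcome_id)) {
    stop("one MR result per outcome is required")
  }
  p <- mr_results$p
  clamped <- !is.na(p) & p <= 0
  if (any(clamped)) {
    warning(sum(clamped), " p-value(s) at or below 0 clamped to double.xmin")
    p[clamped] <- .Machine$double.xmin
  }
  sgn <- ifelse(mr_results$estimate < 0, -1L, 1L)
  data.frame(outcome_id = mr_results$outcome_id,
             sign = sgn, p = p,
             signed_score = sgn * (-log10(p)),
             significant = p <= alpha,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: with p-values sorted ascending,
#' q_(i) = min over j >= i of m p_(j) / j, capped at 1 and returned in the
#' original order.
#'
#' @param p_list numeric vector of p-values in (0, 1].
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_list) {
  if (!length(p_list)) return(numeric(0))
  if (any(!is.finite(p_list)) || any(p_list <= 0) || any(p_list > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_list, method = "BH")
}

#' Cluster-level enrichment and depletion of significant causal effects
#'
#' For each cluster, the 2x2 table of significant/non-significant outcomes
#' inside/outside the cluster is summarised by one-sided hypergeometric tail
#' probabilities (equivalently, one-sided Fisher tests with the margins
#' fixed): with X ~ Hypergeometric(N, K, n_c) for N outcomes, K significant
#' overall and cluster size n_c, p_enrich = P(X >= a) and
#' p_deplete = P(X <= a) where a is the observed count of significant
#' outcomes in the cluster. Benjamini-Hochberg adjustment is applied across
#' clusters separately within each direction.
#'
#' @param significance data.frame from [signed_significance()].
#' @param clusters a `cluster_assignment` from [ward_cluster()], or a named
#'   vector outcome id -> cluster label.
#' @return data.frame with one row per cluster: `cluster`, `n_outcomes`,
#'   `a` (significant in cluster), `b`, `c`, `d` (rest of the 2x2 table),
#'   `p_enrich`, `p_deplete`, `q_enrich`, `q_deplete`.
#' @export
cluster_enrichment <- function(significance, clusters) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels else clusters
  if (is.null(names(labels))) stop("cluster labels must be named by outcome id")
  if (!setequal(names(labels), significance$outcome_id)) {
    stop("significance table and clustering cover different outcomes")
  }
  sig <- stats::setNames(significance$significant, significance$outcome_id)
  sig <- sig[names(labels)]
  N <- length(labels)
  K <- sum(sig)
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    inside <- labels == cl
    nc <- sum(inside)
    if (nc == 0L) {
      warning("empty cluster ", cl, " skipped")
      return(NULL)
    }
    a <- sum(sig[inside])
    data.frame(cluster = cl, n_outcomes = nc, a = a, b = nc - a,
               c = K - a, d = (N - nc) - (K - a),
               p_enrich = stats::phyper(a - 1, K, N - K, nc, lower.tail = FALSE),
               p_deplete = stats::phyper(a, K, N - K, nc),
               stringsAsFactors = FALSE)
  }))
  out$q_enrich <- bh_adjust(out$p_enrich)
  out$q_deplete <- bh_adjust(out$p_deplete)
  rownames(out) <- NULL
  out
}
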