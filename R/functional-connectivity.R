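#' Pairwise Pearson correlation matrix of node signals
#'
#' Correlations are computed on the post-transient window of each signal;
#' the diagonal is set to 0 so downstream edge ranking considers only
#' distinct pairs.  Zero-variance channels get zero correlations (with a
#' warning) instead of `NA`.
#'
#' @param signals numeric matrix, samples x nodes (typically the SLE
#'   observable from [sle_signal()]).
#' @param transient_fraction fraction of leading samples discarded.
#' @return Symmetric correlation matrix with zero diagonal.
#' @export
correlation_matrix <- function(signals, transient_fraction = 1 / 6) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 2) stop("need at least 2 nodes")
  first <- floor(nrow(signals) * transient_fraction) + 1L
  if (nrow(signals) - first + 1L < 100)
    stop("fewer than 100 post-transient samples")
  w <- signals[first:nrow(signals), , drop = FALSE]
  sds <- apply(w, 2, stats::sd)
  dead <- sds == 0
  if (any(dead))
    warning(sprintf("%d zero-variance channel(s); their correlations set to 0",
                    sum(dead)))
  cm <- suppressWarnings(cor(w))
  cm[is.na(cm)] <- 0
  if (any(dead)) { cm[dead, ] <- 0; cm[, dead] <- 0 }
  diag(cm) <- 0
  cm
}

#' Proportional thresholding of a correlation matrix
#'
#' Ranks all upper-triangle values descending by signed correlation and
#' keeps the strongest `round(fraction * n(n-1)/2)` as the edges of a
#' binary functional network.  Ties at the cut are broken by smaller row
#' index, then smaller column index, so the result is deterministic.
#'
#' @param corr symmetric correlation matrix (zero diagonal).
#' @param fraction fraction of possible edges kept, in (0, 1\\]; the
#'   conventional figure for these analyses is 0.275.
#' @param rank_by `"signed"` (default) ranks by the raw correlation;
#'   `"absolute"` ranks by magnitude.
#' @return An `epi_funnet`: list with `n`, binary `adjacency`,
#'   `kept_fraction`, and the `source_correlations`.
#' @export
threshold_top_fraction <- function(corr, fraction = 0.275,
                                   rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  corr <- as.matrix(corr)
  n <- nrow(corr)
  stopifnot(ncol(corr) == n, n >= 2)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  vals <- corr[ut]
  key <- if (rank_by == "signed") vals else abs(vals)
  ord <- order(-key, ut[, 1], ut[, 2])
  n_keep <- round(fraction * nrow(ut))
  keep <- ord[seq_len(n_keep)]
  adj <- matrix(0L, n, n)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(list(n = n, adjacency = adj, kept_fraction = fraction,
                 source_correlations = corr),
            class = "epi_funnet")
}

#' @export
print.epi_funnet <- function(x, ...) {
  cat(sprintf("Functional network: %d nodes, %d edges (top %.1f%%)\n",
              x$n, sum(x$adjacency[upper.tri(x$adjacency)]),
              100 * x$kept_fraction))
  invisible(x)
}

#' Average degree of a node subset
#'
#' Mean degree over the subset; with `normalized = TRUE` (default) the
#' mean is divided by `n - 1`, so a complete graph scores 1 and, in a
#' homogeneous focal network, the focal nodes sit near the lesion
#' proportion.
#'
#' @param net an `epi_funnet` or a binary adjacency matrix.
#' @param subset node indices; must be non-empty.
#' @param normalized divide by `n - 1`?
#' @return Mean (normalized) degree.
#' @export
average_degree <- function(net, subset = NULL, normalized = TRUE) {
  adj <- if (inherits(net, "epi_funnet")) net$adjacency else as.matrix(net)
  n <- nrow(adj)
  if (is.null(subset)) subset <- seq_len(n)
  if (!length(subset)) stop("subset must be non-empty")
  deg <- rowSums(adj)[subset]
  m <- mean(deg)
  if (normalized) m / (n - 1) else m
}
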