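#' Rank-product aggregation across normalization branches
#'
#' Combines per-branch gene statistics for one contrast into an
#' aggregate effect (aLog2FC, the arithmetic mean of per-branch log2
#' fold-changes), an aggregate rank (aRank, the geometric mean of
#' per-branch significance ranks) and a consensus significance call.
#' Within each branch genes are ranked ascending by p-value (rank 1 =
#' most significant; ties receive average ranks). Sorting by aRank is
#' equivalent to sorting by the product of ranks.
#'
#' @param branches named list of per-branch data frames as returned by
#'   \code{\link{branch_stats}}; all must cover the same gene set in
#'   the same order for one contrast.
#' @param alpha significance level applied per branch (default 0.05).
#' @param gate consensus rule: \code{"all"} (q < alpha in every branch;
#'   default, conservative), \code{"any"}, or \code{"median"}
#'   (median branch q < alpha).
#' @return data frame of class \code{"aggregate_stats"} with columns
#'   gene_id, a_log2fc, a_rank, significant, plus per-branch
#'   \code{log2fc.<branch>} and \code{q.<branch>} columns.
#' @export
aggregate_branches <- function(branches, alpha = 0.05,
                               gate = c("all", "any", "median")) {
  gate <- match.arg(gate)
  if (length(branches) < 1) stopf("need at least one branch")
  if (is.null(names(branches)) || any(names(branches) == ""))
    names(branches) <- paste0("branch", seq_along(branches))
  ids <- branches[[1]]$gene_id
  for (b in branches) {
    if (!identical(b$gene_id, ids))
      stopf("branches cover different gene sets")
    if (!all(c("log2fc", "p", "q") %in% names(b)))
      stopf("each branch needs log2fc, p and q columns")
  }
  fc <- vapply(branches, function(b) b$log2fc, numeric(length(ids)))
  qs <- vapply(branches, function(b) b$q, numeric(length(ids)))
  ranks <- vapply(branches,
                  function(b) rank(b$p, ties.method = "average"),
                  numeric(length(ids)))
  fc <- matrix(fc, nrow = length(ids))
  qs <- matrix(qs, nrow = length(ids))
  ranks <- matrix(ranks, nrow = length(ids))
  a_log2fc <- rowMeans(fc)
  a_rank <- exp(rowMeans(log(ranks)))
  significant <- switch(gate,
    all    = rowSums(qs < alpha) == ncol(qs),
    any    = rowSums(qs < alpha) > 0,
    median = apply(qs, 1, stats::median) < alpha)
  out <- data.frame(gene_id = ids, a_log2fc = a_log2fc, a_rank = a_rank,
                    significant = significant, row.names = NULL)
  for (nm in names(branches)) {
    out[[paste0("log2fc.", nm)]] <- branches[[nm]]$log2fc
    out[[paste0("q.", nm)]] <- branches[[nm]]$q
  }
  attr(out, "alpha") <- alpha
  attr(out, "gate") <- gate
  attr(out, "branches") <- names(branches)
  class(out) <- c("aggregate_stats", "data.frame")
  out
}
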