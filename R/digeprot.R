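#' DIGE spot-abundance table
#'
#' Spot abundances standardized to an internal-standard channel, with
#' per-sample metadata. Abundances must be positive (ratios to the
#' internal standard); statistics require at least two technical
#' replicates per condition.
#'
#' @param abundance numeric matrix, spots x samples, all values > 0.
#' @param samples data frame with columns sample_id, strain
#'   (WT/MUT), confrontation (SELF/HOST), replicate.
#' @param protein_id optional character vector mapping spots to
#'   proteins (proteoforms of one protein share a protein_id).
#' @param phospho optional logical flag per spot.
#' @return object of class \code{"spot_table"}.
#' @export
spot_table <- function(abundance, samples, protein_id = NULL,
                       phospho = NULL) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stopf("abundance must be a numeric matrix")
  if (any(abundance <= 0)) stopf("abundances must be positive")
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("spot", seq_len(nrow(abundance)))
  req <- c("sample_id", "strain", "confrontation", "replicate")
  if (!all(req %in% names(samples)))
    stopf("samples must have columns: %s", paste(req, collapse = ", "))
  if (ncol(abundance) != nrow(samples))
    stopf("abundance columns and sample rows differ")
  if (is.null(colnames(abundance))) colnames(abundance) <- samples$sample_id
  samples <- samples[match(colnames(abundance), samples$sample_id), ,
                     drop = FALSE]
  samples$strain <- toupper(as.character(samples$strain))
  samples$confrontation <- toupper(as.character(samples$confrontation))
  samples$group <- group_of(samples$strain, samples$confrontation)
  rownames(samples) <- NULL
  if (!is.null(protein_id) && length(protein_id) != nrow(abundance))
    stopf("protein_id length must equal number of spots")
  structure(list(abundance = abundance, samples = samples,
                 protein_id = protein_id %||% rownames(abundance),
                 phospho = phospho),
            class = "spot_table")
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d spots x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  print(table(x$samples$group))
  invisible(x)
}

#' Spot-level differential abundance between two conditions
#'
#' For each spot the ratio r = mean(A)/mean(B) of raw abundances is
#' reported as an average ratio with the +/-1 sign convention (AR = r
#' if r >= 1, else -1/r; no AR values fall in (-1, 1)) together with
#' log2fc = log2(r). P-values come from a two-sample Student's t-test
#' (pooled variance) on the log2 replicate values. A spot is flagged
#' when |AR| >= 1.5 and p < 0.05.
#'
#' @param table a \code{\link{spot_table}}.
#' @param comparison length-2 character vector of condition (group)
#'   names, e.g. \code{c("WT_HOST", "WT_SELF")}; each must have >= 2
#'   replicates.
#' @param ar_gate,p_gate the flagging thresholds (defaults 1.5, 0.05).
#' @return data frame: spot_id, protein_id, mean_a, mean_b, AR,
#'   log2fc, p, flagged.
#' @export
spot_differential <- function(table, comparison,
                              ar_gate = 1.5, p_gate = 0.05) {
  stopifnot(inherits(table, "spot_table"), length(comparison) == 2)
  grp <- table$samples$group
  a <- grp == comparison[1]
  b <- grp == comparison[2]
  if (sum(a) < 2 || sum(b) < 2)
    stopf("both conditions need >= 2 replicates")
  la <- log2(table$abundance[, a, drop = FALSE])
  lb <- log2(table$abundance[, b, drop = FALSE])
  mean_a <- rowMeans(table$abundance[, a, drop = FALSE])
  mean_b <- rowMeans(table$abundance[, b, drop = FALSE])
  r <- mean_a / mean_b
  ar <- ifelse(r >= 1, r, -1 / r)
  log2fc <- log2(r)
  p <- vapply(seq_len(nrow(la)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    stats::t.test(xa, xb, var.equal = TRUE)$p.value
  }, numeric(1))
  data.frame(spot_id = rownames(table$abundance),
             protein_id = table$protein_id,
             mean_a = mean_a, mean_b = mean_b,
             AR = ar, log2fc = log2fc, p = p,
             flagged = abs(ar) >= ar_gate & p < p_gate,
             row.names = NULL)
}

#' Two-way ANOVA (strain x confrontation) per spot
#'
#' Fits, on log2 abundances, both the model with interaction and the
#' additive model, spot-wise. All four conditions must be present.
#'
#' @param table a \code{\link{spot_table}} with all four conditions.
#' @return data frame: spot_id, p_strain, p_confrontation,
#'   p_interaction (interaction model) and p_strain_add,
#'   p_confrontation_add (additive model).
#' @export
spot_anova <- function(table) {
  stopifnot(inherits(table, "spot_table"))
  s <- table$samples
  if (!all(GROUP_LEVELS %in% s$group))
    stopf("two-way ANOVA needs all four conditions")
  strain <- factor(s$strain)
  conf <- factor(s$confrontation)
  res <- t(vapply(seq_len(nrow(table$abundance)), function(i) {
    y <- log2(table$abundance[i, ])
    # zero-residual spots (e.g. noise-free simulations) trigger a
    # "perfect fit" warning per spot; the NaN p-values they produce are
    # the correct degenerate answer, so silence just that warning
    withCallingHandlers({
      full <- stats::anova(stats::lm(y ~ strain * conf))
      add <- stats::anova(stats::lm(y ~ strain + conf))
    }, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
    c(full[["Pr(>F)"]][1:3], add[["Pr(>F)"]][1:2])
  }, numeric(5)))
  data.frame(spot_id = rownames(table$abundance),
             p_strain = res[, 1], p_confrontation = res[, 2],
             p_interaction = res[, 3],
             p_strain_add = res[, 4], p_confrontation_add = res[, 5],
             row.names = NULL)
}

#' Proteome second-level response difference
#'
#' D = mutant response log2fc minus WT response log2fc, per protein;
#' negative values mean the protein's host response is reduced in the
#' mutant (same sign convention as the transcript second-level
#' contrast).
#'
#' @param wt_resp_log2fc,mut_resp_log2fc named numeric vectors (names
#'   are protein/spot ids) over the same protein set.
#' @return named numeric vector of differences.
#' @export
response_difference <- function(wt_resp_log2fc, mut_resp_log2fc) {
  if (is.null(names(wt_resp_log2fc)) || is.null(names(mut_resp_log2fc)) ||
      !identical(names(wt_resp_log2fc), names(mut_resp_log2fc)))
    stopf("protein sets of the two responses do not match")
  mut_resp_log2fc - wt_resp_log2fc
}

#' Filter profiles for clustering
#'
#' Keeps rows with |log2fc| above the cutoff in at least one
#' comparison column.
#'
#' @param profiles numeric matrix, proteins x comparisons.
#' @param cutoff absolute log2fc cutoff (default 1.5, strict).
#' @return the filtered matrix.
#' @export
filter_profiles <- function(profiles, cutoff = 1.5) {
  keep <- apply(abs(profiles) > cutoff, 1, any)
  profiles[keep, , drop = FALSE]
}

#' Hierarchical clustering of abundance profiles
#'
#' Agglomerative clustering with Euclidean distance and average
#' linkage; the dendrogram is cut into k clusters and cluster indices
#' are relabelled in increasing order of the cluster mean of the first
#' profile column, so labels are deterministic.
#'
#' @param profiles numeric matrix of (filtered) log2fc profiles,
#'   proteins x comparisons, with row names.
#' @param k number of clusters (default 7, matching heatmap groups
#'   I-VII).
#' @return list with \code{cluster} (named integer vector),
#'   \code{hclust} (the tree), and \code{order} (dendrogram leaf
#'   order).
#' @export
cluster_proteins <- function(profiles, k = 7) {
  if (k < 1) stopf("k must be >= 1")
  if (k > nrow(profiles)) stopf("k exceeds number of proteins")
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = "average")
  raw <- stats::cutree(hc, k = k)
  means <- tapply(profiles[, 1], raw, mean)
  relabel <- match(seq_len(k), order(means))
  cl <- relabel[raw]
  names(cl) <- rownames(profiles)
  list(cluster = cl, hclust = hc, order = hc$order)
}

#' Protein-level roll-up over proteoform spots
#'
#' Multiple spots mapping to one protein are kept as separate rows in
#' spot statistics; this helper reports, per protein, the proteoform
#' with the largest |log2fc|.
#'
#' @param stats data frame with columns protein_id and log2fc (e.g.
#'   from \code{\link{spot_differential}}).
#' @return data frame with one row per protein.
#' @export
rollup_proteins <- function(stats) {
  stopifnot(all(c("protein_id", "log2fc") %in% names(stats)))
  idx <- vapply(split(seq_len(nrow(stats)), stats$protein_id),
                function(i) i[which.max(abs(stats$log2fc[i]))],
                integer(1))
  out <- stats[idx, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$protein_id), , drop = FALSE]
}
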