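#' Regulatory-mode labels
#'
#' Named modes for genes that respond robustly differently between the
#' wild type and the mutant. The family prefix follows the sign of the
#' second-level contrast D (mutant response minus WT response):
#' \code{DOWN.*} (D <= -tau_strong) marks responses lost or reduced in
#' the mutant, hence a stimulating role of the kinase; \code{UP.*}
#' (D >= +tau_strong) marks responses gained or increased in the
#' mutant, hence a suppressing role. The infixes describe each strain's
#' own host response: Up / Down (strong, |r| >= tau_strong), Rbt
#' ("regulated below threshold", |r| <= tau_rbt). Genes whose second
#' level is weak or non-significant are NOT_ROBUST; robust genes with a
#' response in the unnamed band tau_rbt < |r| < tau_strong (or in a
#' combination with no named mode) are MIXED.
#'
#' @format character vectors of mode names.
#' @export
DOWN_MODES <- c("DOWN.UpWT.DownMut", "DOWN.DownWT.DownMut",
                "DOWN.RbtWT.DownMut", "DOWN.UpWT.RbtMut")

#' @rdname DOWN_MODES
#' @export
UP_MODES <- c("UP.DownWT.UpMut", "UP.UpWT.UpMut",
              "UP.DownWT.RbtMut", "UP.RbtWT.UpMut")

#' @rdname DOWN_MODES
#' @export
MODE_LABELS <- c(DOWN_MODES, UP_MODES, "NOT_ROBUST", "MIXED")

#' Classification thresholds
#'
#' @param tau_strong strong-regulation threshold on |aLog2FC|, log2
#'   units (default 2).
#' @param tau_rbt regulated-below-threshold band on |aLog2FC|, log2
#'   units (default 1); must satisfy tau_strong > tau_rbt > 0.
#' @param alpha significance level for the consensus gate (default
#'   0.05).
#' @return object of class \code{"thresholds"}.
#' @export
thresholds <- function(tau_strong = 2, tau_rbt = 1, alpha = 0.05) {
  if (!(tau_strong > tau_rbt && tau_rbt > 0))
    stopf("need tau_strong > tau_rbt > 0")
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0,1)")
  structure(list(tau_strong = tau_strong, tau_rbt = tau_rbt,
                 alpha = alpha), class = "thresholds")
}

#' Second-level contrast by subtraction of aggregate responses
#'
#' D = aLog2FC(mutant response) - aLog2FC(WT response). Negative D
#' means the mutant's host response is lower than the wild type's.
#' Because contrasts and branch aggregation are linear, this equals the
#' directly fitted (+1, -1, -1, +1) contrast aggregated over the same
#' branches.
#'
#' @param wt,mut \code{aggregate_stats} for the WT_RESPONSE and
#'   MUT_RESPONSE contrasts over the same gene set.
#' @return data frame gene_id, wt_response, mut_response, D.
#' @export
second_level <- function(wt, mut) {
  if (!identical(wt$gene_id, mut$gene_id))
    stopf("WT and mutant aggregates cover different gene sets")
  data.frame(gene_id = wt$gene_id,
             wt_response = wt$a_log2fc,
             mut_response = mut$a_log2fc,
             D = mut$a_log2fc - wt$a_log2fc,
             row.names = NULL)
}

bucket_response <- function(r, th) {
  ifelse(r >= th$tau_strong, "UP",
    ifelse(r <= -th$tau_strong, "DOWN",
      ifelse(abs(r) <= th$tau_rbt, "RBT", "INTERMEDIATE")))
}

#' Assign regulatory modes
#'
#' A gene is NOT_ROBUST unless |D| >= tau_strong and (when
#' \code{gate_significance} is TRUE, the default) D is
#' consensus-significant. Robust genes are bucketed by their per-strain
#' responses (Up / Down / Rbt / intermediate) and mapped to the named
#' mode matching the sign of D; DOWN.DownWT.DownMut additionally
#' requires the mutant to be the more strongly downregulated strain
#' (automatic when D < 0), symmetrically for UP.UpWT.UpMut. Any
#' intermediate bucket, or a bucket combination with no named mode,
#' yields MIXED.
#'
#' @param wt_r,mut_r per-gene aggregate log2 responses of the two
#'   strains.
#' @param D per-gene second-level contrast values.
#' @param significant logical vector: consensus significance of D.
#'   Ignored when \code{gate_significance = FALSE}.
#' @param th a \code{\link{thresholds}} object.
#' @param gate_significance require D to be significant for a named
#'   mode (default TRUE).
#' @return factor of \code{MODE_LABELS}, one per gene.
#' @export
classify_modes <- function(wt_r, mut_r, D, significant = NULL,
                           th = thresholds(), gate_significance = TRUE) {
  n <- length(D)
  stopifnot(length(wt_r) == n, length(mut_r) == n)
  if (gate_significance) {
    if (is.null(significant)) stopf("significance gate needs a 'significant' vector")
    stopifnot(length(significant) == n)
  } else significant <- rep(TRUE, n)
  lab <- rep("NOT_ROBUST", n)
  robust <- abs(D) >= th$tau_strong & significant
  wb <- bucket_response(wt_r, th)
  mb <- bucket_response(mut_r, th)
  key <- paste(ifelse(D < 0, "DOWN", "UP"), wb, mb, sep = ":")
  map <- c(
    "DOWN:UP:DOWN"  = "DOWN.UpWT.DownMut",
    "DOWN:DOWN:DOWN" = "DOWN.DownWT.DownMut",
    "DOWN:RBT:DOWN" = "DOWN.RbtWT.DownMut",
    "DOWN:UP:RBT"   = "DOWN.UpWT.RbtMut",
    "UP:DOWN:UP"    = "UP.DownWT.UpMut",
    "UP:UP:UP"      = "UP.UpWT.UpMut",
    "UP:DOWN:RBT"   = "UP.DownWT.RbtMut",
    "UP:RBT:UP"     = "UP.RbtWT.UpMut")
  named <- unname(map[key])
  named[is.na(named)] <- "MIXED"
  # both-strong modes additionally require the mutant to be the more
  # extreme strain; implied by the sign of D, made explicit here
  named[named == "DOWN.DownWT.DownMut" & !(mut_r < wt_r)] <- "MIXED"
  named[named == "UP.UpWT.UpMut" & !(mut_r > wt_r)] <- "MIXED"
  lab[robust] <- named[robust]
  factor(lab, levels = MODE_LABELS)
}

#' Summarize mode assignments
#'
#' Counts per named mode and the roll-up percentages over the robust
#' set (named modes only; NOT_ROBUST and MIXED are reported separately
#' and excluded from the denominator): the stimulating family
#' (\code{DOWN.*}), the suppressing family (\code{UP.*}), genes
#' strongly regulated in both strains (both-strong, as a share of the
#' stimulating family), genes that lost their WT upregulation
#' (UpWT modes of the DOWN family), and genes newly downregulated only
#' in the mutant (DOWN.RbtWT.DownMut). Percentages are rounded half-up
#' to integers; when a denominator is zero the percentage is NA.
#'
#' @param labels factor/character vector of \code{MODE_LABELS}.
#' @return object of class \code{"mode_summary"} (a list).
#' @export
summarize_modes <- function(labels) {
  labels <- factor(as.character(labels), levels = MODE_LABELS)
  if (anyNA(labels)) stopf("unknown mode label(s)")
  counts <- table(labels)
  named <- counts[c(DOWN_MODES, UP_MODES)]
  n_robust <- sum(named)
  stim <- sum(counts[DOWN_MODES])
  supp <- sum(counts[UP_MODES])
  both_strong <- sum(counts[c("DOWN.UpWT.DownMut", "DOWN.DownWT.DownMut")])
  lost_up <- sum(counts[c("DOWN.UpWT.DownMut", "DOWN.UpWT.RbtMut")])
  newly_down <- unname(counts["DOWN.RbtWT.DownMut"])
  pct <- function(x, denom) if (denom > 0) round_half_up(100 * x / denom)
                            else NA_real_
  structure(list(
    counts = counts,
    n_robust = n_robust,
    n_not_robust = unname(counts["NOT_ROBUST"]),
    n_mixed = unname(counts["MIXED"]),
    mode_percent = vapply(names(named), function(m)
      pct(counts[[m]], n_robust), numeric(1)),
    stimulating_count = stim,
    stimulating_percent = pct(stim, n_robust),
    suppressing_count = supp,
    suppressing_percent = pct(supp, n_robust),
    both_strong_of_stimulating_count = both_strong,
    both_strong_of_stimulating_percent = pct(both_strong, stim),
    lost_upregulation_count = lost_up,
    lost_upregulation_percent = pct(lost_up, n_robust),
    newly_down_count = newly_down,
    newly_down_percent = pct(newly_down, n_robust)
  ), class = "mode_summary")
}

#' @export
print.mode_summary <- function(x, ...) {
  cat(sprintf("robust genes: %d (+ %d not robust, %d mixed)\n",
              x$n_robust, x$n_not_robust, x$n_mixed))
  for (m in c(DOWN_MODES, UP_MODES))
    if (x$counts[[m]] > 0)
      cat(sprintf("  %-20s %4d (%s%%)\n", m, x$counts[[m]],
                  x$mode_percent[[m]]))
  cat(sprintf("stimulating (DOWN.*): %d (%s%%)\n",
              x$stimulating_count, x$stimulating_percent))
  cat(sprintf("suppressing (UP.*):   %d (%s%%)\n",
              x$suppressing_count, x$suppressing_percent))
  cat(sprintf("both-strong of stimulating: %d (%s%%)\n",
              x$both_strong_of_stimulating_count,
              x$both_strong_of_stimulating_percent))
  invisible(x)
}

#' Fraction of robust genes carrying an annotation flag
#'
#' @param labels mode labels per gene.
#' @param flags logical vector aligned with \code{labels}.
#' @return list with \code{count} and \code{percent} (of the robust
#'   set, rounded half-up).
#' @export
flag_fraction <- function(labels, flags) {
  labels <- as.character(labels)
  if (length(labels) != length(flags)) stopf("length mismatch")
  robust <- labels %in% c(DOWN_MODES, UP_MODES)
  n_robust <- sum(robust)
  count <- sum(flags[robust])
  list(count = count,
       percent = if (n_robust > 0) round_half_up(100 * count / n_robust)
                 else NA_real_)
}

#' Up/down split of a single-strain response summary
#'
#' @param n_up,n_down counts of strongly up- and downregulated genes.
#' @return list with counts, total and integer percentages (half-up).
#' @export
direction_summary <- function(n_up, n_down) {
  total <- n_up + n_down
  if (total <= 0) stopf("need at least one regulated gene")
  list(n_up = n_up, n_down = n_down, total = total,
       up_percent = round_half_up(100 * n_up / total),
       down_percent = round_half_up(100 * n_down / total))
}

#' Expand per-mode counts into a label vector
#'
#' Convenience for fixture arithmetic: turn a named count table (e.g.
#' published group sizes) into a vector of labels suitable for
#' \code{\link{summarize_modes}}.
#'
#' @param counts named integer vector; names must be MODE_LABELS.
#' @return character vector of labels.
#' @export
labels_from_counts <- function(counts) {
  if (is.null(names(counts)) || !all(names(counts) %in% MODE_LABELS))
    stopf("counts must be named by mode labels")
  rep(names(counts), times = counts)
}
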