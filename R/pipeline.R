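#' Run configuration
#'
#' A single validated configuration object driving the end-to-end
#' transcriptome and proteome pipelines. Data come either from a
#' \code{\link{synthetic_config}} or from TSV paths. All analysis
#' defaults are surfaced here: strong/Rbt thresholds 2 and 1 (log2),
#' significance q < 0.05 under Benjamini-Yekutieli, average-ratio gate
#' 1.5 at p < 0.05, enrichment FDR 0.05, intersection alpha 0.05.
#'
#' @param synthetic a \code{\link{synthetic_config}}, or NULL.
#' @param matrix_path,design_path,annotation_path TSV paths for user
#'   data (used when \code{synthetic} is NULL).
#' @param spots_path,spot_design_path TSV paths for a user proteome
#'   spot table.
#' @param normalizations character vector of registered normalization
#'   methods; at least 2 for a meaningful meta-ranking.
#' @param thresholds a \code{\link{thresholds}} object.
#' @param gate consensus gate for branch significance
#'   ("all"/"any"/"median").
#' @param adjust "BY" (default) or "BH".
#' @param enrich_alpha FDR level for term enrichment reporting.
#' @param intersect_alpha p-value level for intersection-network
#'   inclusion.
#' @param ar_gate,ar_p_gate DIGE average-ratio and p gates.
#' @param cluster_k,cluster_cutoff proteome clustering parameters.
#' @param out_dir output directory for TSV/JSON tables (NULL = do not
#'   write).
#' @param seed integer seed (used when \code{synthetic} carries no
#'   seed of its own).
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(synthetic = NULL, matrix_path = NULL,
                       design_path = NULL, annotation_path = NULL,
                       spots_path = NULL, spot_design_path = NULL,
                       normalizations = default_normalizations(),
                       thresholds = dualresponse::thresholds(),
                       gate = "all", adjust = "BY",
                       enrich_alpha = 0.05, intersect_alpha = 0.05,
                       ar_gate = 1.5, ar_p_gate = 0.05,
                       cluster_k = 7, cluster_cutoff = 1.5,
                       out_dir = NULL, seed = 1L) {
  if (is.null(synthetic) && (is.null(matrix_path) || is.null(design_path)))
    stopf("either a synthetic config or matrix/design paths are required")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config"))
    stopf("synthetic must be a synthetic_config")
  if (length(normalizations) < 1)
    stopf("need at least one normalization method")
  missing_norm <- setdiff(normalizations, normalization_methods())
  if (length(missing_norm))
    stopf("unknown normalization(s): %s",
          paste(missing_norm, collapse = ", "))
  stopifnot(inherits(thresholds, "thresholds"))
  gate <- match.arg(gate, c("all", "any", "median"))
  adjust <- match.arg(adjust, c("BY", "BH"))
  structure(list(synthetic = synthetic, matrix_path = matrix_path,
                 design_path = design_path,
                 annotation_path = annotation_path,
                 spots_path = spots_path,
                 spot_design_path = spot_design_path,
                 normalizations = normalizations,
                 thresholds = thresholds, gate = gate, adjust = adjust,
                 enrich_alpha = enrich_alpha,
                 intersect_alpha = intersect_alpha,
                 ar_gate = ar_gate, ar_p_gate = ar_p_gate,
                 cluster_k = cluster_k,
                 cluster_cutoff = cluster_cutoff,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Nested \code{synthetic} and \code{thresholds} blocks are passed to
#' \code{\link{synthetic_config}} and \code{\link{thresholds}}.
#'
#' @param path a .yaml/.yml or .json file.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$synthetic)) {
    if (!is.null(raw$synthetic$mode_proportions))
      raw$synthetic$mode_proportions <- unlist(raw$synthetic$mode_proportions)
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  if (!is.null(raw$thresholds))
    raw$thresholds <- do.call(thresholds, raw$thresholds)
  do.call(run_config, raw)
}

acquire_experiment <- function(config) {
  if (!is.null(config$synthetic))
    return(generate_experiment(config$synthetic))
  bundle <- read_bundle(config$matrix_path, config$design_path)
  annotation <- if (!is.null(config$annotation_path))
    read_tsv(config$annotation_path) else NULL
  spots <- NULL
  if (!is.null(config$spots_path)) {
    tab <- read_tsv(config$spots_path)
    meta <- read_tsv(config$spot_design_path)
    prot <- if ("protein_id" %in% names(tab)) tab$protein_id else NULL
    keep <- setdiff(names(tab), c("spot_id", "protein_id"))
    ab <- as.matrix(tab[, keep, drop = FALSE])
    rownames(ab) <- tab$spot_id
    spots <- spot_table(ab, meta, protein_id = prot)
  }
  list(bundle = bundle, annotation = annotation, truth = NULL,
       spots = spots)
}

#' Run the transcriptome pipeline
#'
#' Normalizes the expression bundle with every method in the bank,
#' computes per-branch moderated statistics for the WT response, the
#' mutant response and the directly fitted second-level contrast,
#' aggregates the branches (rank product), classifies regulatory modes
#' and summarizes them, and (when annotations are available) performs
#' term enrichment of the robust gene set plus the secreted-flag
#' chi-squared test of the stimulating vs suppressing families.
#'
#' @param config a \code{\link{run_config}}.
#' @return list with elements \code{report}, \code{aggregates} (per
#'   contrast), \code{modes} (per-gene table), \code{summary}
#'   (\code{mode_summary}), \code{enrichment}, \code{chi2_secreted},
#'   \code{experiment}.
#' @export
run_transcriptome <- function(config) {
  stopifnot(inherits(config, "run_config"))
  exper <- acquire_experiment(config)
  bundle <- exper$bundle
  th <- config$thresholds

  contrasts <- c("WT_RESPONSE", "MUT_RESPONSE", "SECOND_LEVEL")
  normalized <- lapply(config$normalizations,
                       function(nm) normalize_bundle(bundle, nm))
  names(normalized) <- config$normalizations
  aggregates <- lapply(contrasts, function(ct) {
    branches <- lapply(normalized, branch_stats, contrast = ct,
                       adjust = config$adjust)
    aggregate_branches(branches, alpha = th$alpha, gate = config$gate)
  })
  names(aggregates) <- contrasts

  sl <- second_level(aggregates$WT_RESPONSE, aggregates$MUT_RESPONSE)
  sl$significant <- aggregates$SECOND_LEVEL$significant
  sl$mode <- classify_modes(sl$wt_response, sl$mut_response, sl$D,
                            sl$significant, th)
  summary <- summarize_modes(sl$mode)

  enrichment <- NULL
  chi2_secreted <- NULL
  if (!is.null(exper$annotation)) {
    robust <- sl$gene_id[sl$mode %in% c(DOWN_MODES, UP_MODES)]
    if (length(robust) > 0)
      enrichment <- hypergeom_enrich(robust, exper$annotation)
    ann <- exper$annotation[match(sl$gene_id, exper$annotation$gene_id), ]
    stim <- sl$mode %in% DOWN_MODES
    supp <- sl$mode %in% UP_MODES
    tab <- rbind(stimulating = c(sum(ann$secreted == 1 & stim),
                                 sum(ann$secreted != 1 & stim)),
                 suppressing = c(sum(ann$secreted == 1 & supp),
                                 sum(ann$secreted != 1 & supp)))
    colnames(tab) <- c("secreted", "not_secreted")
    chi2_secreted <- tryCatch(contingency_chi2(tab),
                              error = function(e) list(chi2 = NA_real_,
                                                       p = NA_real_,
                                                       table = tab))
  }

  report <- list(
    stage = "transcriptome",
    n_genes = nrow(bundle$matrix),
    n_arrays = ncol(bundle$matrix),
    normalizations = config$normalizations,
    n_robust = summary$n_robust,
    mode_counts = as.list(summary$counts),
    n_enriched_terms = if (is.null(enrichment)) 0L
                       else sum(enrichment$q <= config$enrich_alpha),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dualresponse")))
  stopifnot(report$n_robust ==
              sum(sl$mode %in% c(DOWN_MODES, UP_MODES)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ct in contrasts)
      write_tsv(aggregates[[ct]],
                file.path(config$out_dir,
                          sprintf("aggregate_%s.tsv", tolower(ct))))
    write_tsv(sl, file.path(config$out_dir, "modes.tsv"))
    write_mode_summary(summary, config$out_dir)
    if (!is.null(enrichment))
      write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(report = report, aggregates = aggregates, modes = sl,
       summary = summary, enrichment = enrichment,
       chi2_secreted = chi2_secreted, experiment = exper)
}

write_mode_summary <- function(summary, dir) {
  counts <- as.data.frame(summary$counts)
  names(counts) <- c("mode", "count")
  write_tsv(counts, file.path(dir, "mode_summary.tsv"))
  out <- unclass(summary)
  out$counts <- as.list(stats::setNames(as.integer(summary$counts),
                                        names(summary$counts)))
  out$mode_percent <- as.list(out$mode_percent)
  jsonlite::write_json(out, file.path(dir, "mode_summary.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the proteome (DIGE) pipeline
#'
#' Computes spot-level differential abundance for every pairwise
#' comparison of the four conditions, two-way ANOVA, the second-level
#' response difference, the |log2fc| profile filter, and hierarchical
#' clustering of the filtered profiles.
#'
#' @param config a \code{\link{run_config}} whose data source carries
#'   a spot table.
#' @return list with elements \code{report}, \code{stats} (per
#'   comparison), \code{anova}, \code{profiles}, \code{response_diff},
#'   \code{clusters}.
#' @export
run_proteome <- function(config) {
  stopifnot(inherits(config, "run_config"))
  exper <- acquire_experiment(config)
  spots <- exper$spots
  if (is.null(spots) || nrow(spots$abundance) == 0) {
    warning("empty spot table; nothing to analyse")
    return(list(report = list(stage = "proteome", n_spots = 0L,
                              n_flagged = 0L, n_clustered = 0L,
                              n_clusters = 0L),
                stats = NULL, anova = NULL, profiles = NULL,
                response_diff = NULL, clusters = NULL))
  }
  pairs <- utils::combn(GROUP_LEVELS, 2, simplify = FALSE)
  stats <- lapply(pairs, function(pr)
    spot_differential(spots, c(pr[2], pr[1]),
                      ar_gate = config$ar_gate,
                      p_gate = config$ar_p_gate))
  names(stats) <- vapply(pairs, function(pr)
    paste(pr[2], "vs", pr[1]), character(1))
  anova <- spot_anova(spots)

  wt_resp <- stats[["WT_HOST vs WT_SELF"]]
  mut_resp <- stats[["MUT_HOST vs MUT_SELF"]]
  self_diff <- stats[["MUT_SELF vs WT_SELF"]]
  d_prot <- response_difference(
    stats::setNames(wt_resp$log2fc, wt_resp$spot_id),
    stats::setNames(mut_resp$log2fc, mut_resp$spot_id))
  profiles <- cbind(mut_response = mut_resp$log2fc,
                    wt_response = wt_resp$log2fc,
                    self_mut_vs_wt = self_diff$log2fc,
                    response_diff = d_prot)
  rownames(profiles) <- wt_resp$spot_id
  filtered <- filter_profiles(profiles, config$cluster_cutoff)
  clusters <- NULL
  if (nrow(filtered) >= 2) {
    k <- min(config$cluster_k, nrow(filtered))
    clusters <- cluster_proteins(filtered, k = k)
  }
  flagged <- unique(unlist(lapply(stats, function(s)
    s$spot_id[s$flagged]), use.names = FALSE))
  report <- list(stage = "proteome",
                 n_spots = nrow(spots$abundance),
                 n_flagged = length(flagged),
                 n_clustered = nrow(filtered),
                 n_clusters = if (is.null(clusters)) 0L
                              else length(unique(clusters$cluster)),
                 seed = config$seed,
                 package_version =
                   as.character(utils::packageVersion("dualresponse")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(stats))
      write_tsv(stats[[nm]],
                file.path(config$out_dir,
                          sprintf("spots_%s.tsv",
                                  gsub(" ", "_", tolower(nm)))))
    write_tsv(anova, file.path(config$out_dir, "spot_anova.tsv"))
    prof_tab <- data.frame(spot_id = rownames(profiles), profiles,
                           row.names = NULL)
    write_tsv(prof_tab, file.path(config$out_dir, "spot_profiles.tsv"))
    if (!is.null(clusters)) {
      leaf_order <- rownames(filtered)[clusters$order]
      heat <- data.frame(spot_id = leaf_order,
                         cluster = clusters$cluster[leaf_order],
                         filtered[leaf_order, , drop = FALSE],
                         row.names = NULL)
      write_tsv(heat, file.path(config$out_dir, "spot_clusters.tsv"))
    }
    jsonlite::write_json(report,
                         file.path(config$out_dir,
                                   "proteome_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(report = report, stats = stats, anova = anova,
       profiles = profiles, response_diff = d_prot,
       clusters = clusters)
}
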