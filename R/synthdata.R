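#' Default planted mode proportions
#'
#' Unregulated genes (NONE) dominate so that FDR experiments have a
#' null majority; the named modes are weighted roughly like the mode
#' mix observed in dual-confrontation experiments (the lost-WT-
#' upregulation modes are the most frequent).
#'
#' @return named numeric vector summing to 1.
#' @export
default_mode_proportions <- function() {
  c(NONE = 0.9,
    DOWN.UpWT.DownMut = 0.030, DOWN.UpWT.RbtMut = 0.012,
    DOWN.RbtWT.DownMut = 0.014, DOWN.DownWT.DownMut = 0.004,
    UP.DownWT.UpMut = 0.010, UP.UpWT.UpMut = 0.010,
    UP.DownWT.RbtMut = 0.010, UP.RbtWT.UpMut = 0.010)
}

#' Configuration for a synthetic dual-confrontation experiment
#'
#' Describes a four-group (WT/MUT x SELF/HOST) universal-reference
#' design with planted per-gene regulatory modes. Strong planted
#' responses have magnitude \code{effect_size}; "regulated below
#' threshold" (Rbt) responses are planted at +/- \code{rbt_effect},
#' strictly inside the |log2FC| <= 1 band, to exercise the band edge.
#' Array noise is i.i.d. Gaussian on the log2 ratios; an optional
#' per-array dye bias constant exercises normalization.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_replicates_per_group arrays per group (default 4).
#' @param mode_proportions named vector over \code{MODE_LABELS} names
#'   plus \code{NONE}, nonnegative, summing to 1.
#' @param effect_size magnitude of strong planted responses, log2
#'   units (default 3); must exceed \code{2 * rbt_effect} so planted
#'   modes are separable at zero noise.
#' @param rbt_effect magnitude of below-threshold responses (default
#'   0.5).
#' @param noise_sd sd of Gaussian array noise, log2 units (default
#'   0.25).
#' @param baseline_sd sd of per-gene baseline log2 ratios versus the
#'   universal reference (default 1).
#' @param dye_bias_sd sd of a per-array additive constant (default 0,
#'   i.e. off).
#' @param annotation_rates list with elements \code{secreted},
#'   \code{mitochondrial} (per-gene flag probabilities), \code{n_terms}
#'   and \code{term_rate} (toy ontology terms and their per-gene
#'   annotation probability).
#' @param protein_fraction fraction of genes mirrored as proteome
#'   spots with the same planted responses plus independent noise
#'   (default 0.1).
#' @param seed integer RNG seed.
#' @return object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_replicates_per_group = 4,
                             mode_proportions = default_mode_proportions(),
                             effect_size = 3,
                             rbt_effect = 0.5,
                             noise_sd = 0.25,
                             baseline_sd = 1.0,
                             dye_bias_sd = 0,
                             annotation_rates = list(secreted = 0.10,
                                                     mitochondrial = 0.09,
                                                     n_terms = 10,
                                                     term_rate = 0.08),
                             protein_fraction = 0.1,
                             seed = 1L) {
  if (n_genes < 1 || n_replicates_per_group < 1)
    stopf("n_genes and n_replicates_per_group must be positive")
  ok_modes <- c("NONE", DOWN_MODES, UP_MODES)
  if (is.null(names(mode_proportions)) ||
      !all(names(mode_proportions) %in% ok_modes))
    stopf("mode_proportions must be named by NONE or the named modes")
  if (any(mode_proportions < 0))
    stopf("mode_proportions must be nonnegative")
  if (abs(sum(mode_proportions) - 1) > 1e-9)
    stopf("mode_proportions must sum to 1 (got %.6f)",
          sum(mode_proportions))
  if (noise_sd < 0 || baseline_sd < 0 || dye_bias_sd < 0)
    stopf("noise/baseline/dye-bias sd must be >= 0")
  if (!(effect_size > 2 * rbt_effect))
    stopf("effect_size must exceed 2 * rbt_effect for separability")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates_per_group = as.integer(n_replicates_per_group),
                 mode_proportions = mode_proportions,
                 effect_size = effect_size, rbt_effect = rbt_effect,
                 noise_sd = noise_sd, baseline_sd = baseline_sd,
                 dye_bias_sd = dye_bias_sd,
                 annotation_rates = annotation_rates,
                 protein_fraction = protein_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## planted (wt, mut) response pair for one gene; rbt_sign is +/-1
planted_effects <- function(mode, effect, rbt, rbt_sign) {
  switch(mode,
    NONE                  = c(0, 0),
    DOWN.UpWT.DownMut     = c( effect, -effect),
    DOWN.DownWT.DownMut   = c(-effect, -2 * effect),
    DOWN.RbtWT.DownMut    = c(rbt_sign * rbt, -effect),
    DOWN.UpWT.RbtMut      = c( effect,  rbt_sign * rbt),
    UP.DownWT.UpMut       = c(-effect,  effect),
    UP.UpWT.UpMut         = c( effect,  2 * effect),
    UP.DownWT.RbtMut      = c(-effect,  rbt_sign * rbt),
    UP.RbtWT.UpMut        = c(rbt_sign * rbt, effect),
    stopf("unknown mode: %s", mode))
}

#' Generate a synthetic dual-confrontation experiment
#'
#' Draws per-gene modes from \code{mode_proportions}, plants the
#' corresponding WT/mutant host responses on top of per-gene baselines,
#' and simulates \code{n_replicates_per_group} arrays per group with
#' i.i.d. Gaussian noise. A configurable fraction of genes is mirrored
#' as proteome "spots" carrying the same planted responses with
#' independent noise, so transcript-protein corroboration is testable.
#' The generator seeds the RNG from \code{config$seed}; identical
#' configurations therefore give identical output.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{bundle}
#'   (\code{\link{expression_bundle}}), \code{annotation} (data frame:
#'   gene_id, funcat_ids, go_ids, secreted, mitochondrial),
#'   \code{truth} (gene_id, mode, wt_effect, mut_effect), and
#'   \code{spots} (a \code{\link{spot_table}}).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  nrep <- config$n_replicates_per_group
  gene_ids <- sprintf("g%04d", seq_len(n))

  modes <- sample(names(config$mode_proportions), n, replace = TRUE,
                  prob = config$mode_proportions)
  rbt_signs <- sample(c(-1, 1), n, replace = TRUE)
  eff <- t(vapply(seq_len(n), function(i)
    planted_effects(modes[i], config$effect_size, config$rbt_effect,
                    rbt_signs[i]), numeric(2)))
  wt_eff <- eff[, 1]
  mut_eff <- eff[, 2]
  baseline <- stats::rnorm(n, 0, config$baseline_sd)

  design <- expand.grid(replicate = seq_len(nrep),
                        confrontation = c("SELF", "HOST"),
                        strain = c("WT", "MUT"),
                        stringsAsFactors = FALSE)
  design <- design[, c("strain", "confrontation", "replicate")]
  design$array_id <- sprintf("%s_%s_r%d", design$strain,
                             design$confrontation, design$replicate)
  group_mean <- cbind(WT_SELF = baseline,
                      WT_HOST = baseline + wt_eff,
                      MUT_SELF = baseline,
                      MUT_HOST = baseline + mut_eff)
  grp <- group_of(design$strain, design$confrontation)
  m <- group_mean[, grp, drop = FALSE] +
    matrix(stats::rnorm(n * nrow(design), 0, config$noise_sd),
           nrow = n)
  if (config$dye_bias_sd > 0) {
    bias <- stats::rnorm(nrow(design), 0, config$dye_bias_sd)
    m <- sweep(m, 2, bias, `+`)
  }
  dimnames(m) <- list(gene_ids, design$array_id)
  bundle <- expression_bundle(m, design)

  ar <- config$annotation_rates
  n_terms <- ar$n_terms %||% 10
  term_ids <- sprintf("GO:%04d", seq_len(n_terms))
  term_mat <- matrix(stats::runif(n * n_terms) < (ar$term_rate %||% 0.08),
                     nrow = n)
  funcat_ids <- sprintf("%02d.%02d", sample(1:40, n, replace = TRUE),
                        sample(1:20, n, replace = TRUE))
  annotation <- data.frame(
    gene_id = gene_ids,
    funcat_ids = funcat_ids,
    go_ids = apply(term_mat, 1, function(r)
      paste(term_ids[r], collapse = ";")),
    secreted = as.integer(stats::runif(n) < (ar$secreted %||% 0.1)),
    mitochondrial = as.integer(stats::runif(n) < (ar$mitochondrial %||% 0.09)),
    row.names = NULL)

  truth <- data.frame(gene_id = gene_ids, mode = modes,
                      wt_effect = wt_eff, mut_effect = mut_eff,
                      secreted = annotation$secreted,
                      mitochondrial = annotation$mitochondrial,
                      row.names = NULL)

  spots <- NULL
  n_prot <- floor(config$protein_fraction * n)
  if (n_prot >= 1) {
    prot_idx <- sort(sample.int(n, n_prot))
    prot_design <- design
    prot_design$array_id <- sub("^", "s_", prot_design$array_id)
    pm <- group_mean[prot_idx, grp, drop = FALSE] +
      matrix(stats::rnorm(n_prot * nrow(design), 0, config$noise_sd),
             nrow = n_prot)
    abundance <- 2^pm  # positive abundances on the raw scale
    dimnames(abundance) <- list(sprintf("spot_%s", gene_ids[prot_idx]),
                                prot_design$array_id)
    spots <- spot_table(abundance,
                        data.frame(sample_id = prot_design$array_id,
                                   strain = prot_design$strain,
                                   confrontation = prot_design$confrontation,
                                   replicate = prot_design$replicate),
                        protein_id = gene_ids[prot_idx])
  }

  list(bundle = bundle, annotation = annotation, truth = truth,
       spots = spots, config = config)
}

#' Write a synthetic experiment to a directory of TSV files
#'
#' Writes expression.tsv / design.tsv (the bundle), annotation.tsv,
#' truth.tsv and, when present, spots.tsv / spot_design.tsv.
#'
#' @param experiment result of \code{\link{generate_experiment}}.
#' @param dir output directory (created if missing).
#' @return invisibly, \code{dir}.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bundle(experiment$bundle,
               file.path(dir, "expression.tsv"),
               file.path(dir, "design.tsv"))
  write_tsv(experiment$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(experiment$truth, file.path(dir, "truth.tsv"))
  if (!is.null(experiment$spots)) {
    st <- experiment$spots
    tab <- data.frame(spot_id = rownames(st$abundance),
                      protein_id = st$protein_id,
                      st$abundance, check.names = FALSE)
    write_tsv(tab, file.path(dir, "spots.tsv"))
    write_tsv(st$samples, file.path(dir, "spot_design.tsv"))
  }
  invisible(dir)
}
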