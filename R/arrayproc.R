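#' Expression bundle: log2 ratio matrix plus array design
#'
#' The container for a universal-reference two-colour experiment: a
#' genes x arrays matrix of log2(sample/reference) ratios and a design
#' table mapping each array to a (strain, confrontation, replicate)
#' triple. Strains are WT or MUT (the signalling-mutant), confrontations
#' SELF (self-confrontation control) or HOST (confrontation with the
#' fungal host).
#'
#' @param matrix numeric matrix, genes in rows, arrays in columns;
#'   column names must be array ids matching \code{design$array_id}.
#' @param design data frame with columns \code{array_id}, \code{strain}
#'   (\code{"WT"}/\code{"MUT"}), \code{confrontation}
#'   (\code{"SELF"}/\code{"HOST"}), \code{replicate}.
#' @return an object of class \code{"expression_bundle"}.
#' @export
expression_bundle <- function(matrix, design) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stopf("matrix must be a numeric matrix")
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("g", seq_len(nrow(matrix)))
  if (anyDuplicated(rownames(matrix)))
    stopf("duplicate gene ids in expression matrix")
  if (!all(is.finite(matrix)))
    stopf("expression matrix contains non-finite values")
  req <- c("array_id", "strain", "confrontation", "replicate")
  if (!all(req %in% names(design)))
    stopf("design table must have columns: %s", paste(req, collapse = ", "))
  if (ncol(matrix) != nrow(design))
    stopf("matrix has %d arrays but design has %d rows",
          ncol(matrix), nrow(design))
  if (is.null(colnames(matrix))) colnames(matrix) <- design$array_id
  if (!setequal(colnames(matrix), design$array_id) ||
      anyDuplicated(design$array_id))
    stopf("array ids in matrix and design do not match")
  design <- design[match(colnames(matrix), design$array_id), , drop = FALSE]
  rownames(design) <- NULL
  design$strain <- toupper(as.character(design$strain))
  design$confrontation <- toupper(as.character(design$confrontation))
  if (!all(design$strain %in% c("WT", "MUT")))
    stopf("strain must be WT or MUT")
  if (!all(design$confrontation %in% c("SELF", "HOST")))
    stopf("confrontation must be SELF or HOST")
  design$group <- factor(group_of(design$strain, design$confrontation),
                         levels = GROUP_LEVELS)
  structure(list(matrix = matrix, design = design,
                 gene_ids = rownames(matrix)),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("expression_bundle: %d genes x %d arrays\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(table(x$design$group))
  invisible(x)
}

#' @export
dim.expression_bundle <- function(x) dim(x$matrix)

#' Read an expression bundle from TSV files
#'
#' The matrix file has gene ids in the first column and one column per
#' array; the design file has columns array_id, strain, confrontation,
#' replicate.
#'
#' @param matrix_path path to the expression TSV.
#' @param design_path path to the design TSV.
#' @return an \code{\link{expression_bundle}}.
#' @export
read_bundle <- function(matrix_path, design_path) {
  tab <- read_tsv(matrix_path)
  design <- read_tsv(design_path)
  gene_ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric cells in expression matrix")
  rownames(m) <- gene_ids
  expression_bundle(m, design)
}

#' Write an expression bundle to TSV files
#'
#' @param bundle an \code{\link{expression_bundle}}.
#' @param matrix_path,design_path output paths.
#' @return invisibly, the bundle.
#' @export
write_bundle <- function(bundle, matrix_path, design_path) {
  tab <- data.frame(gene_id = bundle$gene_ids,
                    bundle$matrix, check.names = FALSE)
  write_tsv(tab, matrix_path)
  write_tsv(bundle$design[, c("array_id", "strain", "confrontation",
                              "replicate")], design_path)
  invisible(bundle)
}

## ---- normalization registry ------------------------------------------------

norm_identity <- function(m) m

norm_median_center <- function(m) {
  sweep(m, 2, apply(m, 2, stats::median))
}

norm_quantile <- function(m) {
  # classic quantile normalization: replace each column by the rank-wise
  # mean of the sorted columns; ties receive the average of their ranks'
  # means
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(m, 2, function(col) {
    o <- order(col)
    grp <- cumsum(c(TRUE, diff(col[o]) != 0))  # tie groups share a value
    res <- numeric(length(col))
    res[o] <- stats::ave(ref, grp)             # ties get their ranks' mean
    res
  })
  dimnames(out) <- dimnames(m)
  out
}

norm_mad_scale <- function(m) {
  centered <- norm_median_center(m)
  mads <- apply(centered, 2, stats::mad)
  mads[mads == 0] <- 1  # MAD-0 columns are left centered only
  sweep(centered, 2, mads, `/`)
}

.norm_registry <- new.env(parent = emptyenv())

#' Register a normalization method
#'
#' @param name unique method name.
#' @param fun function taking and returning a genes x arrays matrix.
#' @export
register_normalization <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, fun, envir = .norm_registry)
  invisible(name)
}

register_normalization("identity", norm_identity)
register_normalization("median_center", norm_median_center)
register_normalization("quantile", norm_quantile)
register_normalization("mad_scale", norm_mad_scale)

#' Names of available normalization methods
#' @return character vector of registered method names.
#' @export
normalization_methods <- function() ls(.norm_registry)

#' Default normalization bank
#'
#' The bank whose branches are combined by the rank-product
#' meta-analysis. The default pairs the two robust location/scale
#' methods, which preserve the log2 scale that the downstream
#' classification thresholds are expressed in. \code{quantile} is
#' available in the registry but is not a default branch: forcing all
#' arrays onto a common distribution systematically attenuates strong
#' condition-specific effects in the distribution tails, which is
#' exactly the signal this pipeline classifies (see the methods
#' vignette). The bank is configurable per run.
#' @return character vector of method names.
#' @export
default_normalizations <- function() c("median_center", "mad_scale")

#' Normalize an expression bundle
#'
#' \code{median_center} subtracts each array's median (every column
#' median becomes 0); \code{quantile} forces all arrays onto the
#' rank-wise mean distribution (every column becomes a permutation of
#' one common vector); \code{mad_scale} median-centres and divides each
#' array by its median absolute deviation (MAD-0 columns are centred
#' only). Gene and array order are never changed.
#'
#' @param bundle an \code{\link{expression_bundle}}.
#' @param method a registered method name.
#' @return a normalized \code{\link{expression_bundle}}.
#' @export
normalize_bundle <- function(bundle, method) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (!method %in% normalization_methods())
    stopf("unknown normalization method: %s", method)
  fun <- get(method, envir = .norm_registry)
  out <- bundle
  out$matrix <- fun(bundle$matrix)
  dimnames(out$matrix) <- dimnames(bundle$matrix)
  out
}
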