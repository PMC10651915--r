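#' Contrast specifications over the four group means
#'
#' Contrasts are coefficient vectors over the group means in the order
#' WT_SELF, WT_HOST, MUT_SELF, MUT_HOST:
#' \describe{
#'   \item{WT_RESPONSE}{(-1, +1, 0, 0) — host- vs self-confrontation in
#'     the wild type.}
#'   \item{MUT_RESPONSE}{(0, 0, -1, +1) — the same response in the
#'     mutant.}
#'   \item{SECOND_LEVEL}{(+1, -1, -1, +1) — mutant response minus WT
#'     response, the "response of the response". Negative values mean
#'     the mutant's host response is lower than the wild type's.}
#' }
#'
#' @param name one of \code{"WT_RESPONSE"}, \code{"MUT_RESPONSE"},
#'   \code{"SECOND_LEVEL"}, or \code{"custom"} with \code{coef} given.
#' @param coef optional custom coefficient vector (must sum to 0).
#' @return an object of class \code{"contrast_spec"}.
#' @export
contrast_spec <- function(name, coef = NULL) {
  builtin <- list(
    WT_RESPONSE  = c(-1,  1,  0, 0),
    MUT_RESPONSE = c( 0,  0, -1, 1),
    SECOND_LEVEL = c( 1, -1, -1, 1)
  )
  if (is.null(coef)) {
    if (!name %in% names(builtin)) stopf("unknown contrast: %s", name)
    coef <- builtin[[name]]
  }
  if (length(coef) != 4 || abs(sum(coef)) > 1e-12)
    stopf("contrast coefficients must be length 4 and sum to 0")
  names(coef) <- GROUP_LEVELS
  structure(list(name = name, coef = coef), class = "contrast_spec")
}

#' Fit the per-gene group-means model and evaluate a contrast
#'
#' A one-way cell-means model over the four (strain, confrontation)
#' groups is fitted per gene. The contrast estimate is the coefficient
#' vector applied to the group means; the residual variance is pooled
#' within groups with \code{df = n_arrays - 4}; the contrast's
#' standard-error multiplier is \code{sqrt(sum(coef^2 / n_g))}.
#'
#' @param bundle an \code{\link{expression_bundle}}; every group must
#'   have at least one array.
#' @param contrast a \code{\link{contrast_spec}}.
#' @return data frame with columns gene_id, log2fc, s2, df, plus the
#'   scalar standard-error multiplier as attribute \code{"se_mult"}.
#' @export
fit_gene_model <- function(bundle, contrast) {
  stopifnot(inherits(bundle, "expression_bundle"),
            inherits(contrast, "contrast_spec"))
  grp <- bundle$design$group
  n_g <- table(grp)
  if (any(n_g == 0))
    stopf("group(s) with no arrays: %s",
          paste(names(n_g)[n_g == 0], collapse = ", "))
  m <- bundle$matrix
  means <- vapply(GROUP_LEVELS, function(g)
    rowMeans(m[, grp == g, drop = FALSE]), numeric(nrow(m)))
  means <- matrix(means, nrow = nrow(m),
                  dimnames = list(rownames(m), GROUP_LEVELS))
  log2fc <- drop(means %*% contrast$coef)
  fitted <- means[, as.integer(grp), drop = FALSE]
  resid <- m - fitted
  df <- ncol(m) - 4L
  s2 <- if (df > 0) rowSums(resid^2) / df else rep(NA_real_, nrow(m))
  out <- data.frame(gene_id = bundle$gene_ids, log2fc = log2fc,
                    s2 = s2, df = df, row.names = NULL)
  attr(out, "se_mult") <- sqrt(sum(contrast$coef^2 / as.numeric(n_g)))
  attr(out, "contrast") <- contrast$name
  out
}

#' Numerical inverse of the trigamma function
#'
#' Solves trigamma(x) = y for x > 0 (trigamma is strictly decreasing).
#' @param y positive value.
#' @return x with trigamma(x) = y.
#' @keywords internal
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  # Newton on x, started from the large-x asymptote trigamma(x) ~ 1/x
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (x <= 0) x <- .Machine$double.eps
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Per-gene residual variances are assumed to follow a scaled
#' F/chi-square hierarchy: s^2 | sigma^2 ~ sigma^2 * chisq(df)/df with
#' 1/sigma^2 ~ chisq(d0)/(d0*s0^2). The prior (d0, s0^2) is estimated
#' by moment matching on log s^2: the sample variance of log s^2 in
#' excess of trigamma(df/2) identifies d0 through the trigamma inverse,
#' and the mean of log s^2 identifies s0^2 after digamma bias
#' correction. The posterior variance is the precision-weighted mix
#' s_tilde^2 = (d0*s0^2 + df*s^2)/(d0 + df), the moderated t is
#' log2fc/(s_tilde*c) with c the contrast's standard-error multiplier,
#' and two-sided p-values use a t distribution on d0 + df degrees of
#' freedom.
#'
#' Degenerate cases: if all variances are identical the common value is
#' used directly as s0^2 with d0 = Inf (the moderated t then equals the
#' ordinary t); if all variances are zero, s0^2 falls back to
#' \code{var_floor} and the condition is recorded in the result.
#'
#' @param fit result of \code{\link{fit_gene_model}} (columns log2fc,
#'   s2, df; attribute se_mult), or a data frame with those columns
#'   plus an explicit \code{se_mult} argument.
#' @param se_mult contrast standard-error multiplier; defaults to the
#'   attribute on \code{fit}.
#' @param d0_override force the prior degrees of freedom (e.g.
#'   \code{Inf}); \code{NULL} (default) estimates them.
#' @param var_floor positive floor used for s0^2 when every gene has
#'   zero residual variance.
#' @return \code{fit} augmented with columns s2_post, t_mod, p, and
#'   attributes \code{d0}, \code{s0_2}, \code{zero_variance_fallback}.
#' @export
ebayes_moderate <- function(fit, se_mult = attr(fit, "se_mult"),
                            d0_override = NULL, var_floor = 1e-8) {
  stopifnot(all(c("log2fc", "s2", "df") %in% names(fit)),
            is.numeric(se_mult), se_mult > 0, var_floor > 0)
  s2 <- fit$s2
  df <- fit$df
  if (sum(df >= 1) < 2) stopf("need >= 2 genes with df >= 1")
  fallback <- FALSE
  pos <- s2 > 0
  if (!any(pos)) {
    # all residual variances are exactly zero (e.g. noise-free data)
    d0 <- Inf
    s0_2 <- var_floor
    fallback <- TRUE
  } else {
    z <- log(s2[pos])
    dfe <- df[pos]
    if (stats::var(z) < 1e-12 && all(pos)) {
      # identical variances: no spread to estimate d0 from; use the
      # common value directly so moderation is a no-op
      d0 <- Inf
      s0_2 <- exp(mean(z))
    } else {
      evar <- stats::var(z) - mean(trigamma(dfe / 2))
      if (evar > 0) {
        d0 <- 2 * trigamma_inverse(evar)
        s0_2 <- exp(mean(z) - mean(digamma(dfe / 2) - log(dfe / 2)) +
                      digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s0_2 <- exp(mean(z) - mean(digamma(dfe / 2) - log(dfe / 2)))
      }
    }
  }
  if (!is.null(d0_override)) {
    d0 <- d0_override
    if (!any(pos)) s0_2 <- var_floor
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + df * s2) / (d0 + df)
  t_mod <- fit$log2fc / (sqrt(s2_post) * se_mult)
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- fit
  out$s2_post <- s2_post
  out$t_mod <- t_mod
  out$p <- p
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "se_mult") <- se_mult
  attr(out, "zero_variance_fallback") <- fallback
  out
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR adjustment valid under arbitrary dependence:
#' q_(i) = min over j >= i of min(1, m * c(m) * p_(j) / j) with
#' c(m) = sum_{k=1..m} 1/k.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted q-values, order-preserving in p.
#' @export
by_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Benjamini-Hochberg adjustment
#' @param p vector of p-values in [0, 1].
#' @return BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-branch gene statistics for one contrast
#'
#' Convenience wrapper: fit the group-means model, moderate the
#' variances, and attach BY-adjusted q-values.
#'
#' @param bundle an \code{\link{expression_bundle}} (already
#'   normalized).
#' @param contrast a \code{\link{contrast_spec}} or builtin name.
#' @param adjust \code{"BY"} (default) or \code{"BH"}.
#' @param ... passed to \code{\link{ebayes_moderate}}.
#' @return data frame with gene_id, log2fc, s2, df, s2_post, t_mod, p,
#'   q; attributes as in \code{\link{ebayes_moderate}}.
#' @export
branch_stats <- function(bundle, contrast, adjust = c("BY", "BH"), ...) {
  adjust <- match.arg(adjust)
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  fit <- fit_gene_model(bundle, contrast)
  mod <- ebayes_moderate(fit, ...)
  mod$q <- if (adjust == "BY") by_adjust(mod$p) else bh_adjust(mod$p)
  mod
}
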