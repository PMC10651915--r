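# Shared fixtures and independent brute-force oracles.

# Build a small bundle from a genes x 4 matrix of group means.
make_bundle <- function(group_means, nrep = 4, noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- nrow(group_means)
  design <- expand.grid(replicate = seq_len(nrep),
                        confrontation = c("SELF", "HOST"),
                        strain = c("WT", "MUT"),
                        stringsAsFactors = FALSE)
  design$array_id <- sprintf("%s_%s_r%d", design$strain,
                             design$confrontation, design$replicate)
  grp <- paste(design$strain, design$confrontation, sep = "_")
  m <- group_means[, grp, drop = FALSE] +
    matrix(rnorm(n * nrow(design), 0, noise_sd), nrow = n)
  dimnames(m) <- list(rownames(group_means) %||%
                        paste0("g", seq_len(n)), design$array_id)
  expression_bundle(m, design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct step-up evaluation of the Benjamini-Yekutieli procedure.
bf_by_adjust <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q <- pmin(1, m * cm * p[o] / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force hypergeometric upper tail by direct enumeration.
bf_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  js <- js[n - js <= N - K]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Naive agglomerative average linkage from the raw distance matrix:
# cluster distance = mean of all inter-point distances. Returns merge
# heights and the partition at every k.
bf_average_linkage <- function(profiles) {
  d <- as.matrix(dist(profiles))
  clusters <- as.list(seq_len(nrow(profiles)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    nc <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    part <- integer(nrow(profiles))
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# Canonical signature of a partition (invariant to label permutation).
partition_signature <- function(part) {
  paste(match(part, unique(part)), collapse = ",")
}

# Log marginal likelihood of observed s2 under the scaled-F hierarchy,
# for the grid-search oracle.
scaled_f_loglik <- function(s2, df, d0, s0_2) {
  sum(stats::df(s2 / s0_2, df, d0, log = TRUE) - log(s0_2))
}
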