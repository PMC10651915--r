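mk_spots <- function(values, nrep = 4) {
  # values: spots x 4 matrix of per-condition log2 abundances
  samples <- expand.grid(replicate = seq_len(nrep),
                         confrontation = c("SELF", "HOST"),
                         strain = c("WT", "MUT"),
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s_r%d", samples$strain,
                               samples$confrontation, samples$replicate)
  grp <- paste(samples$strain, samples$confrontation, sep = "_")
  ab <- 2^values[, grp, drop = FALSE]
  colnames(ab) <- samples$sample_id
  spot_table(ab, samples)
}

cond_cols <- c("WT_SELF", "WT_HOST", "MUT_SELF", "MUT_HOST")

test_that("average ratios follow the +/-1 convention and the gates", {
  v <- rbind(flat   = c(1, 1, 1, 1),
             up3    = c(0, log2(3.02), 0, 0),
             up14   = c(0, log2(1.4), 0, 0),
             down2  = c(1, 0, 1, 1))
  colnames(v) <- cond_cols
  st <- mk_spots(v)
  # make replicate values wiggle so t-tests are defined, except spot 1
  set.seed(2)
  st$abundance[2:4, ] <- st$abundance[2:4, ] *
    2^matrix(rnorm(3 * 16, 0, 0.05), nrow = 3)
  res <- spot_differential(st, c("WT_HOST", "WT_SELF"))

  expect_equal(res$AR[1], 1)       # identical -> AR 1, not flagged
  expect_equal(res$log2fc[1], 0)
  expect_equal(res$p[1], 1)
  expect_false(res$flagged[1])

  expect_gt(res$AR[2], 1.5)        # ~3-fold with tiny p -> flagged
  expect_true(res$flagged[2])
  expect_false(res$flagged[3])     # |AR| 1.4 never passes the AR gate
  expect_lt(res$AR[4], -1.5)       # downregulation reported as negative

  expect_true(all(abs(res$AR) >= 1))
  # AR and log2fc agree about the 1.5-fold gate
  expect_equal(abs(res$log2fc) >= log2(1.5), abs(res$AR) >= 1.5)

  # swapping conditions negates log2fc and mirrors AR
  rev_res <- spot_differential(st, c("WT_SELF", "WT_HOST"))
  expect_equal(rev_res$log2fc, -res$log2fc, tolerance = 1e-12)
  big <- abs(res$AR) > 1
  expect_equal(rev_res$AR[big], -res$AR[big], tolerance = 1e-12)

  one_rep <- mk_spots(v, nrep = 1)
  expect_error(spot_differential(one_rep, c("WT_HOST", "WT_SELF")),
               ">= 2 replicates")
  expect_error(spot_table(matrix(c(-1, 2), 1), data.frame()), "positive")
})

test_that("two-way ANOVA separates strain, confrontation and interaction", {
  set.seed(14)
  v <- rbind(inter = c(0, 0, 0, 3),    # pure interaction effect
             conf  = c(0, 3, 0, 3),    # pure confrontation effect
             null  = c(0, 0, 0, 0))
  colnames(v) <- cond_cols
  st <- mk_spots(v)
  st$abundance <- st$abundance * 2^matrix(rnorm(3 * 16, 0, 0.1), nrow = 3)
  an <- spot_anova(st)
  expect_lt(an$p_interaction[1], 0.01)
  expect_lt(an$p_confrontation[2], 0.001)
  expect_gt(an$p_interaction[2], 0.05)
  expect_gt(an$p_interaction[3], 0.001)
  expect_true(all(c("p_strain_add", "p_confrontation_add") %in% names(an)))
})

test_that("the response difference equals the direct four-mean contrast", {
  set.seed(9)
  v <- matrix(rnorm(20, 0, 2), nrow = 5,
              dimnames = list(paste0("s", 1:5), cond_cols))
  st <- mk_spots(v)
  st$abundance <- st$abundance * 2^matrix(rnorm(5 * 16, 0, 0.2), nrow = 5)
  wt <- spot_differential(st, c("WT_HOST", "WT_SELF"))
  mut <- spot_differential(st, c("MUT_HOST", "MUT_SELF"))
  d <- response_difference(setNames(wt$log2fc, wt$spot_id),
                           setNames(mut$log2fc, mut$spot_id))
  grp <- st$samples$group
  cm <- sapply(c("WT_SELF", "WT_HOST", "MUT_SELF", "MUT_HOST"),
               function(g) rowMeans(st$abundance[, grp == g]))
  direct <- (log2(cm[, "MUT_HOST"]) - log2(cm[, "MUT_SELF"])) -
    (log2(cm[, "WT_HOST"]) - log2(cm[, "WT_SELF"]))
  expect_equal(unname(d), unname(direct), tolerance = 1e-9)
  expect_equal(unname(d["s1"]), unname(mut$log2fc[1] - wt$log2fc[1]))
  expect_error(response_difference(c(a = 1), c(b = 1)), "match")
})

test_that("profile filtering and clustering recover planted structure", {
  prof <- rbind(a1 = c(3, 3, 0, 0), a2 = c(3, 3, 0, 0),
                b1 = c(-3, 0, 2, 0), b2 = c(-3, 0, 2, 0),
                weak = c(0.5, -1, 0.2, 0))
  filt <- filter_profiles(prof, 1.5)
  expect_setequal(rownames(filt), c("a1", "a2", "b1", "b2"))

  cl <- cluster_proteins(filt, k = 2)
  expect_equal(cl$cluster[["a1"]], cl$cluster[["a2"]])
  expect_equal(cl$cluster[["b1"]], cl$cluster[["b2"]])
  expect_false(cl$cluster[["a1"]] == cl$cluster[["b1"]])
  # labels ordered by the cluster mean of the first column
  expect_equal(unname(cl$cluster[c("b1", "a1")]), c(1L, 2L))

  expect_equal(unique(unname(cluster_proteins(filt, k = 1)$cluster)), 1L)
  expect_error(cluster_proteins(filt, k = 9), "exceeds")
  expect_error(cluster_proteins(filt, k = 0), ">= 1")
})

test_that("average-linkage agglomeration matches the brute-force oracle", {
  set.seed(25)
  for (rep in 1:5) {
    prof <- matrix(rnorm(5 * 3), nrow = 5,
                   dimnames = list(paste0("p", 1:5), NULL))
    hc <- cluster_proteins(prof, k = 2)$hclust
    bf <- bf_average_linkage(prof)
    expect_equal(hc$height, bf$heights, tolerance = 1e-9)
    for (k in 2:4) {
      part_pkg <- cutree(hc, k = k)
      part_bf <- bf$partitions[[5 - k]]
      expect_equal(partition_signature(part_pkg),
                   partition_signature(part_bf))
    }
  }
})

test_that("clustering is invariant to row order", {
  set.seed(33)
  prof <- matrix(rnorm(8 * 4), nrow = 8,
                 dimnames = list(paste0("p", 1:8), NULL))
  cl1 <- cluster_proteins(prof, k = 3)$cluster
  perm <- sample(8)
  cl2 <- cluster_proteins(prof[perm, ], k = 3)$cluster
  expect_equal(cl2[names(cl1)], cl1)
})

test_that("proteoform roll-up keeps the strongest spot per protein", {
  st <- data.frame(spot_id = paste0("s", 1:4),
                   protein_id = c("nit", "nit", "nit", "other"),
                   log2fc = c(-11.42, -4.57, -1.79, 2.0))
  ru <- rollup_proteins(st)
  expect_equal(nrow(ru), 2)
  expect_equal(ru$log2fc[ru$protein_id == "nit"], -11.42)
})
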