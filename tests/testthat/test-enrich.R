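toy_annotation <- function() {
  data.frame(
    gene_id = paste0("g", 1:10),
    funcat_ids = rep("01.01", 10),
    go_ids = c(rep("GO:A", 5), rep("GO:B", 5)),
    secreted = c(rep(1, 3), rep(0, 7)),
    mitochondrial = 0)
}

test_that("hypergeometric enrichment matches closed forms and filters", {
  ann <- toy_annotation()
  # study of all 5 GO:A genes among 10: p = C(5,5)C(5,0)/C(10,5) = 1/252
  res <- hypergeom_enrich(paste0("g", 1:5), ann)
  row_a <- res[res$term_id == "GO:A", ]
  expect_equal(row_a$p, 1 / 252, tolerance = 1e-12)
  expect_equal(row_a$study_count, 5)
  # GO:B annotates no study gene -> not reported
  expect_false("GO:B" %in% res$term_id)

  # study == population: no enrichment is possible
  res_all <- hypergeom_enrich(ann$gene_id, ann)
  expect_true(all(res_all$p == 1))

  expect_error(hypergeom_enrich(c("g1", "nope"), ann), "absent")
})

test_that("enrichment p-values match brute-force tail enumeration", {
  set.seed(12)
  for (rep in 1:20) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    genes <- paste0("g", 1:N)
    ann <- data.frame(gene_id = genes, funcat_ids = "x",
                      go_ids = ifelse(seq_len(N) <= K, "GO:T", ""),
                      secreted = 0, mitochondrial = 0)
    study <- sample(genes, n)
    k <- sum(study %in% genes[1:K])
    res <- hypergeom_enrich(study, ann)
    if (k == 0) {
      expect_false("GO:T" %in% res$term_id)
    } else {
      expect_equal(res$p[res$term_id == "GO:T"],
                   bf_hyper_tail(k, K, N, n), tolerance = 1e-12)
    }
  }
})

test_that("annotations propagate up the term DAG when requested", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    go_ids = c("GO:leaf", "GO:leaf", "GO:mid", ""),
                    funcat_ids = "x", secreted = 0, mitochondrial = 0)
  dag <- data.frame(child = c("GO:leaf", "GO:mid"),
                    parent = c("GO:mid", "GO:root"))
  res <- hypergeom_enrich(c("g1", "g2"), ann, propagate = TRUE, dag = dag)
  root <- res[res$term_id == "GO:root", ]
  expect_equal(root$study_count, 2)  # leaf genes count for all ancestors
  expect_equal(root$pop_count, 3)
  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(hypergeom_enrich(c("g1"), ann, propagate = TRUE,
                                dag = cyc), "cycle")
})

test_that("intersection networks assign membership, size and edges", {
  et <- data.frame(term_id = c("A", "B", "C"), study_count = c(4, 2, 7),
                   study_size = 10, pop_count = 5, pop_size = 100,
                   p = c(0.01, 0.2, 0.04), q = c(0.03, 0.3, 0.08))
  ep <- data.frame(term_id = c("A", "B", "D"), study_count = c(3, 1, 2),
                   study_size = 8, pop_count = 5, pop_size = 100,
                   p = c(0.02, 0.6, 0.01), q = c(0.05, 0.7, 0.03))
  dag <- data.frame(child = c("A", "C", "D"), parent = c("C", "root", "A"))
  g <- intersect_networks(et, ep, dag = dag, alpha = 0.05)
  v <- igraph::as_data_frame(g, what = "vertices")
  expect_setequal(v$name, c("A", "C", "D"))
  expect_equal(v$membership[v$name == "A"], "both")
  expect_equal(v$membership[v$name == "C"], "transcriptome_only")
  expect_equal(v$membership[v$name == "D"], "proteome_only")
  expect_equal(v$size[v$name == "A"], 7)  # 4 + 3 cluster frequencies
  e <- igraph::as_data_frame(g, what = "edges")
  # only edges between included terms survive ("root" and B are absent)
  expect_setequal(paste(e$from, e$to), c("A C", "D A"))

  # symmetric in its inputs up to membership label swap
  g2 <- intersect_networks(ep, et, dag = dag, alpha = 0.05)
  v2 <- igraph::as_data_frame(g2, what = "vertices")
  swap <- c(both = "both", transcriptome_only = "proteome_only",
            proteome_only = "transcriptome_only")
  expect_equal(unname(swap[v$membership[order(v$name)]]),
               v2$membership[order(v2$name)])

  empty <- et[0, ]
  g0 <- intersect_networks(empty, empty, alpha = 0.05)
  expect_equal(igraph::vcount(g0), 0)

  # GraphML and TSV export round-trip
  dir <- withr::local_tempdir()
  write_network(g, graphml_path = file.path(dir, "net.graphml"),
                nodes_path = file.path(dir, "nodes.tsv"),
                edges_path = file.path(dir, "edges.tsv"))
  back <- igraph::read_graph(file.path(dir, "net.graphml"),
                             format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(nrow(read_tsv(file.path(dir, "nodes.tsv"))), 3)
})

test_that("the packaged toy ontology drives propagation and networks", {
  dag <- read_tsv(system.file("extdata", "toy_go_dag.tsv",
                              package = "dualresponse"))
  ann <- data.frame(gene_id = paste0("g", 1:8),
                    go_ids = c(rep("GO:0006006", 4),
                               rep("GO:0016620", 3), ""),
                    funcat_ids = "x", secreted = 0, mitochondrial = 0)
  et <- hypergeom_enrich(paste0("g", 1:4), ann, propagate = TRUE,
                         dag = dag)
  # glucose metabolism propagates up to the metabolic-process root
  expect_true("GO:0008152" %in% et$term_id)
  ep <- hypergeom_enrich(paste0("g", 5:7), ann, propagate = TRUE,
                         dag = dag)
  g <- intersect_networks(et, ep, dag = dag, alpha = 1 - 1e-9)
  v <- igraph::as_data_frame(g, what = "vertices")
  expect_true(all(c("transcriptome_only", "proteome_only") %in%
                    v$membership))
})

test_that("the 2x2 chi-squared test matches Pearson arithmetic", {
  ind <- contingency_chi2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(ind$chi2, 0)
  expect_equal(ind$p, 1)
  diag <- contingency_chi2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag$chi2, 20)  # all expected counts are 5
  expect_error(contingency_chi2(matrix(c(7, 0, 8, 0), 2)), "margin")
  # Yates correction shrinks the statistic
  y <- contingency_chi2(matrix(c(10, 0, 0, 10), 2), yates = TRUE)
  expect_lt(y$chi2, 20)
})

test_that("BH never exceeds BY on the same p-vector", {
  set.seed(3)
  p <- runif(50)
  expect_true(all(bh_adjust(p) <= by_adjust(p) + 1e-12))
})
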