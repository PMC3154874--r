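# helper: network from an explicit edge list (similarities are irrelevant
# to expansion, so fill defined GO similarity just above a 0.7 cutoff)
edge_network <- function(nodes, from, to) {
  edges <- if (length(from) == 0) data.frame() else data.frame(
    gene_a = pmin(from, to), gene_b = pmax(from, to),
    sim_go = 0.8, sim_mesh = NA_real_, support = "GO", weight = 0.8,
    stringsAsFactors = FALSE)
  annotation_network(nodes, edges, cutoff = 0.7)
}

test_that("hop_expand runs BFS with the < 3 sequential connections boundary", {
  net <- edge_network(LETTERS[1:4], c("A", "B", "C"), c("B", "C", "D"))
  # path A-B-C-D, bait A, max_hops 2: D (3 hops) excluded, C (2 hops) kept
  expect_equal(hop_expand(net, "A", 2), c(A = 0L, B = 1L, C = 2L))
  # multi-source
  expect_equal(hop_expand(net, c("A", "D"), 1),
               c(A = 0L, B = 1L, C = 1L, D = 0L))
  # max_hops 0 -> baits only
  expect_equal(hop_expand(net, c("A", "D"), 0), c(A = 0L, D = 0L))
  # missing baits: skipped with warning; all missing -> error listing them
  expect_warning(d <- hop_expand(net, c("A", "ZZ"), 1), "ZZ")
  expect_equal(d, c(A = 0L, B = 1L))
  expect_error(suppressWarnings(hop_expand(net, c("YY", "ZZ"), 1)), "YY")
})

test_that("hop_expand agrees with the igraph-distances oracle", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(6:14, 1)
    nodes <- sprintf("N%02d", 1:n)
    m <- sample(3:12, 1)
    from <- sample(nodes, m, replace = TRUE)
    to <- sample(nodes, m, replace = TRUE)
    keep <- from != to
    pairs <- unique(data.frame(a = pmin(from[keep], to[keep]),
                               b = pmax(from[keep], to[keep])))
    net <- edge_network(nodes, pairs$a, pairs$b)
    baits <- sample(nodes, sample(1:3, 1))
    h <- sample(0:3, 1)
    expect_equal(suppressWarnings(hop_expand(net, baits, h)),
                 oracle_bait_distance(net, baits, h))
  }
})

test_that("hop-expansion node sets are monotone in max_hops", {
  set.seed(42)
  for (i in 1:20) {
    nodes <- sprintf("N%02d", 1:12)
    from <- sample(nodes, 14, replace = TRUE)
    to <- sample(nodes, 14, replace = TRUE)
    keep <- from != to
    pairs <- unique(data.frame(a = pmin(from[keep], to[keep]),
                               b = pmax(from[keep], to[keep])))
    net <- edge_network(nodes, pairs$a, pairs$b)
    baits <- sample(nodes, 2)
    for (h in 0:2) {
      lo <- names(hop_expand(net, baits, h))
      hi <- names(hop_expand(net, baits, h + 1L))
      expect_true(all(lo %in% hi))
    }
  }
})

test_that("overlay_expression assigns the Venn partition", {
  s1 <- make_calls(c("A", "B", "C", "D"),
                   c("up", "down", "not_expressed", "not_expressed"))
  s2 <- make_calls(c("A", "B", "C", "D"),
                   c("not_expressed", "down", "up", "not_expressed"),
                   stage = "stage2")
  expect_equal(
    overlay_expression(c("A", "B", "C", "D"), s1, s2),
    c(A = "stage1_only", B = "both", C = "stage2_only",
      D = "bait_unexpressed"))
  # gene absent from both call lists: warning, treated as not expressed
  expect_warning(lab <- overlay_expression(c("A", "ZZ"), s1, s2), "ZZ")
  expect_equal(lab[["ZZ"]], "bait_unexpressed")
})

test_that("overlay on a synthetic expansion recovers planted label counts", {
  # 60 genes with planted 20/10/25/5 labels
  genes <- sprintf("G%02d", 1:60)
  lab <- rep(c("stage1_only", "stage2_only", "both", "bait_unexpressed"),
             c(20, 10, 25, 5))
  d1 <- ifelse(lab %in% c("stage1_only", "both"), "unchanged",
               "not_expressed")
  d2 <- ifelse(lab %in% c("stage2_only", "both"), "up", "not_expressed")
  got <- overlay_expression(genes, make_calls(genes, d1),
                            make_calls(genes, d2, stage = "stage2"))
  expect_equal(unname(table(got)[c("stage1_only", "stage2_only", "both",
                                   "bait_unexpressed")]),
               table(lab)[c("stage1_only", "stage2_only", "both",
                            "bait_unexpressed")],
               ignore_attr = TRUE)
})

test_that("extract_clusters returns ordered connected components", {
  # two disjoint triangles + a singleton
  net <- edge_network(
    c("A", "B", "C", "P", "Q", "R", "Z"),
    c("A", "B", "A", "P", "Q", "P"), c("B", "C", "C", "Q", "R", "R"))
  cl <- extract_clusters(net, net$nodes)
  expect_length(cl, 3)
  expect_equal(lapply(cl, `[[`, "members"),
               list(c("A", "B", "C"), c("P", "Q", "R"), "Z"))
  expect_equal(vapply(cl, `[[`, 0L, "cluster_id"), 1:3)
  # single connected graph -> one cluster equal to kept_genes
  net2 <- edge_network(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  cl2 <- extract_clusters(net2, c("A", "B", "C"))
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$members, c("A", "B", "C"))
  # empty kept set is not an error
  expect_equal(extract_clusters(net, character()), list())
  expect_error(extract_clusters(net, "NOPE"), "not in network")
})

test_that("components match the union-find oracle on random graphs", {
  set.seed(43)
  for (i in 1:10) {
    nodes <- sprintf("N%02d", 1:40)
    m <- sample(10:50, 1)
    from <- sample(nodes, m, replace = TRUE)
    to <- sample(nodes, m, replace = TRUE)
    keep <- from != to
    pairs <- unique(data.frame(a = pmin(from[keep], to[keep]),
                               b = pmax(from[keep], to[keep])))
    net <- edge_network(nodes, pairs$a, pairs$b)
    cl <- extract_clusters(net, nodes)
    got <- unlist(lapply(cl, function(c)
      setNames(rep(c$cluster_id, length(c$members)), c$members)))
    want <- oracle_components(nodes, pairs$a, pairs$b)
    expect_equal(adjusted_rand_index(got[nodes], want[nodes]), 1)
    # partition: disjoint cover
    expect_setequal(names(got), nodes)
    expect_false(anyDuplicated(names(got)) > 0)
  }
})

test_that("expand_pipeline composes deterministically on a mini scenario", {
  cfg <- simulation_config(n_genes = 50, n_modules = 3, module_size = 6,
                           n_baits = 5, n_terms_per_namespace = 100,
                           reversal_fraction = 0.1, noise_cv = 0,
                           detection_noise = 0, seed = 9)
  corp <- simulate_corpus(cfg)
  expr <- simulate_expression(cfg)
  s1 <- differential_contrast(expr$tables$stage1$ctrl, expr$tables$stage1$nsn)
  s2 <- differential_contrast(expr$tables$stage2$ctrl, expr$tables$stage2$nsn)
  ex <- expand_pipeline(corp$corpus, corp$baits, s1, s2)

  # analytic truth: module genes reachable within 2 hops of a bait; with
  # high within-module overlap each module is a connected unit, so the
  # expansion covers exactly the modules containing a bait
  truth <- merge(corp$truth, expr$truth, by = "gene")
  bait_modules <- unique(truth$module_id[truth$is_bait])
  expected_genes <- truth$gene[!is.na(truth$module_id) &
                               truth$module_id %in% bait_modules]
  expect_setequal(names(ex$bait_distance), expected_genes)
  # venn labels match the generator truth on the expanded genes
  sub <- truth[match(names(ex$venn_label), truth$gene), ]
  expect_equal(unname(ex$venn_label), sub$venn)
  # summary counts are consistent
  vc <- ex$summary$venn_counts
  expect_equal(vc$stage1_only + vc$stage2_only + vc$both +
                 vc$bait_unexpressed, ex$summary$n_network_genes)
  expect_equal(ex$summary$n_expressed,
               ex$summary$n_network_genes - vc$bait_unexpressed)

  # determinism: identical inputs -> byte-identical reports
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_expansion_report(ex, p1)
  ex2 <- expand_pipeline(corp$corpus, corp$baits, s1, s2)
  write_expansion_report(ex2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("near-1 cutoff collapses the expansion towards the baits", {
  cfg <- simulation_config(n_genes = 50, n_modules = 3, module_size = 6,
                           n_baits = 5, n_terms_per_namespace = 100,
                           noise_cv = 0, detection_noise = 0, seed = 9)
  corp <- simulate_corpus(cfg)
  expr <- simulate_expression(cfg)
  s1 <- differential_contrast(expr$tables$stage1$ctrl, expr$tables$stage1$nsn)
  s2 <- differential_contrast(expr$tables$stage2$ctrl, expr$tables$stage2$nsn)
  ex <- expand_pipeline(corp$corpus, corp$baits, s1, s2, cutoff = 0.999)
  # only term-set-identical neighbours can survive; the expansion must
  # contain the baits and nothing outside the planted modules
  present <- intersect(corp$baits$genes, corpus_genes(corp$corpus))
  expect_true(all(present %in% names(ex$bait_distance)))
  modules <- corp$truth$gene[!is.na(corp$truth$module_id)]
  expect_true(all(names(ex$bait_distance) %in% modules))
  # and it is no larger than the default-cutoff expansion
  ex_def <- expand_pipeline(corp$corpus, corp$baits, s1, s2, cutoff = 0.7)
  expect_true(all(names(ex$bait_distance) %in% names(ex_def$bait_distance)))
})

test_that("expanded network exports with overlay node attributes", {
  cfg <- simulation_config(n_genes = 30, n_modules = 2, module_size = 5,
                           n_baits = 2, n_terms_per_namespace = 80, seed = 2)
  corp <- simulate_corpus(cfg)
  expr <- simulate_expression(cfg)
  s1 <- differential_contrast(expr$tables$stage1$ctrl, expr$tables$stage1$nsn)
  s2 <- differential_contrast(expr$tables$stage2$ctrl, expr$tables$stage2$nsn)
  ex <- expand_pipeline(corp$corpus, corp$baits, s1, s2)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_expanded_network(ex, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(g)$name, names(ex$venn_label))
  expect_equal(setNames(igraph::V(g)$venn_label, igraph::V(g)$name)[
    names(ex$venn_label)], ex$venn_label)
})
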