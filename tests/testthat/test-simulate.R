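test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_genes = 10, n_modules = 3,
                                 module_size = 8), "exceed")
  expect_error(simulation_config(effect_ratio = 1), "effect_ratio")
  expect_error(simulation_config(reversal_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(n_terms_per_namespace = 10,
                                 core_terms_per_module = 20),
               "infeasible")
})

test_that("corpus limit cases: full overlap and zero overlap", {
  base <- list(n_genes = 20, n_modules = 2, module_size = 6,
               background_term_rate = 0, n_terms_per_namespace = 60,
               core_terms_per_module = 10, n_baits = 2, seed = 4)
  # overlap 1, background 0: identical within-module term sets -> cosine 1
  cfg1 <- do.call(simulation_config, c(base,
                                       within_module_term_overlap = 1))
  sim1 <- simulate_corpus(cfg1)
  t1 <- sim1$truth
  mod1 <- t1$gene[!is.na(t1$module_id) & t1$module_id == 1]
  expect_equal(annotation_similarity(sim1$corpus, mod1[1], mod1[2], "GO"),
               1.0)
  expect_equal(annotation_similarity(sim1$corpus, mod1[1], mod1[2], "MESH"),
               1.0)
  # across modules: disjoint cores -> similarity 0
  mod2 <- t1$gene[!is.na(t1$module_id) & t1$module_id == 2]
  expect_equal(annotation_similarity(sim1$corpus, mod1[1], mod2[1], "GO"), 0)

  # overlap 0, background 0: every term set empty -> no edges at any cutoff
  cfg0 <- do.call(simulation_config, c(base,
                                       within_module_term_overlap = 0))
  sim0 <- simulate_corpus(cfg0)
  expect_true(all(vapply(sim0$corpus$assignments,
                         function(a) length(c(a$GO, a$MESH)) == 0, TRUE)))
  net0 <- build_network(sim0$corpus, cutoff = 0.1)
  expect_equal(nrow(net0$edges), 0)
})

test_that("planted counts are exact (assignment, not sampling)", {
  for (frac in c(0, 0.1, 0.25)) {
    cfg <- simulation_config(n_genes = 200, reversal_fraction = frac,
                             seed = 8)
    truth <- simulate_expression(cfg)$truth
    expect_equal(sum(truth$planted_reversal), round(frac * 200))
    expect_equal(sum(truth$venn == "stage1_only"), round(0.15 * 200))
    expect_equal(sum(truth$venn == "bait_unexpressed"), round(0.05 * 200))
  }
})

test_that("reversal_fraction 0 yields zero (up, down) genes", {
  cfg <- simulation_config(n_genes = 100, reversal_fraction = 0,
                           noise_cv = 0, detection_noise = 0, seed = 6)
  expr <- simulate_expression(cfg)
  s1 <- differential_contrast(expr$tables$stage1$ctrl,
                              expr$tables$stage1$nsn)
  s2 <- differential_contrast(expr$tables$stage2$ctrl,
                              expr$tables$stage2$nsn)
  part <- pattern_partition(expr$truth$gene, s1, s2)
  expect_equal(part$count[part$stage1 == "up" & part$stage2 == "down"], 0)
})

test_that("same seed gives byte-identical bundles; different seeds differ", {
  cfg <- simulation_config(n_genes = 40, n_modules = 2, module_size = 5,
                           n_terms_per_namespace = 60, n_baits = 2, seed = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  f1 <- write_fixture_bundle(cfg, d1)
  f2 <- write_fixture_bundle(cfg, d2)
  expect_length(f1, 8)
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     label = nm)
  cfg2 <- simulation_config(n_genes = 40, n_modules = 2, module_size = 5,
                            n_terms_per_namespace = 60, n_baits = 2,
                            seed = 11)
  f3 <- write_fixture_bundle(cfg2, d3)
  expect_false(identical(readLines(f1[["truth"]]),
                         readLines(f3[["truth"]])))
})

test_that("bundles are re-loadable by every loader in the package", {
  cfg <- simulation_config(n_genes = 40, n_modules = 2, module_size = 5,
                           n_terms_per_namespace = 60, n_baits = 2, seed = 10)
  dir <- withr::local_tempdir()
  files <- write_fixture_bundle(cfg, dir)
  t11 <- load_expression_table(files[["expr_stage1_ctrl"]], "stage1", "ctrl")
  t12 <- load_expression_table(files[["expr_stage1_nsn"]], "stage1", "nsn")
  t21 <- load_expression_table(files[["expr_stage2_ctrl"]], "stage2", "ctrl")
  t22 <- load_expression_table(files[["expr_stage2_nsn"]], "stage2", "nsn")
  expect_equal(length(t11$genes), 40)
  corpus <- load_annotations(files[["annotations"]])
  expect_true(length(corpus_genes(corpus)) > 0)
  baits <- read_gene_list(files[["baits"]])
  expect_length(baits, 2)
  ext <- read_gmt(files[["external"]])
  expect_length(ext, 1)
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$bundle_version, 1)
  expect_equal(nrow(truth$truth), 40)
  expect_equal(truth$config$seed, 10)
  # the bundle drives the pipeline end to end
  s1 <- differential_contrast(t11, t12)
  s2 <- differential_contrast(t21, t22)
  ex <- expand_pipeline(corpus, baits, s1, s2)
  expect_s3_class(ex, "expanded_network")
})

test_that("zero-noise generator output is recovered exactly end to end", {
  cfg <- simulation_config(n_genes = 150, noise_cv = 0, detection_noise = 0,
                           n_modules = 3, module_size = 6, n_baits = 3,
                           n_terms_per_namespace = 150, seed = 12)
  expr <- simulate_expression(cfg)
  s1 <- differential_contrast(expr$tables$stage1$ctrl,
                              expr$tables$stage1$nsn)
  s2 <- differential_contrast(expr$tables$stage2$ctrl,
                              expr$tables$stage2$nsn)
  truth <- expr$truth
  expect_equal(s1$direction[match(truth$gene, s1$gene)],
               truth$pattern_stage1)
  expect_equal(s2$direction[match(truth$gene, s2$gene)],
               truth$pattern_stage2)
  venn <- overlay_expression(truth$gene, s1, s2)
  expect_equal(unname(venn[truth$gene]), truth$venn)
})

test_that("default scenario recall of planted reversals is high", {
  cfg <- simulation_config()  # n=500, reversal 0.1, ratio 3, cv 0.2, seed 7
  expr <- simulate_expression(cfg)
  s1 <- differential_contrast(expr$tables$stage1$ctrl,
                              expr$tables$stage1$nsn)
  s2 <- differential_contrast(expr$tables$stage2$ctrl,
                              expr$tables$stage2$nsn)
  called <- s1$gene[s1$direction == "up" &
                    s2$direction[match(s1$gene, s2$gene)] == "down"]
  planted <- expr$truth$gene[expr$truth$planted_reversal]
  recall <- length(intersect(called, planted)) / length(planted)
  expect_gte(recall, 0.95)
})
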