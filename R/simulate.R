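# Seeded synthetic-data generator with planted structure.
#
# The generator emulates the statistical shape the pipeline assumes:
#  * an annotation corpus in which functionally related genes share a core
#    of GO and MeSH terms (planted modules) on top of Zipf-distributed
#    background terms, so that thresholded cosine similarity recovers the
#    modules;
#  * two-stage, two-condition expression tables with log-normal signals,
#    detection p-values, and a planted minority of genes with the reversal
#    pattern (up in the incompetent-oocyte contrast, down in the
#    incompetent-embryo contrast);
#  * a bait list drawn from the planted modules and a synthetic external
#    ("cancer-related") gene set.
# Planting is by deterministic assignment of seeded-shuffled gene indices,
# so truth counts are exact; identical configs (including seed) produce
# byte-identical fixture bundles.

#' Simulation configuration
#'
#' Defaults state the reference synthetic scenario: 500 genes, 3 planted
#' annotation modules of 8 genes sharing 90% of a 20-term core per
#' namespace, ~1 background term per gene per namespace, a planted reversal
#' fraction of 0.1 at true fold change 3, log-normal signal noise with
#' CV 0.2, detection noise 0.01, two samples per condition, seed 7.
#'
#' @param n_genes number of genes.
#' @param n_modules,module_size planted annotation modules
#'   (`n_modules * module_size <= n_genes`).
#' @param within_module_term_overlap fraction of the module core each member
#'   receives (1 = identical term sets).
#' @param background_term_rate expected background terms per gene per
#'   namespace (Poisson), drawn from a Zipf-like frequency distribution.
#' @param n_terms_per_namespace size of each namespace's term universe.
#' @param core_terms_per_module size of each module's reserved core.
#' @param n_baits number of bait genes (taken round-robin from the modules;
#'   `<= n_modules * module_size`).
#' @param reversal_fraction fraction of genes planted as (up, down).
#' @param effect_ratio true fold change of planted genes (> 1).
#' @param noise_cv coefficient of variation of log-normal signals.
#' @param detection_noise probability that a truly expressed gene-condition
#'   fails the detection threshold.
#' @param n_samples samples per condition.
#' @param stage1_only_fraction,stage2_only_fraction,unexpressed_fraction
#'   fractions of genes expressed only at stage 1, only at stage 2, or at
#'   neither stage; the remainder is expressed at both.
#' @param external_fraction fraction of genes flagged as members of the
#'   synthetic external gene set.
#' @param base_signal mean signal of expressed genes (arbitrary units).
#' @param null_signal mean signal of undetected genes.
#' @param seed integer RNG seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 500L, n_modules = 3L,
                              module_size = 8L,
                              within_module_term_overlap = 0.9,
                              background_term_rate = 1.0,
                              n_terms_per_namespace = 400L,
                              core_terms_per_module = 20L,
                              n_baits = 5L,
                              reversal_fraction = 0.1,
                              effect_ratio = 3.0,
                              noise_cv = 0.2,
                              detection_noise = 0.01,
                              n_samples = 2L,
                              stage1_only_fraction = 0.15,
                              stage2_only_fraction = 0.05,
                              unexpressed_fraction = 0.05,
                              external_fraction = 0.3,
                              base_signal = 200,
                              null_signal = 5,
                              seed = 7L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", 2L),
    n_modules = check_count(n_modules, "n_modules"),
    module_size = check_count(module_size, "module_size"),
    within_module_term_overlap =
      check_fraction(within_module_term_overlap, "within_module_term_overlap"),
    background_term_rate = as.numeric(background_term_rate),
    n_terms_per_namespace =
      check_count(n_terms_per_namespace, "n_terms_per_namespace", 1L),
    core_terms_per_module =
      check_count(core_terms_per_module, "core_terms_per_module"),
    n_baits = check_count(n_baits, "n_baits", 1L),
    reversal_fraction = check_fraction(reversal_fraction, "reversal_fraction"),
    effect_ratio = as.numeric(effect_ratio),
    noise_cv = as.numeric(noise_cv),
    detection_noise = check_fraction(detection_noise, "detection_noise"),
    n_samples = check_count(n_samples, "n_samples", 1L),
    stage1_only_fraction =
      check_fraction(stage1_only_fraction, "stage1_only_fraction"),
    stage2_only_fraction =
      check_fraction(stage2_only_fraction, "stage2_only_fraction"),
    unexpressed_fraction =
      check_fraction(unexpressed_fraction, "unexpressed_fraction"),
    external_fraction = check_fraction(external_fraction, "external_fraction"),
    base_signal = as.numeric(base_signal),
    null_signal = as.numeric(null_signal),
    seed = check_count(seed, "seed"))
  if (cfg$background_term_rate < 0) abort("background_term_rate must be >= 0")
  if (cfg$effect_ratio <= 1) abort("effect_ratio must be > 1")
  if (cfg$noise_cv < 0) abort("noise_cv must be >= 0")
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    abort("n_modules * module_size must not exceed n_genes")
  if (cfg$n_baits > max(cfg$n_modules * cfg$module_size, 1L))
    abort("n_baits must not exceed the number of module genes")
  core_total <- cfg$n_modules * cfg$core_terms_per_module
  if (core_total > cfg$n_terms_per_namespace ||
      (cfg$background_term_rate > 0 &&
       core_total >= cfg$n_terms_per_namespace))
    abort("infeasible config: module cores do not fit the term universe")
  venn_frac <- cfg$stage1_only_fraction + cfg$stage2_only_fraction +
    cfg$unexpressed_fraction
  if (venn_frac > 1) abort("stage/unexpressed fractions exceed 1")
  if (cfg$reversal_fraction > 1 - venn_frac)
    abort("reversal_fraction exceeds the fraction expressed at both stages")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: %d genes, %d modules x %d, reversal %.2f, seed %d\n",
    x$n_genes, x$n_modules, x$module_size, x$reversal_fraction, x$seed))
  invisible(x)
}

sim_gene_names <- function(config) sprintf("G%04d", seq_len(config$n_genes))

#' Simulate an annotation corpus with planted modules
#'
#' Module members share a term core per namespace (the member keeps
#' `round(overlap * core)` core terms) plus Poisson-many background terms
#' drawn from a Zipf-like (1/rank) frequency distribution over the
#' non-core terms. Background genes carry only background terms and may be
#' unannotated. Bait genes are taken round-robin across modules.
#'
#' @param config a `simulation_config`.
#' @return list with `corpus` (an `annotation_corpus`), `truth`
#'   (data.frame gene, module_id, is_bait) and `baits` (a `bait_set`).
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    genes <- sim_gene_names(config)
    shuffled <- sample(genes)
    n_mod_genes <- config$n_modules * config$module_size
    module_id <- setNames(rep(NA_integer_, config$n_genes), genes)
    if (n_mod_genes > 0)
      module_id[shuffled[seq_len(n_mod_genes)]] <-
        rep(seq_len(config$n_modules), each = config$module_size)

    term_ids <- list(
      GO = sprintf("GO:%06d", seq_len(config$n_terms_per_namespace)),
      MESH = sprintf("D%06d", seq_len(config$n_terms_per_namespace)))
    core_n <- config$core_terms_per_module
    n_core_total <- config$n_modules * core_n
    bg_idx <- setdiff(seq_len(config$n_terms_per_namespace),
                      seq_len(n_core_total))
    bg_w <- 1 / seq_along(bg_idx)  # Zipf-like skew
    keep_core <- round(config$within_module_term_overlap * core_n)

    assignments <- lapply(genes, function(g) {
      out <- list()
      for (ns in NAMESPACES) {
        terms <- character()
        m <- module_id[[g]]
        if (!is.na(m) && keep_core > 0) {
          core <- term_ids[[ns]][((m - 1L) * core_n + 1L):(m * core_n)]
          terms <- sample(core, keep_core)
        }
        if (config$background_term_rate > 0 && length(bg_idx) > 0) {
          nb <- rpois(1, config$background_term_rate)
          if (nb > 0)
            terms <- union(terms,
                           term_ids[[ns]][sample(bg_idx, min(nb, length(bg_idx)),
                                                 prob = bg_w)])
        }
        out[[ns]] <- terms
      }
      out
    })
    names(assignments) <- genes
    corpus <- annotation_corpus(assignments, term_universe = term_ids)

    # round-robin across modules: member 1 of each module, then member 2, ...
    mod_genes <- shuffled[seq_len(n_mod_genes)]
    bait_pool <- matrix(mod_genes, nrow = config$module_size,
                        ncol = config$n_modules)
    baits <- as.vector(t(bait_pool))[seq_len(config$n_baits)]
    truth <- data.frame(gene = genes, module_id = unname(module_id[genes]),
                        is_bait = genes %in% baits,
                        stringsAsFactors = FALSE)
    list(corpus = corpus, truth = truth,
         baits = bait_set(baits, label = "planted-module baits"))
  })
}

#' Simulate two-stage, two-condition expression tables
#'
#' Signals are log-normal with the configured CV around condition means;
#' planted reversal genes have NSN/ctrl mean ratio `effect_ratio` at stage 1
#' and ctrl/NSN mean ratio `effect_ratio` at stage 2. Expressed
#' gene-conditions receive detection p-values well below the 0.01 threshold
#' except with probability `detection_noise`; undetected ones receive
#' p-values in [0.5, 1].
#'
#' @param config a `simulation_config`.
#' @return list with `tables` (nested: `stage1`/`stage2`, each with `ctrl`
#'   and `nsn` `expression_table`s), `truth` (gene, venn, pattern_stage1,
#'   pattern_stage2, planted_reversal, in_external_set) and `external`
#'   (a synthetic `gene_set`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, {
    genes <- sim_gene_names(config)
    n <- config$n_genes
    shuffled <- sample(genes)
    n_unexp <- round(config$unexpressed_fraction * n)
    n_s1 <- round(config$stage1_only_fraction * n)
    n_s2 <- round(config$stage2_only_fraction * n)
    venn <- setNames(rep("both", n), shuffled)
    venn[seq_len(n_unexp)] <- "bait_unexpressed"
    venn[n_unexp + seq_len(n_s1)] <- "stage1_only"
    venn[n_unexp + n_s1 + seq_len(n_s2)] <- "stage2_only"
    both_genes <- shuffled[venn == "both"]
    n_rev <- round(config$reversal_fraction * n)
    if (n_rev < 1 && config$reversal_fraction > 0)
      warn("reversal_fraction * n_genes < 1: zero planted reversal genes")
    planted <- both_genes[seq_len(n_rev)]
    venn <- venn[genes]

    pat1 <- setNames(ifelse(venn %in% c("both", "stage1_only"), "unchanged",
                            "not_expressed"), genes)
    pat2 <- setNames(ifelse(venn %in% c("both", "stage2_only"), "unchanged",
                            "not_expressed"), genes)
    pat1[planted] <- "up"
    pat2[planted] <- "down"

    r <- config$effect_ratio
    m0 <- config$base_signal
    mean_for <- function(stage, condition) {
      expressed <- if (stage == "stage1")
        venn %in% c("both", "stage1_only") else
        venn %in% c("both", "stage2_only")
      m <- ifelse(expressed, m0, config$null_signal)
      is_p <- names(venn) %in% planted
      if (stage == "stage1" && condition == "nsn") m[is_p] <- m0 * r
      if (stage == "stage2" && condition == "ctrl") m[is_p] <- m0 * r
      setNames(m, names(venn))
    }
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    draw_table <- function(stage, condition) {
      m <- mean_for(stage, condition)
      expressed <- venn %in%
        c("both", if (stage == "stage1") "stage1_only" else "stage2_only")
      signal <- matrix(rlnorm(n * config$n_samples,
                              meanlog = rep(log(m) - sdlog^2 / 2,
                                            config$n_samples),
                              sdlog = sdlog),
                       nrow = n)
      flip <- runif(n) < config$detection_noise
      detp <- matrix(NA_real_, n, config$n_samples)
      for (s in seq_len(config$n_samples)) {
        detp[, s] <- ifelse(expressed & !flip, runif(n, 0, 0.005),
                     ifelse(expressed, runif(n, 0.02, 0.5),
                            runif(n, 0.5, 1)))
      }
      expression_table(genes, signal, detp,
                       sample_ids = paste0(condition, "_s",
                                           seq_len(config$n_samples)),
                       stage = stage, condition = condition)
    }
    tables <- list(
      stage1 = list(ctrl = draw_table("stage1", "ctrl"),
                    nsn = draw_table("stage1", "nsn")),
      stage2 = list(ctrl = draw_table("stage2", "ctrl"),
                    nsn = draw_table("stage2", "nsn")))

    n_ext <- round(config$external_fraction * n)
    ext_genes <- sample(genes, n_ext)
    truth <- data.frame(
      gene = genes,
      venn = unname(venn),
      pattern_stage1 = unname(pat1),
      pattern_stage2 = unname(pat2),
      planted_reversal = genes %in% planted,
      in_external_set = genes %in% ext_genes,
      stringsAsFactors = FALSE)
    external <- gene_set("cancer_related_synthetic", ext_genes,
                         source = "synthetic stand-in for a tumour-expression catalogue")
    list(tables = tables, truth = truth, external = external)
  })
}

#' Write a self-describing fixture bundle
#'
#' Emits 8 plain-text files into `out_dir`: four expression TSVs
#' (`expr_stage{1,2}_{ctrl,nsn}.tsv`), `annotations.tsv`, `baits.txt`,
#' `external.gmt`, and `truth.json` (merged truth table plus the config
#' echo and a bundle version). Every file is re-loadable by the package's
#' loaders, and identical configs produce byte-identical bundles.
#'
#' @param config a `simulation_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  corp <- simulate_corpus(config)
  expr <- simulate_expression(config)
  p <- function(f) file.path(out_dir, f)
  files <- c(
    expr_stage1_ctrl = p("expr_stage1_ctrl.tsv"),
    expr_stage1_nsn = p("expr_stage1_nsn.tsv"),
    expr_stage2_ctrl = p("expr_stage2_ctrl.tsv"),
    expr_stage2_nsn = p("expr_stage2_nsn.tsv"),
    annotations = p("annotations.tsv"),
    baits = p("baits.txt"),
    external = p("external.gmt"),
    truth = p("truth.json"))
  write_expression_table(expr$tables$stage1$ctrl, files[["expr_stage1_ctrl"]])
  write_expression_table(expr$tables$stage1$nsn, files[["expr_stage1_nsn"]])
  write_expression_table(expr$tables$stage2$ctrl, files[["expr_stage2_ctrl"]])
  write_expression_table(expr$tables$stage2$nsn, files[["expr_stage2_nsn"]])
  write_annotations(corp$corpus, files[["annotations"]])
  write_gene_list(corp$baits$genes, files[["baits"]])
  write_gmt(expr$external, files[["external"]])
  truth <- merge(corp$truth, expr$truth, by = "gene", sort = TRUE)
  jsonlite::write_json(
    list(bundle_version = 1L, config = unclass(config), truth = truth),
    files[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")
  invisible(files)
}
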