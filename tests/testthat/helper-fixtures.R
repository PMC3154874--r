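# Fixture builders and independent oracles shared across the test files.
# Oracles deliberately take a different computational route from the package
# (explicit vectors, exhaustive enumeration, union-find, igraph distances).

# --- builders ---------------------------------------------------------------

# expression table from per-gene mean signals / detection p-values
make_table <- function(genes, signal, detp, stage = "stage1",
                       condition = "ctrl", samples = 1L) {
  signal <- matrix(rep(signal, samples), ncol = samples)
  detp <- matrix(rep(detp, samples), ncol = samples)
  expression_table(genes, signal, detp,
                   sample_ids = paste0("s", seq_len(samples)),
                   stage = stage, condition = condition)
}

# contrast_calls from direction vectors (fold changes filled arbitrarily)
make_calls <- function(genes, directions, stage = "stage1") {
  out <- data.frame(gene = toupper(genes), direction = directions,
                    fold_change = ifelse(directions %in% c("up", "down"),
                                         2, 1),
                    expressed_ctrl = directions != "not_expressed",
                    expressed_nsn = directions != "not_expressed",
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  attr(out, "stage") <- stage
  class(out) <- c("contrast_calls", "data.frame")
  out
}

# corpus from a list like list(GENEA = list(GO = c(...), MESH = c(...)))
make_corpus <- function(spec) annotation_corpus(spec)

# random corpus: n genes, random term draws per namespace
random_corpus <- function(n_genes = 12, n_terms = 15, max_per_gene = 6,
                          p_empty = 0.1) {
  genes <- sprintf("RG%02d", seq_len(n_genes))
  terms <- list(GO = sprintf("GO:%04d", seq_len(n_terms)),
                MESH = sprintf("D%04d", seq_len(n_terms)))
  assignments <- lapply(genes, function(g) {
    lapply(setNames(c("GO", "MESH"), c("GO", "MESH")), function(ns) {
      if (runif(1) < p_empty) return(character())
      sample(terms[[ns]], sample.int(max_per_gene, 1))
    })
  })
  names(assignments) <- genes
  annotation_corpus(assignments, term_universe = terms)
}

# --- oracles ----------------------------------------------------------------

# brute-force cosine via explicit 0/1 (or idf-weighted) vectors over the
# full term universe
oracle_cosine <- function(corpus, a, b, ns, weighting = "binary") {
  terms <- corpus$term_universe[[ns]]
  vec <- function(g) as.numeric(terms %in% corpus$assignments[[g]][[ns]])
  va <- vec(toupper(a)); vb <- vec(toupper(b))
  if (sum(va) == 0 || sum(vb) == 0) return(NA_real_)
  if (weighting == "idf") {
    df <- sapply(terms, function(t)
      sum(vapply(corpus$assignments, function(x) t %in% x[[ns]], TRUE)))
    w <- log(length(corpus$assignments) / df)
    va <- va * w; vb <- vb * w
    if (sum(va^2) == 0 || sum(vb^2) == 0) return(NA_real_)
  }
  sum(va * vb) / sqrt(sum(va * va) * sum(vb * vb))
}

# exhaustive enumeration of all C(N, n) draws
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- combn(N, n)
  succ <- colSums(draws <= K)  # items 1..K are the successes
  mean(succ >= k)
}

# union-find connected components over an edge list
oracle_components <- function(nodes, edges_a, edges_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (length(edges_a) > 0)
    for (i in seq_along(edges_a)) {
      ra <- find(edges_a[i]); rb <- find(edges_b[i])
      if (ra != rb) parent[[ra]] <- rb
    }
  vapply(nodes, find, "")
}

# multi-source BFS distances via igraph's shortest paths
oracle_bait_distance <- function(network, baits, max_hops) {
  el <- if (nrow(network$edges) == 0)
    data.frame(gene_a = character(), gene_b = character())
  else network$edges[, c("gene_a", "gene_b")]
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE, vertices = data.frame(name = network$nodes))
  baits <- intersect(baits, network$nodes)
  d <- igraph::distances(g, v = baits)
  dmin <- apply(d, 2, min)
  dmin <- dmin[is.finite(dmin) & dmin <= max_hops]
  out <- as.integer(dmin)
  names(out) <- names(dmin)
  out[order(names(out))]
}

# write a small expression TSV from a data.frame-like spec
write_expr_tsv <- function(path, genes, samples, signal, detp) {
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (i in seq_along(samples)) {
    df[[paste0(samples[i], ".signal")]] <- signal[, i]
    df[[paste0(samples[i], ".detp")]] <- detp[, i]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
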