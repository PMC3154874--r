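# Bait-seeded, hop-limited network expansion with expression overlay.
#
# Starting from a bait gene set (e.g. known OCT4-regulated genes), the
# annotation network is explored breadth-first up to a maximum hop count
# (default 2, the reading of "fewer than 3 sequential connections").
# Expression calls at the two stages are then overlaid to partition the
# expanded genes into a Venn of stage-1-only / stage-2-only / both /
# unexpressed compartments, and clusters are extracted as connected
# components of the expressed subgraph.

VENN_LABELS <- c("stage1_only", "stage2_only", "both", "bait_unexpressed")

#' Construct a bait gene set
#'
#' @param genes character vector of bait gene symbols (non-empty).
#' @param label free-text label, e.g. `"OCT4-regulated"`.
#' @return an object of class `bait_set`.
#' @export
bait_set <- function(genes, label = "") {
  genes <- unique(norm_symbols(genes))
  if (length(genes) == 0) abort("bait set is empty")
  structure(list(genes = sort(genes), label = label), class = "bait_set")
}

as_baits <- function(baits) {
  if (inherits(baits, "bait_set")) baits else bait_set(baits)
}

#' Hop-limited expansion from a bait set
#'
#' Multi-source breadth-first search from the baits present in the network;
#' genes farther than `max_hops` edges from every bait are excluded. Baits
#' absent from the network are skipped with a warning (mirroring baits that
#' lack annotation); if no bait is present an error lists the missing ones.
#'
#' @param network an `annotation_network`.
#' @param baits a `bait_set` or character vector.
#' @param max_hops non-negative integer; default 2 (i.e. fewer than 3
#'   sequential connections).
#' @return named integer vector of hop distances (0 for baits), sorted by
#'   gene, covering exactly the genes retained.
#' @export
hop_expand <- function(network, baits, max_hops = 2L) {
  stopifnot(inherits(network, "annotation_network"))
  max_hops <- check_count(max_hops, "max_hops")
  baits <- as_baits(baits)
  present <- intersect(baits$genes, network$nodes)
  absent <- setdiff(baits$genes, network$nodes)
  if (length(present) == 0)
    abort("no bait present in the network; missing baits: %s",
          paste(absent, collapse = ", "))
  if (length(absent) > 0)
    warn("%d bait(s) absent from the network and skipped: %s",
         length(absent), paste(absent, collapse = ", "))

  adj <- if (nrow(network$edges) == 0) list() else local({
    e <- network$edges
    split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b))
  })
  dist <- setNames(rep(NA_integer_, length(network$nodes)), network$nodes)
  dist[present] <- 0L
  frontier <- present
  d <- 0L
  while (length(frontier) > 0 && d < max_hops) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    nb <- nb[!is.na(nb) & is.na(dist[nb])]
    d <- d + 1L
    dist[nb] <- d
    frontier <- nb
  }
  out <- dist[!is.na(dist)]
  out[order(names(out))]
}

#' Overlay two-stage expression calls onto an expanded gene set
#'
#' A gene is "expressed at a stage" iff its contrast-call direction there is
#' not `not_expressed` (i.e. it was detected in at least one condition).
#' Genes expressed at neither stage are labelled `bait_unexpressed` and are
#' excluded from the expressed-network gene count.
#'
#' @param genes character vector of expanded genes.
#' @param stage1_calls,stage2_calls `contrast_calls` for the two stages.
#' @return named character vector of Venn labels (`stage1_only`,
#'   `stage2_only`, `both`, `bait_unexpressed`), sorted by gene.
#' @export
overlay_expression <- function(genes, stage1_calls, stage2_calls) {
  genes <- sort(unique(norm_symbols(genes)))
  if (length(genes) == 0) abort("empty gene set")
  d1 <- setNames(stage1_calls$direction, stage1_calls$gene)
  d2 <- setNames(stage2_calls$direction, stage2_calls$gene)
  in_neither <- !(genes %in% names(d1)) & !(genes %in% names(d2))
  if (any(in_neither))
    warn("%d gene(s) missing from both call lists, treated as not expressed: %s",
         sum(in_neither), paste(utils::head(genes[in_neither], 5),
                                collapse = ", "))
  e1 <- !is.na(d1[genes]) & d1[genes] != "not_expressed"
  e2 <- !is.na(d2[genes]) & d2[genes] != "not_expressed"
  lab <- ifelse(e1 & e2, "both",
         ifelse(e1, "stage1_only",
         ifelse(e2, "stage2_only", "bait_unexpressed")))
  setNames(lab, genes)
}

#' Extract gene clusters as connected components
#'
#' Clusters are the connected components of the subgraph induced on
#' `kept_genes` (isolated kept genes form singleton clusters). Cluster ids
#' are assigned in decreasing size order, ties broken by the
#' lexicographically smallest member. Whether every cluster contains a core
#' (`both`-labelled) gene is reported, not enforced.
#'
#' @param network an `annotation_network`.
#' @param kept_genes genes to induce on (subset of the network's nodes).
#' @param venn_label optional named Venn labels used to fill `core_members`.
#' @param baits optional `bait_set` or character vector for `bait_members`.
#' @return list of `gene_cluster` objects (possibly empty).
#' @export
extract_clusters <- function(network, kept_genes, venn_label = NULL,
                             baits = NULL) {
  stopifnot(inherits(network, "annotation_network"))
  kept_genes <- unique(norm_symbols(kept_genes))
  missing <- setdiff(kept_genes, network$nodes)
  if (length(missing) > 0)
    abort("kept gene not in network: '%s'", missing[1])
  if (length(kept_genes) == 0) return(list())
  g <- as_igraph(network, nodes = sort(kept_genes))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  ord <- order(-lengths(members), vapply(members, `[`, "", 1L))
  members <- members[ord]
  bait_genes <- if (is.null(baits)) character() else as_baits(baits)$genes
  lapply(seq_along(members), function(k) {
    m <- members[[k]]
    core <- if (is.null(venn_label)) character()
            else m[!is.na(venn_label[m]) & venn_label[m] == "both"]
    structure(list(cluster_id = k, members = m,
                   core_members = unname(core),
                   bait_members = intersect(m, bait_genes),
                   has_core = length(core) > 0),
              class = "gene_cluster")
  })
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("cluster %d: %d genes (%d core, %d bait)\n", x$cluster_id,
              length(x$members), length(x$core_members),
              length(x$bait_members)))
  invisible(x)
}

#' Full bait-seeded expansion pipeline
#'
#' Deterministic composition: build the annotation network over the corpus
#' genes, expand from the baits under the hop limit, overlay the two-stage
#' expression calls to obtain the Venn partition, and extract clusters from
#' the expressed subgraph. With `expression_first = TRUE` the network is
#' instead built only over genes expressed at at least one stage.
#'
#' @param corpus an `annotation_corpus`.
#' @param baits a `bait_set` or character vector.
#' @param stage1_calls,stage2_calls `contrast_calls` for the two stages.
#' @param cutoff similarity cutoff (strict), default 0.7.
#' @param max_hops hop limit, default 2.
#' @param weighting similarity weighting, `"binary"` or `"idf"`.
#' @param expression_first restrict the network to expressed genes before
#'   expansion (default FALSE: annotate first, intersect with expression
#'   afterwards).
#' @return an `expanded_network`: list with the induced `network`,
#'   `bait_distance`, `venn_label`, `clusters` and a `summary` of counts.
#' @export
expand_pipeline <- function(corpus, baits, stage1_calls, stage2_calls,
                            cutoff = 0.7, max_hops = 2L,
                            weighting = c("binary", "idf"),
                            expression_first = FALSE) {
  weighting <- match.arg(weighting)
  baits <- as_baits(baits)
  genes <- corpus_genes(corpus)
  if (expression_first) {
    venn_all <- suppressWarnings(
      overlay_expression(genes, stage1_calls, stage2_calls))
    genes <- names(venn_all)[venn_all != "bait_unexpressed"]
    genes <- union(genes, intersect(baits$genes, corpus_genes(corpus)))
  }
  net <- build_network(corpus, genes, cutoff = cutoff, weighting = weighting)
  dist <- hop_expand(net, baits, max_hops = max_hops)
  expanded <- names(dist)
  venn <- overlay_expression(expanded, stage1_calls, stage2_calls)
  kept <- expanded[venn[expanded] != "bait_unexpressed"]
  clusters <- extract_clusters(net, kept, venn_label = venn, baits = baits)

  sub_edges <- net$edges[net$edges$gene_a %in% expanded &
                         net$edges$gene_b %in% expanded, , drop = FALSE]
  subnet <- annotation_network(expanded, sub_edges, cutoff, weighting)
  venn_counts <- vapply(VENN_LABELS, function(l) sum(venn == l), 0L)
  structure(list(
    network = subnet,
    bait_distance = dist,
    venn_label = venn,
    clusters = clusters,
    summary = list(
      n_network_genes = length(expanded),
      n_expressed = length(kept),
      venn_counts = as.list(venn_counts),
      n_clusters = length(clusters),
      all_clusters_have_core =
        length(clusters) > 0 && all(vapply(clusters, `[[`, TRUE, "has_core")))),
    class = "expanded_network")
}

#' @export
print.expanded_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("expanded_network: %d genes (%d expressed), %d clusters\n",
              s$n_network_genes, s$n_expressed, s$n_clusters))
  cat(sprintf("  venn: stage1_only=%d stage2_only=%d both=%d unexpressed=%d\n",
              s$venn_counts$stage1_only, s$venn_counts$stage2_only,
              s$venn_counts$both, s$venn_counts$bait_unexpressed))
  invisible(x)
}

#' Write an expansion report as JSON
#'
#' The report contains the Venn counts, cluster memberships and per-gene
#' labels and bait distances; identical inputs produce byte-identical files.
#'
#' @param expanded an `expanded_network`.
#' @param path output path.
#' @export
write_expansion_report <- function(expanded, path) {
  stopifnot(inherits(expanded, "expanded_network"))
  genes <- names(expanded$venn_label)
  report <- list(
    summary = expanded$summary,
    genes = data.frame(
      gene = genes,
      venn_label = unname(expanded$venn_label[genes]),
      bait_distance = unname(expanded$bait_distance[genes]),
      stringsAsFactors = FALSE),
    clusters = lapply(expanded$clusters, function(cl)
      list(cluster_id = cl$cluster_id, members = cl$members,
           core_members = cl$core_members, bait_members = cl$bait_members,
           has_core = cl$has_core)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export an expanded network to GraphML with overlay attributes
#'
#' Adds `venn_label` and `bait_distance` node attributes on top of the edge
#' attributes written by [export_network()].
#'
#' @param expanded an `expanded_network`.
#' @param path output path.
#' @export
export_expanded_network <- function(expanded, path) {
  stopifnot(inherits(expanded, "expanded_network"))
  net <- expanded$network
  if (length(net$nodes) == 0) abort("cannot export an empty network")
  g <- as_igraph(net)
  if (nrow(net$edges) > 0) {
    enc <- function(x) ifelse(is.na(x), -1, x)
    igraph::E(g)$sim_go <- enc(net$edges$sim_go)
    igraph::E(g)$sim_mesh <- enc(net$edges$sim_mesh)
    igraph::E(g)$support <- net$edges$support
    igraph::E(g)$weight <- net$edges$weight
  }
  nm <- igraph::V(g)$name
  igraph::V(g)$venn_label <- unname(expanded$venn_label[nm])
  igraph::V(g)$bait_distance <- unname(expanded$bait_distance[nm])
  g <- igraph::set_graph_attr(g, "cutoff", net$cutoff)
  g <- igraph::set_graph_attr(g, "weighting", net$weighting)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
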