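# Annotation-similarity network construction and GraphML / SIF export.
#
# For every unordered gene pair, per-namespace cosine similarity is computed
# and an undirected edge is created iff at least one namespace similarity
# STRICTLY exceeds the cutoff (default 0.7). Edge "support" records which
# namespace(s) exceed the cutoff (GO / MESH / BOTH), mirroring the three
# edge colours of published annotation-network figures; edge weight is the
# maximum of the defined namespace similarities.

#' Construct an annotation network object
#'
#' Usually produced by [build_network()]; exposed for import and testing.
#'
#' @param nodes character vector of gene symbols.
#' @param edges data.frame with columns `gene_a`, `gene_b` (with
#'   `gene_a < gene_b`), `sim_go`, `sim_mesh` (NA when undefined), `support`
#'   (`GO`/`MESH`/`BOTH`), `weight`.
#' @param cutoff similarity cutoff in (0, 1).
#' @param weighting `"binary"` or `"idf"`.
#' @return an object of class `annotation_network`.
#' @export
annotation_network <- function(nodes, edges, cutoff, weighting = "binary") {
  nodes <- sort(norm_symbols(nodes))
  if (nrow(edges) > 0) {
    stopifnot(all(c("gene_a", "gene_b", "sim_go", "sim_mesh",
                    "support", "weight") %in% names(edges)))
    if (any(edges$gene_a >= edges$gene_b))
      abort("edges must satisfy gene_a < gene_b")
    if (any(!edges$gene_a %in% nodes) || any(!edges$gene_b %in% nodes))
      abort("edge endpoint not in node set")
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, cutoff = as.numeric(cutoff),
                 weighting = weighting),
            class = "annotation_network")
}

#' @export
print.annotation_network <- function(x, ...) {
  cat(sprintf(
    "annotation_network: %d nodes, %d edges (cutoff %g, %s weighting)\n",
    length(x$nodes), nrow(x$edges), x$cutoff, x$weighting))
  if (nrow(x$edges) > 0)
    print(table(support = x$edges$support))
  invisible(x)
}

empty_edges <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             sim_go = numeric(), sim_mesh = numeric(),
             support = character(), weight = numeric(),
             stringsAsFactors = FALSE)
}

# per-namespace similarities for all pairs with a non-zero dot product;
# returns list(sims = data.frame(i, j, sim), defined = logical per gene)
pair_similarities <- function(corpus, namespace, genes, weighting) {
  X <- incidence_matrix(corpus, namespace, genes, weighting)
  sq <- Matrix::rowSums(X^2)
  C <- Matrix::tcrossprod(X)
  # force general (both-triangle) storage before reading triplets
  C <- methods::as(methods::as(C, "generalMatrix"), "TsparseMatrix")
  keep <- C@i < C@j
  i <- C@i[keep] + 1L
  j <- C@j[keep] + 1L
  sim <- C@x[keep] / sqrt(sq[i] * sq[j])
  list(sims = data.frame(i = i, j = j, sim = sim), defined = sq > 0)
}

#' Build the gene-gene annotation-similarity network
#'
#' An edge is created between two genes iff the cosine similarity of their
#' term vectors strictly exceeds `cutoff` in at least one namespace.
#'
#' @param corpus an `annotation_corpus`.
#' @param genes genes to include (default: all corpus genes); at least 2.
#' @param cutoff similarity cutoff in (0, 1); strict comparison. Default 0.7.
#' @param weighting term weighting passed to the similarity computation.
#' @return an `annotation_network` with deterministic node/edge ordering.
#' @export
build_network <- function(corpus, genes = NULL, cutoff = 0.7,
                          weighting = c("binary", "idf")) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  weighting <- match.arg(weighting)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1)
    abort("cutoff must be in (0, 1)")
  if (is.null(genes)) genes <- corpus_genes(corpus)
  genes <- sort(unique(norm_symbols(genes)))
  missing <- setdiff(genes, corpus_genes(corpus))
  if (length(missing) > 0) abort("gene not in corpus: '%s'", missing[1])
  if (length(genes) < 2) abort("at least 2 genes are required")

  ps <- lapply(setNames(NAMESPACES, NAMESPACES), function(ns)
    pair_similarities(corpus, ns, genes, weighting))

  key <- function(d) paste(d$i, d$j)
  go <- ps$GO$sims; mesh <- ps$MESH$sims
  go_pass <- go[go$sim > cutoff, , drop = FALSE]
  mesh_pass <- mesh[mesh$sim > cutoff, , drop = FALSE]
  all_keys <- union(key(go_pass), key(mesh_pass))
  if (length(all_keys) == 0)
    return(annotation_network(genes, empty_edges(), cutoff, weighting))

  ij <- do.call(rbind, strsplit(all_keys, " ", fixed = TRUE))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  lookup <- function(d, defined) {
    v <- setNames(d$sim, key(d))[paste(i, j)]
    v[is.na(v)] <- 0  # annotated pair with no shared terms
    v[!defined[i] | !defined[j]] <- NA_real_
    unname(v)
  }
  sim_go <- lookup(go, ps$GO$defined)
  sim_mesh <- lookup(mesh, ps$MESH$defined)
  go_sup <- !is.na(sim_go) & sim_go > cutoff
  mesh_sup <- !is.na(sim_mesh) & sim_mesh > cutoff
  edges <- data.frame(
    gene_a = genes[i], gene_b = genes[j],
    sim_go = sim_go, sim_mesh = sim_mesh,
    support = ifelse(go_sup & mesh_sup, "BOTH",
                     ifelse(go_sup, "GO", "MESH")),
    weight = pmax(ifelse(is.na(sim_go), -Inf, sim_go),
                  ifelse(is.na(sim_mesh), -Inf, sim_mesh)),
    stringsAsFactors = FALSE)
  annotation_network(genes, edges, cutoff, weighting)
}

as_igraph <- function(network, nodes = NULL) {
  nodes <- nodes %||% network$nodes
  e <- network$edges
  if (nrow(e) == 0) e <- empty_edges()
  e <- e[e$gene_a %in% nodes & e$gene_b %in% nodes, , drop = FALSE]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Export an annotation network to GraphML or SIF
#'
#' GraphML carries `sim_go`, `sim_mesh`, `support` and `weight` as edge
#' attributes (undefined similarities encoded as -1) and the cutoff and
#' weighting as graph attributes, so [import_network()] reproduces the
#' network exactly. SIF uses the support label as the interaction type;
#' isolated nodes are written as single-field lines.
#'
#' @param network an `annotation_network` (non-empty).
#' @param path output path.
#' @param format `"graphml"` or `"sif"`.
#' @export
export_network <- function(network, path, format = c("graphml", "sif")) {
  stopifnot(inherits(network, "annotation_network"))
  if (length(format) != 1L || !format %in% c("graphml", "sif"))
    abort("unknown format '%s' (expected graphml or sif)",
          paste(format, collapse = ","))
  if (length(network$nodes) == 0) abort("cannot export an empty network")
  if (format == "sif") {
    e <- network$edges
    lines <- character()
    if (nrow(e) > 0)
      lines <- paste(e$gene_a, e$support, e$gene_b, sep = "\t")
    isolated <- setdiff(network$nodes, c(e$gene_a, e$gene_b))
    writeLines(c(lines, isolated), path)
    return(invisible(path))
  }
  g <- as_igraph(network)
  if (nrow(network$edges) > 0) {
    enc <- function(x) ifelse(is.na(x), -1, x)
    igraph::E(g)$sim_go <- enc(network$edges$sim_go)
    igraph::E(g)$sim_mesh <- enc(network$edges$sim_mesh)
    igraph::E(g)$support <- network$edges$support
    igraph::E(g)$weight <- network$edges$weight
  }
  g <- igraph::set_graph_attr(g, "cutoff", network$cutoff)
  g <- igraph::set_graph_attr(g, "weighting", network$weighting)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a GraphML network written by [export_network()]
#'
#' @param path GraphML file path.
#' @return an `annotation_network`.
#' @export
import_network <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  cutoff <- igraph::graph_attr(g, "cutoff") %||% NA_real_
  weighting <- igraph::graph_attr(g, "weighting") %||% "binary"
  if (igraph::ecount(g) == 0)
    return(annotation_network(nodes, empty_edges(), cutoff, weighting))
  el <- igraph::as_edgelist(g)
  dec <- function(x) ifelse(x < 0, NA_real_, x)
  edges <- data.frame(
    gene_a = pmin(el[, 1], el[, 2]),
    gene_b = pmax(el[, 1], el[, 2]),
    sim_go = dec(igraph::E(g)$sim_go),
    sim_mesh = dec(igraph::E(g)$sim_mesh),
    support = igraph::E(g)$support,
    weight = igraph::E(g)$weight,
    stringsAsFactors = FALSE)
  annotation_network(nodes, edges, cutoff, weighting)
}
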