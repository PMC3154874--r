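# Gene -> term annotation corpora and term-vector similarity.
#
# Each gene carries a set of annotation terms in each of two namespaces (GO
# and MeSH). Similarity between two genes within a namespace is the cosine
# of their term-incidence vectors; with binary weighting this reduces to
# |A n B| / sqrt(|A| * |B|). A gene with no terms in a namespace has
# *undefined* similarity there (unannotated is not the same as dissimilar).

NAMESPACES <- c("GO", "MESH")

norm_namespace <- function(ns) {
  ns <- toupper(as.character(ns))
  ns[ns == "MeSH"] <- "MESH"
  ns
}

#' Construct an annotation corpus
#'
#' @param assignments named list: gene symbol -> list with elements `GO` and
#'   `MESH`, each a character vector of term identifiers (possibly empty).
#' @param term_universe optional named list (`GO`, `MESH`) of all terms per
#'   namespace; defaults to the union of assigned terms.
#' @return an object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(assignments, term_universe = NULL) {
  if (length(assignments) == 0) abort("empty annotation corpus")
  genes <- norm_symbols(names(assignments))
  if (anyDuplicated(genes)) abort("duplicate gene in corpus: '%s'",
                                  genes[duplicated(genes)][1])
  names(assignments) <- genes
  assignments <- lapply(assignments, function(a) {
    list(GO = unique(as.character(a$GO %||% character())),
         MESH = unique(as.character(a$MESH %||% character())))
  })
  assignments <- assignments[order(genes)]
  if (is.null(term_universe)) {
    term_universe <- lapply(setNames(NAMESPACES, NAMESPACES), function(ns)
      sort(unique(unlist(lapply(assignments, `[[`, ns), use.names = FALSE))))
  } else {
    for (ns in NAMESPACES) {
      assigned <- unique(unlist(lapply(assignments, `[[`, ns),
                                use.names = FALSE))
      missing <- setdiff(assigned, term_universe[[ns]])
      if (length(missing) > 0)
        abort("term '%s' assigned but absent from %s universe",
              missing[1], ns)
    }
  }
  structure(list(assignments = assignments, term_universe = term_universe),
            class = "annotation_corpus")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation_corpus: %d genes; %d GO terms, %d MeSH terms\n",
              length(x$assignments), length(x$term_universe$GO),
              length(x$term_universe$MESH)))
  invisible(x)
}

#' Genes of an annotation corpus
#' @param corpus an `annotation_corpus`.
#' @return sorted character vector of gene symbols.
#' @export
corpus_genes <- function(corpus) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  names(corpus$assignments)
}

term_set <- function(corpus, gene, namespace) {
  corpus$assignments[[gene]][[namespace]]
}

#' Read gene annotations from a 3-column TSV
#'
#' Columns: gene, namespace (`GO` or `MESH`), term. No header; `#` comment
#' lines allowed.
#'
#' @param path file path.
#' @return an `annotation_corpus`.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("gene", "namespace", "term"))
  if (nrow(df) == 0) abort("empty annotation file: %s", path)
  df$namespace <- norm_namespace(df$namespace)
  bad <- setdiff(unique(df$namespace), NAMESPACES)
  if (length(bad) > 0)
    abort("format error: unknown namespace '%s' (expected GO or MESH)", bad[1])
  df$gene <- norm_symbols(df$gene)
  assignments <- lapply(split(df[c("namespace", "term")], df$gene), function(d)
    list(GO = unique(d$term[d$namespace == "GO"]),
         MESH = unique(d$term[d$namespace == "MESH"])))
  annotation_corpus(assignments)
}

#' Write an annotation corpus as a 3-column TSV
#' @param corpus an `annotation_corpus`.
#' @param path output path.
#' @export
write_annotations <- function(corpus, path) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  con <- file(path, "w")
  on.exit(close(con))
  for (g in corpus_genes(corpus))
    for (ns in NAMESPACES) {
      terms <- term_set(corpus, g, ns)
      if (length(terms) > 0)
        writeLines(paste(g, ns, sort(terms), sep = "\t"), con)
    }
  invisible(path)
}

idf_weights <- function(corpus, namespace) {
  n <- length(corpus$assignments)
  df <- table(unlist(lapply(corpus$assignments, `[[`, namespace),
                     use.names = FALSE))
  w <- log(n / as.numeric(df))
  setNames(w, names(df))
}

#' Annotation similarity between two genes in one namespace
#'
#' Cosine similarity of the genes' term vectors. With `binary` weighting this
#' is `|A n B| / sqrt(|A| * |B|)`. With `idf` weighting each term is weighted
#' by `log(N / df)` where `df` is the number of corpus genes carrying the
#' term, down-weighting ubiquitous terms. If either gene has no terms (or,
#' under idf, a zero-norm vector), the similarity is undefined and `NA` is
#' returned.
#'
#' @param corpus an `annotation_corpus`.
#' @param a,b gene symbols (case-insensitive).
#' @param namespace `"GO"` or `"MESH"`.
#' @param weighting `"binary"` (default) or `"idf"`.
#' @return numeric in [0, 1], or `NA` if undefined.
#' @export
annotation_similarity <- function(corpus, a, b, namespace,
                                  weighting = c("binary", "idf")) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  weighting <- match.arg(weighting)
  namespace <- norm_namespace(namespace)
  if (!namespace %in% NAMESPACES) abort("unknown namespace '%s'", namespace)
  a <- norm_symbols(a); b <- norm_symbols(b)
  for (g in c(a, b))
    if (is.null(corpus$assignments[[g]])) abort("unknown gene '%s'", g)
  A <- term_set(corpus, a, namespace)
  B <- term_set(corpus, b, namespace)
  if (length(A) == 0 || length(B) == 0) return(NA_real_)
  if (weighting == "binary") {
    length(intersect(A, B)) / sqrt(length(A) * length(B))
  } else {
    w <- idf_weights(corpus, namespace)
    num <- sum(w[intersect(A, B)]^2)
    den <- sqrt(sum(w[A]^2) * sum(w[B]^2))
    if (den == 0) return(NA_real_)
    num / den
  }
}

# genes x terms incidence matrix for one namespace (sparse)
incidence_matrix <- function(corpus, namespace, genes,
                             weighting = "binary") {
  terms <- corpus$term_universe[[namespace]]
  sets <- lapply(genes, function(g) term_set(corpus, g, namespace))
  lens <- lengths(sets)
  i <- rep(seq_along(genes), lens)
  j <- match(unlist(sets, use.names = FALSE), terms)
  x <- rep(1, length(j))
  if (weighting == "idf") {
    w <- idf_weights(corpus, namespace)
    x <- unname(w[unlist(sets, use.names = FALSE)])
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(genes), max(length(terms), 1L)),
                       dimnames = list(genes, NULL))
}
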