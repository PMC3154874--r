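# Term enrichment of a regulated gene list, with macro-category rollup.
#
# Each term annotated to at least one list gene is tested with the
# hypergeometric upper tail against a reference universe (the
# "entire genome" analog); terms at or below the p threshold (default 0.01)
# are retained. Enriched terms can then be rolled up into expert-defined
# macro categories, tallying the distinct up- and down-regulated genes
# under each category. No term propagation up the GO graph is performed: a
# gene counts for exactly the terms assigned in the corpus.

#' Hypergeometric term enrichment
#'
#' For every term (in the requested namespaces) annotated to at least one
#' list gene: `N` = universe size, `K` = universe genes carrying the term,
#' `n` = list size, `k` = list genes carrying the term; upper-tail p-value.
#' Records with `p <= p_threshold` are retained, sorted by p then term id.
#'
#' @param gene_list character vector of genes, subset of `universe`.
#' @param corpus an `annotation_corpus` covering the universe.
#' @param universe background genes; default: all corpus genes.
#' @param p_threshold retention threshold on the enrichment p (default
#'   0.01, inclusive).
#' @param namespaces namespaces to test (default both GO and MESH).
#' @return data.frame of class `enrichment_records` with columns `term`,
#'   `namespace`, `annotated_in_list`, `annotated_in_universe`, `p_value`,
#'   `macro_category` (NA until assigned); the list genes per retained term
#'   are kept in the `term_genes` attribute.
#' @export
enrich_terms <- function(gene_list, corpus, universe = NULL,
                         p_threshold = 0.01,
                         namespaces = c("GO", "MESH")) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  namespaces <- norm_namespace(namespaces)
  if (!all(namespaces %in% NAMESPACES)) abort("unknown namespace")
  gene_list <- unique(norm_symbols(gene_list))
  if (length(gene_list) == 0) abort("empty gene list")
  if (is.null(universe)) universe <- corpus_genes(corpus)
  universe <- unique(norm_symbols(universe))
  if (length(universe) == 0) abort("empty universe")
  if (length(setdiff(universe, corpus_genes(corpus))) > 0)
    abort("universe gene not in corpus: '%s'",
          setdiff(universe, corpus_genes(corpus))[1])
  if (length(setdiff(gene_list, universe)) > 0)
    abort("list gene not in universe: '%s'",
          setdiff(gene_list, universe)[1])

  rows <- list()
  term_genes <- list()
  for (ns in namespaces) {
    uni_terms <- lapply(corpus$assignments[universe], `[[`, ns)
    term2gene <- split(rep(universe, lengths(uni_terms)),
                       unlist(uni_terms, use.names = FALSE))
    for (term in names(term2gene)) {
      in_list <- intersect(term2gene[[term]], gene_list)
      if (length(in_list) == 0) next
      p <- hypergeom_upper_tail(length(universe), length(term2gene[[term]]),
                                length(gene_list), length(in_list))
      if (p > p_threshold) next
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, namespace = ns,
        annotated_in_list = length(in_list),
        annotated_in_universe = length(term2gene[[term]]),
        p_value = p, macro_category = NA_character_,
        stringsAsFactors = FALSE)
      term_genes[[paste(ns, term)]] <- sort(in_list)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(term = character(), namespace = character(),
               annotated_in_list = integer(), annotated_in_universe = integer(),
               p_value = numeric(), macro_category = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "term_genes") <- term_genes
  attr(out, "n_list") <- length(gene_list)
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Read a macro-category map
#'
#' Two-column TSV `term_or_glob<TAB>category`, no header, `#` comments.
#' Patterns may be exact term ids or shell-style globs (e.g. `GO:001*`);
#' the first matching row wins, so order encodes precedence.
#'
#' @param path file path.
#' @return data.frame of class `macro_map` with columns `pattern`,
#'   `category`.
#' @export
read_macro_map <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("pattern", "category"))
  class(df) <- c("macro_map", "data.frame")
  df
}

#' Construct a macro-category map in code
#' @param pattern character vector of term ids or globs.
#' @param category parallel character vector of category labels.
#' @return a `macro_map` data.frame.
#' @export
macro_map <- function(pattern = character(), category = character()) {
  stopifnot(length(pattern) == length(category))
  structure(data.frame(pattern = as.character(pattern),
                       category = as.character(category),
                       stringsAsFactors = FALSE),
            class = c("macro_map", "data.frame"))
}

assign_macro <- function(terms, map) {
  if (nrow(map) == 0) return(rep("unassigned", length(terms)))
  vapply(terms, function(t) {
    for (r in seq_len(nrow(map))) {
      pat <- map$pattern[r]
      if (t == pat || grepl(glob2rx(pat), t)) return(map$category[r])
    }
    "unassigned"
  }, "", USE.NAMES = FALSE)
}

#' Roll enriched terms up into macro categories
#'
#' Each enriched term is assigned to at most one category (unmapped terms
#' fall under `unassigned`). A category's tally counts the *distinct* list
#' genes annotated to any of its terms, split by the stage-1 contrast
#' direction; a gene annotated to terms of two categories is counted in
#' both, so tallies are not a partition of the gene list.
#'
#' @param records non-empty `enrichment_records` from [enrich_terms()].
#' @param map a `macro_map`.
#' @param stage1_calls `contrast_calls` supplying up/down directions.
#' @return data.frame with columns `category`, `n_up`, `n_down`, `n_genes`
#'   (distinct genes), ordered by category with `unassigned` last.
#' @export
rollup_macro <- function(records, map, stage1_calls) {
  stopifnot(inherits(records, "enrichment_records"))
  if (nrow(records) == 0) abort("no enrichment records to roll up")
  term_genes <- attr(records, "term_genes")
  cat_of <- assign_macro(records$term, map)
  dirs <- setNames(stage1_calls$direction, stage1_calls$gene)
  cats <- unique(cat_of)
  cats <- c(sort(setdiff(cats, "unassigned")),
            intersect("unassigned", cats))
  rows <- lapply(cats, function(cc) {
    keys <- paste(records$namespace, records$term)[cat_of == cc]
    genes <- unique(unlist(term_genes[keys], use.names = FALSE))
    d <- dirs[genes]
    data.frame(category = cc,
               n_up = sum(!is.na(d) & d == "up"),
               n_down = sum(!is.na(d) & d == "down"),
               n_genes = length(genes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
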