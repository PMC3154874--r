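# Joint two-stage expression patterns and exact hypergeometric tests.
#
# A gene's pattern is the pair of contrast directions at the two stages;
# the focal "reversal" pattern (up in the incompetent oocyte contrast, down
# in the incompetent embryo contrast) is the signature of maternal
# transcripts whose repression is released after fertilisation. Enrichment
# of a pattern within a bait set, and overlap of a network with an external
# gene set, are both scored with the exact hypergeometric upper tail.

#' Joint differential pattern of a gene across the two stages
#'
#' @param stage1_calls,stage2_calls `contrast_calls` for the two stages.
#' @param gene gene symbol; must be present in at least one call list
#'   (missing stage counts as `not_expressed`).
#' @return named character vector `c(stage1 = ..., stage2 = ...)`.
#' @export
joint_pattern <- function(stage1_calls, stage2_calls, gene) {
  gene <- norm_symbols(gene)
  if (length(gene) != 1L) abort("one gene at a time")
  d1 <- stage1_calls$direction[match(gene, stage1_calls$gene)]
  d2 <- stage2_calls$direction[match(gene, stage2_calls$gene)]
  if (is.na(d1) && is.na(d2))
    abort("gene '%s' absent from both call lists", gene)
  c(stage1 = ifelse(is.na(d1), "not_expressed", d1),
    stage2 = ifelse(is.na(d2), "not_expressed", d2))
}

#' Counts of genes per joint pattern
#'
#' Exhaustive tally over the 16 (stage1 direction, stage2 direction)
#' combinations; counts sum to the number of input genes. Genes missing
#' from a call list count as `not_expressed` at that stage (with a warning
#' if missing from both).
#'
#' @param genes non-empty character vector of gene symbols.
#' @param stage1_calls,stage2_calls `contrast_calls` for the two stages.
#' @return data.frame with columns `stage1`, `stage2`, `count` (16 rows).
#' @export
pattern_partition <- function(genes, stage1_calls, stage2_calls) {
  genes <- unique(norm_symbols(genes))
  if (length(genes) == 0) abort("empty gene set")
  d1 <- stage1_calls$direction[match(genes, stage1_calls$gene)]
  d2 <- stage2_calls$direction[match(genes, stage2_calls$gene)]
  if (any(is.na(d1) & is.na(d2)))
    warn("%d gene(s) absent from both call lists, counted as not_expressed",
         sum(is.na(d1) & is.na(d2)))
  d1[is.na(d1)] <- "not_expressed"
  d2[is.na(d2)] <- "not_expressed"
  tab <- table(factor(d1, DIRECTIONS), factor(d2, DIRECTIONS))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("stage1", "stage2", "count")
  out <- out[order(match(out$stage1, DIRECTIONS),
                   match(out$stage2, DIRECTIONS)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_hyper_args <- function(N, K, n, k) {
  N <- check_count(N, "N", 1L); K <- check_count(K, "K")
  n <- check_count(n, "n"); k <- check_count(k, "k")
  if (K > N) abort("K must satisfy 0 <= K <= N")
  if (n > N) abort("n must satisfy 0 <= n <= N")
  if (k > min(n, K)) abort("k must satisfy 0 <= k <= min(n, K)")
  list(N = N, K = K, n = n, k = k)
}

# Exact pmf over the whole support, evaluated in linear space: the mode
# term is an anchored product of O(n) bounded ratios (with power-of-two
# rescaling against under/overflow) and the remaining terms follow by the
# adjacent-k ratio recurrence. Differences of large log-factorials
# (lgamma/lchoose) carry ~1e-11 absolute log error at N ~ 1e4, which would
# break the 1e-12 normalization bound; the product form keeps the relative
# error near machine epsilon.
hyper_pmf_support <- function(N, K, n) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  ks <- lo:hi
  km <- as.integer(floor((n + 1) * ((K + 1) / (N + 2))))
  km <- min(max(km, lo), hi)
  # anchor: p(km) = prod_{i<km} (K-i)(n-i) / ((i+1)(N-i))
  #               * prod_{j<n-km} (N-K-j) / (N-km-j)
  m <- 1
  sc <- 0L
  i <- 0L
  while (i < km) {
    m <- m * (((K - i) * (n - i)) / ((i + 1) * (N - i)))
    i <- i + 1L
    if (m > 1e150 || m < 1e-150) {
      ex <- as.integer(floor(log2(m)))
      m <- m / 2^ex
      sc <- sc + ex
    }
  }
  j <- 0L
  while (j < n - km) {
    m <- m * ((N - K - j) / (N - km - j))
    j <- j + 1L
    if (m > 1e150 || m < 1e-150) {
      ex <- as.integer(floor(log2(m)))
      m <- m / 2^ex
      sc <- sc + ex
    }
  }
  h <- sc %/% 2L
  p_km <- (m * 2^h) * 2^(sc - h)
  p <- numeric(length(ks))
  p[km - lo + 1L] <- p_km
  if (km < hi)
    for (k in km:(hi - 1L))
      p[k - lo + 2L] <- p[k - lo + 1L] *
        (((K - k) * (n - k)) / ((k + 1) * (N - K - n + k + 1)))
  if (km > lo)
    for (k in km:(lo + 1L))
      p[k - lo] <- p[k - lo + 1L] *
        ((k * (N - K - n + k)) / ((K - k + 1) * (n - k + 1)))
  setNames(p, ks)
}

#' Hypergeometric probability mass function
#'
#' Exact pmf of the number of successes when drawing `n` items without
#' replacement from a population of `N` containing `K` successes. Evaluated
#' stably at large `N` (no naive factorials): an anchored product of bounded
#' ratios at the mode plus the adjacent-`k` recurrence, accurate to near
#' machine epsilon even at `N` of 1e5.
#'
#' @param N population size; `K` successes in the population; `n` draws.
#' @param K,n see `N`.
#' @return named numeric vector over the support
#'   `max(0, n - (N - K)) .. min(n, K)`; sums to 1.
#' @export
hypergeom_pmf <- function(N, K, n) {
  a <- check_hyper_args(N, K, n, 0L)
  hyper_pmf_support(a$N, a$K, a$n)
}

#' Hypergeometric upper-tail probability P[X >= k]
#'
#' Exact one-sided over-representation p-value, inclusive of the observed
#' count: the probability of observing `k` or more successes in `n` draws
#' without replacement from a population of `N` with `K` successes.
#'
#' @param N population size.
#' @param K successes in the population (`0 <= K <= N`).
#' @param n number of draws (`0 <= n <= N`).
#' @param k observed successes (`0 <= k <= min(n, K)`).
#' @return probability in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 4)  # 5 / 210
hypergeom_upper_tail <- function(N, K, n, k) {
  a <- check_hyper_args(N, K, n, k)
  if (a$k == 0L) return(1.0)
  p <- hyper_pmf_support(a$N, a$K, a$n)
  keep <- as.integer(names(p)) >= a$k
  # smallest terms first for accurate accumulation
  min(sum(rev(p[keep])), 1.0)
}

hypergeom_result <- function(N, K, n, k, extra = list()) {
  structure(c(list(population_N = N, successes_K = K, draws_n = n,
                   observed_k = k,
                   p_upper = hypergeom_upper_tail(N, K, n, k)), extra),
            class = "hypergeom_result")
}

#' @export
print.hypergeom_result <- function(x, ...) {
  cat(sprintf(
    "hypergeometric upper tail: N=%d K=%d n=%d k=%d  P[X >= k] = %.4g\n",
    x$population_N, x$successes_K, x$draws_n, x$observed_k, x$p_upper))
  invisible(x)
}

#' Enrichment of a joint pattern within a bait set
#'
#' Tests whether the focal joint pattern (default the reversal pattern
#' `up` at stage 1, `down` at stage 2) is over-represented among the baits
#' relative to a universe of genes. Population `N` = universe genes with
#' calls at both stages, `K` = universe genes with the focal pattern,
#' `n` = baits, `k` = baits with the focal pattern.
#'
#' @param bait_genes character vector or `bait_set`, subset of the universe.
#' @param stage1_calls,stage2_calls `contrast_calls` for the two stages.
#' @param focal length-2 character vector (stage1 direction, stage2
#'   direction); default `c("up", "down")`.
#' @param universe universe genes; default: genes present in both call
#'   lists.
#' @return a `hypergeom_result` (upper-tail p in `$p_upper`).
#' @export
pattern_enrichment <- function(bait_genes, stage1_calls, stage2_calls,
                               focal = c("up", "down"), universe = NULL) {
  baits <- as_baits(bait_genes)$genes
  if (length(focal) != 2L || !all(focal %in% DIRECTIONS))
    abort("focal must be two directions (stage1, stage2)")
  if (is.null(universe))
    universe <- intersect(stage1_calls$gene, stage2_calls$gene)
  universe <- unique(norm_symbols(universe))
  if (length(universe) == 0) abort("empty universe")
  outside <- setdiff(baits, universe)
  if (length(outside) > 0)
    abort("bait gene(s) outside the universe: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  d1 <- stage1_calls$direction[match(universe, stage1_calls$gene)]
  d2 <- stage2_calls$direction[match(universe, stage2_calls$gene)]
  d1[is.na(d1)] <- "not_expressed"
  d2[is.na(d2)] <- "not_expressed"
  is_focal <- setNames(d1 == focal[1] & d2 == focal[2], universe)
  hypergeom_result(N = length(universe), K = sum(is_focal),
                   n = length(baits), k = sum(is_focal[baits]),
                   extra = list(focal = focal))
}

#' Construct a gene set
#'
#' @param name set label.
#' @param genes non-empty character vector of symbols.
#' @param source free-text provenance note.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes, source = "") {
  genes <- unique(norm_symbols(genes))
  if (length(genes) == 0) abort("gene set '%s' is empty", name)
  structure(list(name = as.character(name), genes = sort(genes),
                 source = as.character(source)), class = "gene_set")
}

#' Overlap of a network gene set with an external gene set
#'
#' Reports the overlap count and fraction, plus the hypergeometric
#' upper-tail p-value with `N` = universe size, `K` = external genes in the
#' universe, `n` = network genes, `k` = overlap.
#'
#' @param network_genes character vector, subset of the universe.
#' @param external a `gene_set` or character vector (e.g. cancer-related
#'   genes).
#' @param universe character vector of background genes.
#' @return list with `overlap_count`, `overlap_fraction`, `test`
#'   (a `hypergeom_result`); class `overlap_test`.
#' @export
geneset_overlap_test <- function(network_genes, external, universe) {
  network_genes <- unique(norm_symbols(network_genes))
  ext <- if (inherits(external, "gene_set")) external$genes
         else unique(norm_symbols(external))
  universe <- unique(norm_symbols(universe))
  if (length(universe) == 0) abort("empty universe")
  outside <- setdiff(network_genes, universe)
  if (length(outside) > 0)
    abort("network gene(s) outside the universe: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  K_set <- intersect(ext, universe)
  if (length(K_set) == 0)
    abort("external set does not intersect the universe")
  k <- length(intersect(network_genes, K_set))
  res <- hypergeom_result(N = length(universe), K = length(K_set),
                          n = length(network_genes), k = k)
  structure(list(overlap_count = k,
                 overlap_fraction = k / length(network_genes),
                 test = res),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap: %d / %d (%.1f%%)\n", x$overlap_count,
              x$test$draws_n, 100 * x$overlap_fraction))
  print(x$test)
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name<TAB>source<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file: %s", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("GMT line with fewer than 3 fields")
    gene_set(f[1], f[-(1:2)], source = f[2])
  })
  setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets a `gene_set` or list of them.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$source, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
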