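#' @keywords internal
"_PACKAGE"

#' @importFrom stats rlnorm rpois runif setNames
#' @importFrom utils combn glob2rx read.delim write.table head
NULL

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Normalize gene symbols
#'
#' Gene symbols are compared case-insensitively throughout; all symbols are
#' uppercased on entry. Empty symbols or symbols containing whitespace are
#' rejected.
#'
#' @param x character vector of gene symbols.
#' @param what label used in error messages.
#' @return uppercased character vector.
#' @export
norm_symbols <- function(x, what = "gene symbol") {
  x <- as.character(x)
  if (any(is.na(x) | !nzchar(x)))
    abort("empty %s at position %d", what, which(is.na(x) | !nzchar(x))[1])
  if (any(grepl("\\s", x)))
    abort("%s contains whitespace: '%s'", what, x[grepl("\\s", x)][1])
  toupper(x)
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    abort("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    abort("'%s' must be a single number in [0, 1]", name)
  as.numeric(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, ~0 for independent ones. Used to score planted-module
#' recovery.
#'
#' @param a,b vectors of cluster labels, same length.
#' @return numeric scalar.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) abort("need at least 2 items")
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# deterministic numeric formatting for file writers (byte-identical bundles)
fmt_num <- function(x, digits = 8) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[is.na(x)] <- "NA"
  out
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return uppercased character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) abort("gene list is empty: %s", path)
  unique(norm_symbols(x))
}

#' Write a plain-text gene list
#'
#' @param genes character vector of symbols.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(norm_symbols(genes), path)
  invisible(path)
}
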