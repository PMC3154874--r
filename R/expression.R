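# Expression tables, detection calls and fold-change contrasts.
#
# The input shape follows Illumina BeadStudio-style exports: per gene, one
# background-subtracted signal and one detection p-value per sample. A gene
# is "expressed" when its detection p-value is at or below a threshold
# (default 0.01); a gene is differentially expressed between the control and
# the NSN (developmentally incompetent) condition when the ratio of mean
# signals reaches a fold-change threshold (default 1.5).

STAGES <- c("stage1", "stage2")
CONDITIONS <- c("ctrl", "nsn")
DIRECTIONS <- c("up", "down", "unchanged", "not_expressed")

norm_stage <- function(stage) {
  s <- tolower(as.character(stage))
  s[s %in% c("1", "oocyte", "mii")] <- "stage1"
  s[s %in% c("2", "embryo", "2cell", "2-cell")] <- "stage2"
  if (length(s) != 1L || !s %in% STAGES)
    abort("stage must be one of: %s", paste(STAGES, collapse = ", "))
  s
}

norm_condition <- function(condition) {
  cnd <- tolower(as.character(condition))
  cnd[cnd %in% c("competent_ctrl", "control")] <- "ctrl"
  cnd[cnd %in% c("incompetent_nsn")] <- "nsn"
  if (length(cnd) != 1L || !cnd %in% CONDITIONS)
    abort("condition must be one of: %s", paste(CONDITIONS, collapse = ", "))
  cnd
}

#' Construct an expression table
#'
#' @param genes character vector of gene symbols (uppercased, unique).
#' @param signal numeric matrix, genes x samples, finite signals
#'   (background-subtracted values may be negative; they are floored later
#'   when ratios are computed).
#' @param detp numeric matrix, genes x samples, detection p-values in [0, 1].
#' @param sample_ids character vector of sample labels (columns).
#' @param stage `"stage1"` (MII oocyte) or `"stage2"` (2-cell embryo).
#' @param condition `"ctrl"` (competent control) or `"nsn"` (incompetent NSN).
#' @return an object of class `expression_table`.
#' @export
expression_table <- function(genes, signal, detp, sample_ids, stage, condition) {
  genes <- norm_symbols(genes)
  if (anyDuplicated(genes))
    abort("duplicate gene symbol after case normalization: '%s'",
          genes[duplicated(genes)][1])
  signal <- as.matrix(signal)
  detp <- as.matrix(detp)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) < 1L) abort("at least one sample is required")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  if (nrow(signal) != length(genes) || nrow(detp) != length(genes) ||
      ncol(signal) != length(sample_ids) || ncol(detp) != length(sample_ids))
    abort("signal/detp dimensions do not match genes x samples")
  if (!all(is.finite(signal))) abort("non-finite signal values")
  bad <- which(!is.finite(detp) | detp < 0 | detp > 1)
  if (length(bad) > 0) {
    row <- (bad[1] - 1L) %% length(genes) + 1L
    abort("detection p-value outside [0, 1] for gene '%s' (row %d)",
          genes[row], row)
  }
  dimnames(signal) <- dimnames(detp) <- list(genes, sample_ids)
  structure(
    list(genes = genes, signal = signal, detp = detp,
         sample_ids = sample_ids,
         stage = norm_stage(stage), condition = norm_condition(condition)),
    class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples [%s / %s]\n",
              length(x$genes), length(x$sample_ids), x$stage, x$condition))
  invisible(x)
}

#' Read an expression table from TSV
#'
#' Expected header: `gene`, then per sample a `<sample>.signal` and a
#' `<sample>.detp` column. UTF-8; lines starting with `#` are comments.
#'
#' @param path file path.
#' @inheritParams expression_table
#' @return an `expression_table`.
#' @export
load_expression_table <- function(path, stage, condition) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 1 || names(df)[1] != "gene")
    abort("format error: first column must be named 'gene' (%s)", path)
  cols <- names(df)[-1]
  sig_cols <- grep("\\.signal$", cols, value = TRUE)
  detp_cols <- grep("\\.detp$", cols, value = TRUE)
  other <- setdiff(cols, c(sig_cols, detp_cols))
  if (length(other) > 0)
    abort("format error: unrecognized column '%s'", other[1])
  samples <- sub("\\.signal$", "", sig_cols)
  for (s in samples)
    if (!paste0(s, ".detp") %in% detp_cols)
      abort("format error: missing column '%s.detp'", s)
  for (s in sub("\\.detp$", "", detp_cols))
    if (!paste0(s, ".signal") %in% sig_cols)
      abort("format error: missing column '%s.signal'", s)
  if (length(samples) == 0) abort("format error: no sample columns in %s", path)
  signal <- as.matrix(df[, paste0(samples, ".signal"), drop = FALSE])
  detp <- as.matrix(df[, paste0(samples, ".detp"), drop = FALSE])
  if (!is.numeric(signal) || !is.numeric(detp))
    abort("format error: non-numeric signal/detp values in %s", path)
  bad <- which(rowSums(detp < 0 | detp > 1 | !is.finite(detp)) > 0)
  if (length(bad) > 0)
    abort("validation error: detection p outside [0, 1] at data row %d of %s",
          bad[1], path)
  expression_table(df$gene, signal, detp, samples, stage, condition)
}

#' Write an expression table to TSV
#'
#' Inverse of [load_expression_table()]; numeric output is formatted
#' deterministically so seeded bundles are byte-identical.
#'
#' @param table an `expression_table`.
#' @param path output path.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  out <- data.frame(gene = table$genes, stringsAsFactors = FALSE)
  for (s in table$sample_ids) {
    out[[paste0(s, ".signal")]] <- fmt_num(table$signal[, s])
    out[[paste0(s, ".detp")]] <- fmt_num(table$detp[, s])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Thresholds for expression and differential calls
#'
#' @param fc_threshold fold-change threshold (> 1); a ratio at or above it is
#'   called regulated. Default 1.5.
#' @param detp_threshold detection p-value threshold; a gene with detection
#'   p at or below it is called expressed. Default 0.01.
#' @param signal_floor positive floor applied to mean signals before ratio
#'   computation, guarding against non-positive background-subtracted values.
#'   Default 1.
#' @return an object of class `contrast_thresholds`.
#' @export
contrast_thresholds <- function(fc_threshold = 1.5, detp_threshold = 0.01,
                                signal_floor = 1.0) {
  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    abort("fc_threshold must be > 1")
  if (!is.numeric(detp_threshold) || detp_threshold <= 0 || detp_threshold >= 1)
    abort("detp_threshold must be in (0, 1)")
  if (!is.numeric(signal_floor) || signal_floor <= 0)
    abort("signal_floor must be > 0")
  structure(list(fc_threshold = as.numeric(fc_threshold),
                 detp_threshold = as.numeric(detp_threshold),
                 signal_floor = as.numeric(signal_floor)),
            class = "contrast_thresholds")
}

#' Call expressed genes from detection p-values
#'
#' A gene is expressed if its per-gene summary detection p-value — the
#' minimum across the condition's samples, i.e. detected in any replicate —
#' is at or below the threshold (inclusive).
#'
#' @param table an `expression_table`.
#' @param thresholds a `contrast_thresholds` object.
#' @return named logical vector over the table's genes.
#' @export
call_expressed <- function(table, thresholds = contrast_thresholds()) {
  stopifnot(inherits(table, "expression_table"))
  if (length(table$genes) == 0) abort("empty expression table")
  p <- apply(table$detp, 1, min)
  setNames(p <= thresholds$detp_threshold, table$genes)
}

#' Fold change between two mean signals
#'
#' Means are floored at `floor`, then the ratio of the larger to the smaller
#' is returned (always >= 1). Direction is NSN relative to control: `up`
#' means higher in NSN.
#'
#' @param mean_ctrl,mean_nsn mean signals (vectorized).
#' @param floor positive floor applied before division.
#' @return data.frame with columns `ratio` and `direction`
#'   (`up`/`down`/`unchanged`).
#' @export
#' @examples
#' fold_change(2, 3)   # ratio 1.5, up
fold_change <- function(mean_ctrl, mean_nsn, floor = 1.0) {
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    abort("floor must be a single positive number")
  if (!all(is.finite(mean_ctrl)) || !all(is.finite(mean_nsn)))
    abort("non-finite mean signal")
  a <- pmax(mean_ctrl, floor)
  b <- pmax(mean_nsn, floor)
  ratio <- pmax(a, b) / pmin(a, b)
  direction <- ifelse(b > a, "up", ifelse(b < a, "down", "unchanged"))
  data.frame(ratio = ratio, direction = direction, stringsAsFactors = FALSE)
}

#' Differential contrast between control and NSN tables
#'
#' Over the union of genes in the two tables: a gene expressed in neither
#' condition is `not_expressed`; a gene expressed in at least one condition
#' with mean-signal ratio at or above the fold-change threshold is `up` or
#' `down` (NSN relative to control); otherwise `unchanged`. A gene absent
#' from one table counts as undetected there (detection p = 1, mean 0).
#'
#' @param ctrl,nsn `expression_table`s for the same stage.
#' @param thresholds a `contrast_thresholds` object.
#' @return a `contrast_calls` data.frame (gene, direction, fold_change,
#'   expressed_ctrl, expressed_nsn), sorted by gene; stage and thresholds
#'   kept as attributes.
#' @export
differential_contrast <- function(ctrl, nsn,
                                  thresholds = contrast_thresholds()) {
  stopifnot(inherits(ctrl, "expression_table"),
            inherits(nsn, "expression_table"))
  if (ctrl$stage != nsn$stage)
    abort("stage mismatch: '%s' vs '%s'", ctrl$stage, nsn$stage)
  genes <- sort(union(ctrl$genes, nsn$genes))

  summarize <- function(tab) {
    mean_sig <- setNames(rep(0, length(genes)), genes)
    expressed <- setNames(rep(FALSE, length(genes)), genes)
    mean_sig[tab$genes] <- rowMeans(tab$signal)
    expressed[tab$genes] <- call_expressed(tab, thresholds)
    list(mean = mean_sig, expressed = expressed)
  }
  sc <- summarize(ctrl)
  sn <- summarize(nsn)

  fc <- fold_change(sc$mean, sn$mean, thresholds$signal_floor)
  any_expr <- sc$expressed | sn$expressed
  direction <- ifelse(!any_expr, "not_expressed",
               ifelse(fc$ratio >= thresholds$fc_threshold, fc$direction,
                      "unchanged"))
  out <- data.frame(
    gene = genes,
    direction = direction,
    fold_change = ifelse(any_expr, fc$ratio, NA_real_),
    expressed_ctrl = unname(sc$expressed),
    expressed_nsn = unname(sn$expressed),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "stage") <- ctrl$stage
  attr(out, "thresholds") <- thresholds
  class(out) <- c("contrast_calls", "data.frame")
  out
}

expressed_in_label <- function(calls) {
  paste0(ifelse(calls$expressed_ctrl, "ctrl", ""),
         ifelse(calls$expressed_ctrl & calls$expressed_nsn, ",", ""),
         ifelse(calls$expressed_nsn, "NSN", ""))
}

#' Write contrast calls to TSV
#'
#' Columns: `gene`, `direction`, `fold_change`, `expressed_in` (comma-joined
#' subset of `ctrl`,`NSN`).
#'
#' @param calls a `contrast_calls` data.frame.
#' @param path output path.
#' @export
write_contrast_calls <- function(calls, path) {
  stopifnot(inherits(calls, "contrast_calls"))
  out <- data.frame(gene = calls$gene, direction = calls$direction,
                    fold_change = fmt_num(calls$fold_change),
                    expressed_in = expressed_in_label(calls),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s", attr(calls, "stage")), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read contrast calls written by [write_contrast_calls()]
#'
#' @param path file path.
#' @param stage optional stage label; defaults to the `# stage=` header
#'   comment if present.
#' @return a `contrast_calls` data.frame.
#' @export
read_contrast_calls <- function(path, stage = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (is.null(stage) && grepl("^# stage=", first))
    stage <- sub("^# stage=", "", first)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "direction", "fold_change", "expressed_in")
  if (!all(need %in% names(df)))
    abort("format error: missing column '%s'", setdiff(need, names(df))[1])
  if (!all(df$direction %in% DIRECTIONS))
    abort("unknown direction '%s'",
          setdiff(df$direction, DIRECTIONS)[1])
  out <- data.frame(
    gene = norm_symbols(df$gene),
    direction = df$direction,
    fold_change = suppressWarnings(as.numeric(df$fold_change)),
    expressed_ctrl = grepl("ctrl", df$expressed_in),
    expressed_nsn = grepl("NSN", df$expressed_in),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(stage)) attr(out, "stage") <- norm_stage(stage)
  class(out) <- c("contrast_calls", "data.frame")
  out
}
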