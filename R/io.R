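# Readers and writers for the external formats the pipeline touches.
# BED dialect: 0-based half-open, optional strand in column 6, "." for
# unstranded. All outputs are UTF-8, tab-separated, LF-terminated.

read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  skipped <- sum(!keep & nzchar(lines))
  if (skipped > 0)
    message("skipped ", skipped, " comment/track line(s) in ", basename(path))
  list(lines = lines[keep], line_no = which(keep))
}

#' Read a BED file of peaks or mapped tags
#'
#' Parses BED3/BED6 strictly: every data line needs at least three
#' tab-separated fields, integer coordinates with `0 <= start < end`, and a
#' strand symbol in `{+, -, .}` when column 6 is present. Malformed lines
#' abort with the offending line number; nothing is silently dropped
#' (comment/`track`/`browser` lines are skipped with a diagnostic).
#'
#' @param path BED file path.
#' @param expected_kind `"peaks"` returns an [interval_set()]; `"tags"`
#'   returns a [tag_set()] (one record per mapped read).
#' @param sample_label label for the returned set; defaults to the file name.
#' @param mark,condition,library_size tag-set metadata (tags only);
#'   `library_size` defaults to the number of tags.
#' @return An `interval_set` or `tag_set`, sorted canonically.
#' @export
read_bed <- function(path, expected_kind = c("peaks", "tags"),
                     sample_label = NULL, mark = "5hmC", condition = "WT",
                     library_size = NULL) {
  expected_kind <- match.arg(expected_kind)
  if (is.null(sample_label)) sample_label <- basename(path)
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0L) {
    return(if (expected_kind == "peaks") interval_set(sample_label = sample_label)
           else tag_set(sample_label = sample_label, mark = mark,
                        condition = condition, library_size = library_size))
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1L]
    stop("BED parse error at line ", tl$line_no[i],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0 | start >= end)
  if (length(bad))
    stop("BED parse error at line ", tl$line_no[bad[1L]],
         ": invalid coordinates (need integers with 0 <= start < end)",
         call. = FALSE)
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else ".", ""), ".")
  score <- ifelse(nf >= 5L, suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", ""))), 0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6L, vapply(fields, function(f)
    if (length(f) >= 6L) f[[6L]] else ".", ""), ".")
  bads <- which(!strand %in% STRAND_SYMBOLS)
  if (length(bads))
    stop("BED parse error at line ", tl$line_no[bads[1L]],
         ": unknown strand symbol '", strand[bads[1L]], "'", call. = FALSE)
  if (expected_kind == "peaks") {
    interval_set(chrom, start, end, strand = strand, name = name,
                 score = score, sample_label = sample_label)
  } else {
    tag_set(chrom, start, end, strand = strand, sample_label = sample_label,
            mark = mark, condition = condition, library_size = library_size)
  }
}

#' Write intervals or tags as BED6
#'
#' Canonical output: sorted by (chrom, start, end), six tab-separated columns,
#' unstranded records written with strand `"."`, LF line endings. Writing then
#' re-reading is the identity on canonical records.
#'
#' @param records an [interval_set()] or [tag_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  validate_intervals(records)
  x <- as.data.frame(records)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  if (!"name" %in% names(x)) x$name <- "."
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), x$name,
                   format(x$score, trim = TRUE, scientific = FALSE),
                   x$strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read gene models from TSV or BED6
#'
#' Accepts either a TSV with header columns `gene_id`, `chrom`, `strand`,
#' `tx_start`, `tx_end`, or a BED6 file whose name column carries the gene
#' id. Both encodings of the same genes parse to identical tables. Duplicate
#' gene ids and missing strands are validation errors.
#'
#' @param path file path.
#' @return A [gene_models()] table keyed by `gene_id`.
#' @export
read_gene_models <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0L) stop("no gene records in ", path, call. = FALSE)
  header <- strsplit(tl$lines[1L], "\t", fixed = TRUE)[[1L]]
  if ("gene_id" %in% header) {
    x <- utils::read.table(text = tl$lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
    need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("gene model TSV missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    gene_models(x$gene_id, x$chrom, x$strand, x$tx_start, x$tx_end)
  } else {
    bed <- read_bed(path, "peaks")
    if (any(bed$strand == "."))
      stop("gene models in BED form require a strand in column 6",
           call. = FALSE)
    gene_models(bed$name, bed$chrom, bed$strand, bed$start, bed$end)
  }
}

#' Read a differential-expression table
#'
#' TSV with header `gene_id`, `expr_a`, `expr_b` and optionally `log2fc`,
#' `p_value`, `q_value`. A missing `log2fc` is recomputed as
#' `log2((expr_b + c) / (expr_a + c))` with pseudocount `c = 1`; a missing
#' `q_value` is filled with the sentinel 1.0. p- and q-values outside
#' `[0, 1]` are validation errors.
#'
#' @param path file path.
#' @param pseudocount pseudocount for recomputing `log2fc` when absent.
#' @return A data frame of class `de_table` with columns `gene_id`, `expr_a`,
#'   `expr_b`, `log2fc`, `p_value`, `q_value`.
#' @export
read_de_table <- function(path, pseudocount = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "expr_a", "expr_b", "p_value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"log2fc" %in% names(x))
    x$log2fc <- log2((x$expr_b + pseudocount) / (x$expr_a + pseudocount))
  if (!"q_value" %in% names(x)) x$q_value <- 1.0
  de_table(x$gene_id, x$expr_a, x$expr_b, x$log2fc, x$p_value, x$q_value)
}

de_table <- function(gene_id, expr_a, expr_b, log2fc, p_value, q_value) {
  x <- data.frame(gene_id = as.character(gene_id),
                  expr_a = as.numeric(expr_a), expr_b = as.numeric(expr_b),
                  log2fc = as.numeric(log2fc),
                  p_value = as.numeric(p_value),
                  q_value = as.numeric(q_value), stringsAsFactors = FALSE)
  if (any(is.na(x$p_value)) || any(x$p_value < 0 | x$p_value > 1))
    stop("p_value outside [0, 1]", call. = FALSE)
  if (any(is.na(x$q_value)) || any(x$q_value < 0 | x$q_value > 1))
    stop("q_value outside [0, 1]", call. = FALSE)
  if (any(x$expr_a < 0 | x$expr_b < 0))
    stop("expression levels must be >= 0", call. = FALSE)
  class(x) <- c("de_table", "data.frame")
  x
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns name, length (no header).
#' @return A [genome_table()].
#' @export
read_genome_table <- function(path) {
  tl <- read_tab_lines(path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("genome table needs two tab-separated columns (name, length)",
         call. = FALSE)
  genome_table(vapply(fields, `[[`, "", 1L),
               as.numeric(vapply(fields, `[[`, "", 2L)))
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  tl <- read_tab_lines(path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT parse error: each line needs name, description and >= 1 member",
         call. = FALSE)
  stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)])),
    vapply(fields, `[[`, "", 1L)
  )
}

#' Write gene models as TSV
#' @param genes a [gene_models()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(as.data.frame(genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
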