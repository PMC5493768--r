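# Internal constructors and validators for the package's in-memory types.
#
# All coordinates are 0-based half-open (BED native): an interval [start, end)
# covers bases start .. end-1. Strand is "+", "-" or "." (unstranded).

STRAND_SYMBOLS <- c("+", "-", ".")

#' Construct a set of genomic intervals
#'
#' The atom of all peak and region arithmetic: a data frame of located spans
#' on named sequences, 0-based half-open, optionally stranded, carried with a
#' sample label. The sorted form by (chrom, start, end) is canonical.
#'
#' @param chrom character vector of sequence names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end` (half-open; empty
#'   intervals are rejected).
#' @param strand strand per interval: `"+"`, `"-"` or `"."`; recycled.
#' @param name,score optional labels / numeric scores; recycled.
#' @param sample_label label describing the sample the intervals belong to.
#' @return A data frame of class `interval_set` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand` and attribute `sample_label`, sorted by
#'   (chrom, start, end).
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), strand = ".", name = ".",
                         score = 0, sample_label = "unnamed") {
  n <- length(chrom)
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "sample_label") <- sample_label
  class(x) <- c("interval_set", "data.frame")
  x
}

validate_intervals <- function(x, where = "interval set") {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop(where, ": chrom must be non-empty", call. = FALSE)
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(where, ": invalid coordinates (need 0 <= start < end) at record(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bads <- which(!(x$strand %in% STRAND_SYMBOLS))
  if (length(bads))
    stop(where, ": unknown strand symbol at record(s) ",
         paste(utils::head(bads, 5L), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Construct a set of mapped sequencing tags
#'
#' An [interval_set()] of mapped-read records (one interval per read) plus the
#' sample's library size, the denominator of every reads-per-million value.
#' The library size may exceed the number of tags when the tag file is a
#' filtered subset of the mapped reads.
#'
#' @inheritParams interval_set
#' @param mark assayed mark: `"5hmC"`, `"TF"` or `"input"`.
#' @param condition `"WT"` or `"KO"`.
#' @param library_size total mapped reads; defaults to the tag count.
#' @return A data frame of class `c("tag_set", "interval_set")` with
#'   attributes `sample_label`, `mark`, `condition`, `library_size`.
#' @export
tag_set <- function(chrom = character(), start = integer(), end = integer(),
                    strand = ".", sample_label = "unnamed",
                    mark = c("5hmC", "TF", "input"),
                    condition = c("WT", "KO"), library_size = NULL) {
  mark <- match.arg(mark)
  condition <- match.arg(condition)
  x <- interval_set(chrom, start, end, strand = strand,
                    sample_label = sample_label)
  if (is.null(library_size)) library_size <- nrow(x)
  library_size <- as.numeric(library_size)
  if (length(library_size) != 1L || is.na(library_size) || library_size < 1)
    stop("library_size must be a positive number", call. = FALSE)
  if (library_size < nrow(x))
    stop("library_size (", library_size, ") is smaller than the tag count (",
         nrow(x), ")", call. = FALSE)
  attr(x, "mark") <- mark
  attr(x, "condition") <- condition
  attr(x, "library_size") <- library_size
  class(x) <- c("tag_set", class(x))
  x
}

#' Library size of a tag set
#' @param tags a [tag_set()].
#' @return The total mapped reads used for RPM normalization.
#' @export
library_size <- function(tags) {
  ls <- attr(tags, "library_size")
  if (is.null(ls)) stop("not a tag_set: no library_size attribute",
                        call. = FALSE)
  ls
}

#' Construct a gene-model table
#'
#' Transcription units used to anchor promoters, gene bodies and flanks:
#' gene id, chromosome, strand and the transcribed span
#' `[tx_start, tx_end)`. The TSS of a `+` gene is `tx_start`; the TSS of a
#' `-` gene is `tx_end - 1` (the last base, first transcribed).
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param tx_start,tx_end transcribed span, 0-based half-open,
#'   `tx_end - tx_start >= 1`.
#' @return A data frame of class `gene_models`, ordered by `gene_id`.
#' @export
gene_models <- function(gene_id, chrom, strand, tx_start, tx_end) {
  x <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    tx_start = as.numeric(tx_start),
    tx_end = as.numeric(tx_end),
    stringsAsFactors = FALSE
  )
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup))
    stop("duplicate gene_id: ", paste(dup, collapse = ", "), call. = FALSE)
  if (any(!x$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-' (missing strands are not allowed)",
         call. = FALSE)
  bad <- which(is.na(x$tx_start) | is.na(x$tx_end) | x$tx_start < 0 |
                 x$tx_end - x$tx_start < 1)
  if (length(bad))
    stop("invalid transcript span for gene(s): ",
         paste(utils::head(x$gene_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  x <- x[order(x$gene_id), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("gene_models", "data.frame")
  x
}

#' Construct a genome table (chromosome lengths)
#'
#' @param chrom chromosome names.
#' @param length chromosome lengths in bp (>= 1).
#' @return A named numeric vector of class `genome_table`.
#' @export
genome_table <- function(chrom, length) {
  len <- as.numeric(length)
  if (any(is.na(len)) || any(len < 1))
    stop("chromosome lengths must be >= 1", call. = FALSE)
  if (anyDuplicated(chrom))
    stop("duplicate chromosome names in genome table", call. = FALSE)
  x <- stats::setNames(len, as.character(chrom))
  class(x) <- "genome_table"
  x
}

#' Specify an anchored gene region
#'
#' Describes a region relative to a gene model: a promoter window around the
#' TSS, the gene body (TSS offset to TES), a flank, or the whole transcribed
#' unit. Upstream/downstream are in transcript orientation (5' to 3').
#'
#' @param kind one of `"promoter"`, `"gene_body"`, `"upstream_flank"`,
#'   `"downstream_flank"`, `"whole_gene"`.
#' @param upstream_bp,downstream_bp extents in bp (>= 0). For `promoter`,
#'   bases upstream/downstream of the TSS (their sum must be >= 1). For
#'   `gene_body`, `downstream_bp` is the offset of the body start downstream
#'   of the TSS. For flanks, the flank width.
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(kind = c("promoter", "gene_body", "upstream_flank",
                                 "downstream_flank", "whole_gene"),
                        upstream_bp = 0, downstream_bp = 0) {
  kind <- match.arg(kind)
  if (upstream_bp < 0 || downstream_bp < 0)
    stop("region extents must be >= 0", call. = FALSE)
  if (kind == "promoter" && upstream_bp + downstream_bp < 1)
    stop("promoter requires upstream_bp + downstream_bp >= 1", call. = FALSE)
  structure(list(kind = kind, upstream_bp = upstream_bp,
                 downstream_bp = downstream_bp),
            class = "region_spec")
}

# Give two GRanges a common seqlevels universe so pairwise operations do
# not warn about disjoint sequence sets.
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

# GRanges bridge: 0-based half-open data frame -> 1-based closed GRanges.
as_granges <- function(x, use_strand = FALSE) {
  strand <- if (use_strand && "strand" %in% names(x)) x$strand
            else rep("*", nrow(x))
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = strand
  )
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<%s> %d interval(s), sample '%s'\n",
              class(x)[1L], nrow(x), attr(x, "sample_label")))
  if (inherits(x, "tag_set"))
    cat(sprintf("  mark=%s condition=%s library_size=%s\n",
                attr(x, "mark"), attr(x, "condition"),
                format(library_size(x), big.mark = ",")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}
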