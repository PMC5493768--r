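# Interval algebra over 0-based half-open coordinates: merging, windowed
# proximity, whole-interval subtraction, overlap and coverage fractions, and
# strand-aware anchored gene regions. Backed by IRanges/GenomicRanges; the
# conventions that matter here are pinned down explicitly:
#   - touching intervals (end == start) merge;
#   - gap distance is edge-to-edge between closest boundaries, 0 for
#     overlapping or touching intervals; "within W bp" means gap <= W
#     inclusive.

#' Merge one or more interval sets into a non-overlapping union
#'
#' Returns the sorted union; overlapping and touching intervals (half-open
#' `end == start`) are joined. Idempotent.
#'
#' @param ... one or more [interval_set()] objects (or plain data frames with
#'   `chrom`, `start`, `end`).
#' @param sample_label label for the merged set.
#' @return An [interval_set()] of pairwise non-overlapping intervals.
#' @export
merge_intervals <- function(..., sample_label = "merged") {
  sets <- list(...)
  dfs <- lapply(sets, function(s) as.data.frame(s)[c("chrom", "start", "end")])
  x <- do.call(rbind, dfs)
  if (is.null(x) || nrow(x) == 0L)
    return(interval_set(sample_label = sample_label))
  merged <- granges_to_df(GenomicRanges::reduce(as_granges(x)))
  interval_set(merged$chrom, merged$start, merged$end,
               sample_label = sample_label)
}

# Edge-to-edge gap (bp) from each query to its nearest subject on the same
# chromosome; NA when the chromosome has no subject. 0 for overlap/touch.
nearest_gap <- function(query, subject) {
  qg <- as_granges(as.data.frame(query))
  sg <- as_granges(as.data.frame(subject))
  h <- harmonize_seqlevels(qg, sg)
  qg <- h$a; sg <- h$b
  d <- rep(NA_real_, length(qg))
  if (length(sg)) {
    hits <- GenomicRanges::distanceToNearest(qg, sg, ignore.strand = TRUE)
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  d
}

#' Count query intervals within a window of any subject interval
#'
#' A query is a hit iff some subject interval on the same chromosome overlaps
#' it or lies at an edge-to-edge gap of at most `window` bp (inclusive).
#' `window = 0` counts exactly the overlapping-or-touching queries.
#'
#' @param query,subject interval sets.
#' @param window maximum gap in bp (>= 0).
#' @return A list with `k` (hits), `n` (queries) and `hits` (logical per
#'   query, in the canonical sorted order of `query`).
#' @export
count_within_window <- function(query, subject, window = 500) {
  if (window < 0) stop("window must be >= 0", call. = FALSE)
  gap <- nearest_gap(query, subject)
  hits <- !is.na(gap) & gap <= window
  list(k = sum(hits), n = nrow(query), hits = hits)
}

#' Anchored region of a gene (promoter, body, flank, whole gene)
#'
#' Strand-aware region construction. The TSS is `tx_start` on `+` genes and
#' `tx_end - 1` on `-` genes; "upstream" means 5' of the TSS in transcript
#' orientation. A promoter spanning `u` bp upstream and `d` bp downstream of
#' the TSS has width `u + d` (the TSS base belongs to the downstream part).
#' The gene body runs from `downstream_bp` past the TSS to the TES.
#' Coordinates are clipped at 0 and at the chromosome length when `genome`
#' is supplied.
#'
#' @param gene one row of a [gene_models()] table (or a list with the same
#'   fields).
#' @param spec a [region_spec()].
#' @param genome optional [genome_table()] used for clipping.
#' @return A one-row data frame with `chrom`, `start`, `end`, `strand`.
#' @export
anchored_region <- function(gene, spec, genome = NULL) {
  g <- gene_models(gene$gene_id, gene$chrom, gene$strand, gene$tx_start,
                   gene$tx_end)
  r <- anchored_regions(g, spec, genome, drop_degenerate = FALSE)
  if (is.na(r$start[1L]))
    stop("degenerate region: gene ", g$gene_id[1L], " is too short for ",
         spec$kind, " with a ", spec$downstream_bp, " bp TSS offset",
         call. = FALSE)
  r[1L, c("chrom", "start", "end", "strand")]
}

#' Anchored regions for a whole gene table (vectorized)
#'
#' As [anchored_region()], for every gene at once. Genes whose region would
#' be empty (gene bodies shorter than the TSS offset, or regions clipped
#' away entirely) get `NA` coordinates and are either dropped with a
#' diagnostic (`drop_degenerate = TRUE`) or kept as `NA` rows.
#'
#' @param genes a [gene_models()] table.
#' @param spec a [region_spec()].
#' @param genome optional [genome_table()] for clipping.
#' @param drop_degenerate drop `NA`-region genes with a message?
#' @return A data frame with one row per (retained) gene: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
anchored_regions <- function(genes, spec, genome = NULL,
                             drop_degenerate = TRUE) {
  stopifnot(inherits(spec, "region_spec"))
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$tx_start, genes$tx_end - 1)
  up <- spec$upstream_bp
  down <- spec$downstream_bp
  start <- end <- rep(NA_real_, nrow(genes))
  if (spec$kind == "promoter") {
    start <- ifelse(plus, tss - up, tss - down + 1)
    end <- ifelse(plus, tss + down, tss + up + 1)
  } else if (spec$kind == "whole_gene") {
    start <- genes$tx_start
    end <- genes$tx_end
  } else if (spec$kind == "gene_body") {
    len <- genes$tx_end - genes$tx_start
    ok <- len > down
    start <- ifelse(plus, genes$tx_start + down, genes$tx_start)
    end <- ifelse(plus, genes$tx_end, genes$tx_end - down)
    start[!ok] <- NA_real_
    end[!ok] <- NA_real_
  } else if (spec$kind == "upstream_flank") {
    start <- ifelse(plus, genes$tx_start - up, genes$tx_end)
    end <- ifelse(plus, genes$tx_start, genes$tx_end + up)
  } else if (spec$kind == "downstream_flank") {
    start <- ifelse(plus, genes$tx_end, genes$tx_start - down)
    end <- ifelse(plus, genes$tx_end + down, genes$tx_start)
  }
  start <- pmax(start, 0)
  if (!is.null(genome)) {
    miss <- setdiff(unique(genes$chrom), names(genome))
    if (length(miss))
      stop("chromosome(s) missing from genome table: ",
           paste(miss, collapse = ", "), call. = FALSE)
    end <- pmin(end, unclass(genome)[genes$chrom])
  }
  empty <- !is.na(start) & !is.na(end) & start >= end
  start[empty] <- NA_real_
  end[empty] <- NA_real_
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = start, end = end, strand = genes$strand,
                    stringsAsFactors = FALSE)
  if (drop_degenerate) {
    bad <- is.na(out$start)
    if (any(bad))
      message("excluded ", sum(bad), " gene(s) with degenerate ", spec$kind,
              " region(s)")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Intervals of one set not overlapping another
#'
#' Whole-interval granularity: an interval of `a` is kept iff it overlaps no
#' interval of `b`; nothing is trimmed. This is the "unique peaks" operation
#' used when comparing peak sets between conditions.
#'
#' @param a,b interval sets.
#' @return The subset of `a` (canonical order) with zero overlap with `b`.
#' @export
subtract_overlapping <- function(a, b) {
  a_sorted <- interval_set(a$chrom, a$start, a$end, strand = a$strand,
                           name = a$name, score = a$score,
                           sample_label = attr(a, "sample_label") %||% "a")
  if (nrow(a_sorted) == 0L || nrow(b) == 0L) return(a_sorted)
  h <- harmonize_seqlevels(as_granges(as.data.frame(a_sorted)),
                           as_granges(as.data.frame(b)))
  hit <- IRanges::overlapsAny(h$a, h$b)
  out <- a_sorted[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Fraction of intervals in one set overlapping another
#'
#' @param a,b interval sets; `a` must be non-empty.
#' @return `(number of a-intervals overlapping >= 1 b-interval) / |a|`.
#' @export
overlap_fraction <- function(a, b) {
  if (nrow(a) == 0L)
    stop("overlap fraction undefined for an empty query set", call. = FALSE)
  if (nrow(b) == 0L) return(0)
  h <- harmonize_seqlevels(as_granges(as.data.frame(a)),
                           as_granges(as.data.frame(b)))
  mean(IRanges::overlapsAny(h$a, h$b))
}

#' Fraction of the genome covered by a widened interval set
#'
#' Each interval is widened by `extend` bp on both sides (clipped to
#' chromosome bounds), the union is taken, and the covered length is divided
#' by the total genome length. This is the null proportion used by
#' [proximity_test()]: the probability that a uniformly placed point lies
#' within `extend` bp of the set.
#'
#' @param b an interval set.
#' @param genome a [genome_table()] covering every chromosome of `b`.
#' @param extend widening in bp (>= 0).
#' @return Covered fraction in `(0, 1]` (0 if `b` is empty).
#' @export
coverage_fraction <- function(b, genome, extend = 0) {
  if (extend < 0) stop("extend must be >= 0", call. = FALSE)
  total <- sum(unclass(genome))
  if (nrow(b) == 0L) return(0)
  miss <- setdiff(unique(b$chrom), names(genome))
  if (length(miss))
    stop("chromosome(s) missing from genome table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  start <- pmax(b$start - extend, 0)
  end <- pmin(b$end + extend, unclass(genome)[b$chrom])
  gr <- GenomicRanges::reduce(as_granges(
    data.frame(chrom = b$chrom, start = start, end = end)))
  sum(as.numeric(GenomicRanges::width(gr))) / total
}
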