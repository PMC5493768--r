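# Tag-to-density quantification. Every tag is assigned to at most one
# position by its midpoint, floor((start + end) / 2), so a tag is counted
# exactly once per region and never double-counted at bin boundaries.
# RPM = raw_count * 1e6 / library_size; RPKM = RPM * 1000 / region length.

tag_midpoints <- function(tags) floor((tags$start + tags$end) / 2)

# GRanges of width-1 midpoint positions.
midpoint_granges <- function(tags) {
  mid <- tag_midpoints(tags)
  GenomicRanges::GRanges(tags$chrom, IRanges::IRanges(mid + 1, width = 1))
}

#' Tag density of a single region
#'
#' Counts tags whose midpoint lies in `[start, end)` of the region and
#' normalizes to reads per million mapped (RPM) and per kb of region length
#' (RPKM).
#'
#' @param tags a [tag_set()].
#' @param region a one-row data frame (or list) with `chrom`, `start`, `end`.
#' @return A list with `raw_count`, `rpm`, `rpkm`, `region_length`.
#' @export
region_density <- function(tags, region) {
  mid <- tag_midpoints(tags)
  inside <- tags$chrom == region$chrom & mid >= region$start &
    mid < region$end
  raw <- sum(inside)
  rpm <- raw * 1e6 / library_size(tags)
  len <- region$end - region$start
  list(raw_count = raw, rpm = rpm, rpkm = rpm * 1000 / len,
       region_length = len)
}

#' Per-gene region densities for a whole gene table
#'
#' Builds the anchored region of every gene (see [anchored_regions()]),
#' drops genes with degenerate regions (with a diagnostic), and counts tag
#' midpoints per region. Equivalent to calling [region_density()] gene by
#' gene, but vectorized.
#'
#' @param tags a [tag_set()].
#' @param genes a [gene_models()] table (non-empty).
#' @param spec a [region_spec()].
#' @param genome optional [genome_table()] for clipping.
#' @return A data frame of class `density_table`, ordered by `gene_id`:
#'   `gene_id`, `region_kind`, `raw_count`, `rpm`, `rpkm`, `region_length`.
#' @export
gene_density_table <- function(tags, genes, spec, genome = NULL) {
  if (nrow(genes) == 0L) stop("empty gene table", call. = FALSE)
  regions <- anchored_regions(genes, spec, genome, drop_degenerate = TRUE)
  if (nrow(regions) == 0L)
    stop("all genes excluded as degenerate for region kind ", spec$kind,
         call. = FALSE)
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1, regions$end))
  h <- harmonize_seqlevels(reg_gr, midpoint_granges(tags))
  hits <- GenomicRanges::countOverlaps(h$a, h$b)
  rpm <- hits * 1e6 / library_size(tags)
  len <- regions$end - regions$start
  out <- data.frame(gene_id = regions$gene_id, region_kind = spec$kind,
                    raw_count = as.integer(hits), rpm = rpm,
                    rpkm = rpm * 1000 / len, region_length = len,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("density_table", "data.frame")
  out
}

#' Scaled metagene profile (flank - scaled gene body - flank)
#'
#' Each gene body is rescaled to `n_body_bins` percent-of-gene bins and
#' bracketed by fixed-width flank bins covering `flank_bp` upstream of the
#' TSS and downstream of the TES. Tag midpoints are assigned to bins; each
#' gene's bin value is RPM divided by the bin width in kb, so 100-bp flank
#' bins and variable-width body bins share one axis; the profile is the mean
#' over genes. Minus-strand genes are reversed so bin order always runs
#' 5' to 3'. Genes shorter than `n_body_bins` bp are excluded with a
#' diagnostic.
#'
#' @param tags a [tag_set()].
#' @param genes a [gene_models()] table.
#' @param flank_bp flank extent in bp (default 5000).
#' @param flank_bin_bp flank bin width in bp (default 100; must divide
#'   `flank_bp`).
#' @param n_body_bins number of percent-of-gene body bins (default 100).
#' @return An object of class `metagene_profile`: list with `upstream`,
#'   `body`, `downstream` numeric vectors (mean RPM/kb per bin),
#'   `bin_definitions` and `n_genes`.
#' @export
metagene_profile <- function(tags, genes, flank_bp = 5000,
                             flank_bin_bp = 100, n_body_bins = 100) {
  if (flank_bp %% flank_bin_bp != 0)
    stop("flank_bin_bp must divide flank_bp", call. = FALSE)
  n_flank <- flank_bp / flank_bin_bp
  len <- genes$tx_end - genes$tx_start
  keep <- len >= n_body_bins
  if (any(!keep))
    message("excluded ", sum(!keep), " gene(s) shorter than ", n_body_bins,
            " bp from the metagene profile")
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0L)
    stop("all genes excluded from the metagene profile", call. = FALSE)
  len <- genes$tx_end - genes$tx_start
  n_genes <- nrow(genes)
  n_bins <- 2L * n_flank + n_body_bins

  # (tag, gene) pairs where the midpoint falls in [tx_start-flank, tx_end+flank)
  mid_gr <- midpoint_granges(tags)
  ext_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$tx_start - flank_bp, 0) + 1,
                     genes$tx_end + flank_bp))
  h <- harmonize_seqlevels(mid_gr, ext_gr)
  ov <- GenomicRanges::findOverlaps(h$a, h$b)
  total <- numeric(n_bins * n_genes) # per (gene, bin) weighted counts, flat
  if (length(ov)) {
    ti <- S4Vectors::queryHits(ov)
    gi <- S4Vectors::subjectHits(ov)
    mid <- tag_midpoints(tags)[ti]
    plus <- genes$strand[gi] == "+"
    # transcript-oriented offset from the TSS (0 = first transcribed base)
    rel <- ifelse(plus, mid - genes$tx_start[gi],
                  (genes$tx_end[gi] - 1) - mid)
    gl <- len[gi]
    zone <- ifelse(rel < 0, 1L, ifelse(rel < gl, 2L, 3L))
    bin <- integer(length(rel))
    bin[zone == 1L] <- floor((rel[zone == 1L] + flank_bp) / flank_bin_bp) + 1L
    bin[zone == 2L] <- n_flank +
      pmin(floor(rel[zone == 2L] / gl[zone == 2L] * n_body_bins), n_body_bins - 1) + 1L
    bin[zone == 3L] <- n_flank + n_body_bins +
      floor((rel[zone == 3L] - gl[zone == 3L]) / flank_bin_bp) + 1L
    ok <- bin >= 1L & bin <= n_bins & rel >= -flank_bp & rel < gl + flank_bp
    # weight: RPM per kb of bin = 1e9 / (library_size * bin_width_bp)
    width_bp <- ifelse(zone == 2L, gl / n_body_bins, flank_bin_bp)
    w <- 1e9 / (library_size(tags) * width_bp)
    idx <- (gi[ok] - 1L) * n_bins + bin[ok]
    acc <- rowsum(w[ok], idx)
    total[as.integer(rownames(acc))] <- acc[, 1L]
  }
  bin_means <- unname(rowsum(total, rep(seq_len(n_bins),
                                        times = n_genes))[, 1L]) / n_genes
  structure(list(
    upstream = bin_means[seq_len(n_flank)],
    body = bin_means[n_flank + seq_len(n_body_bins)],
    downstream = bin_means[n_flank + n_body_bins + seq_len(n_flank)],
    bin_definitions = list(flank_bp = flank_bp, flank_bin_bp = flank_bin_bp,
                           n_body_bins = n_body_bins),
    n_genes = n_genes
  ), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  d <- x$bin_definitions
  cat(sprintf(
    "<metagene_profile> %d genes; %d+%d+%d bins (%d bp flanks, %d bp flank bins)\n",
    x$n_genes, length(x$upstream), length(x$body), length(x$downstream),
    d$flank_bp, d$flank_bin_bp))
  cat(sprintf("  mean signal: upstream %.4g, body %.4g, downstream %.4g RPM/kb\n",
              mean(x$upstream), mean(x$body), mean(x$downstream)))
  invisible(x)
}

#' Metagene profile as a plain table
#'
#' @param x a [metagene_profile()].
#' @param ... unused.
#' @return Data frame with `bin` (1..total), `position_label` (e.g. `-5000`,
#'   `body_37%`, `+4900`) and `value` (mean RPM/kb).
#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  d <- x$bin_definitions
  n_flank <- length(x$upstream)
  labels <- c(
    sprintf("%d", seq(-d$flank_bp, -d$flank_bin_bp, by = d$flank_bin_bp)),
    sprintf("body_%d%%", seq_len(d$n_body_bins)),
    sprintf("+%d", seq(0, d$flank_bp - d$flank_bin_bp, by = d$flank_bin_bp))
  )
  data.frame(bin = seq_along(labels), position_label = labels,
             value = c(x$upstream, x$body, x$downstream),
             stringsAsFactors = FALSE)
}

#' Plot a metagene profile
#'
#' @param x a [metagene_profile()].
#' @param add add to an existing plot?
#' @param col line colour.
#' @param ... passed to [graphics::lines()] / [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.metagene_profile <- function(x, add = FALSE, col = "black", ...) {
  v <- c(x$upstream, x$body, x$downstream)
  n_flank <- length(x$upstream)
  if (!add) {
    graphics::plot(seq_along(v), v, type = "l", col = col,
                   xlab = "position (flank | body 1-100% | flank)",
                   ylab = "mean signal (RPM/kb)", xaxt = "n", ...)
    graphics::axis(1, at = c(1, n_flank + 1, n_flank + length(x$body),
                             length(v)),
                   labels = c(sprintf("-%d bp", x$bin_definitions$flank_bp),
                              "TSS", "TES",
                              sprintf("+%d bp", x$bin_definitions$flank_bp)))
    graphics::abline(v = c(n_flank + 0.5, n_flank + length(x$body) + 0.5),
                     lty = 3, col = "grey")
  } else {
    graphics::lines(seq_along(v), v, col = col, ...)
  }
  invisible(x)
}

#' Gene-by-sample log2 RPM matrix on promoters and gene bodies
#'
#' For every tag sample and both region kinds, computes per-gene RPM and
#' returns `log2(rpm + pseudocount)` with genes as rows and
#' `sample:region` columns. Genes degenerate for either region in any sample
#' are dropped so all columns share one gene order. Column means (the values
#' the per-column violin summaries display) are attached as attribute
#' `column_means`.
#'
#' @param genes a [gene_models()] table.
#' @param tag_samples named list of [tag_set()] objects.
#' @param promoter promoter [region_spec()] (default 500 bp each side of the
#'   TSS).
#' @param body gene-body [region_spec()] (default TSS+500 to TES).
#' @param pseudocount added to RPM before log2 (default 1).
#' @param genome optional [genome_table()] for clipping.
#' @return A numeric matrix of class `region_matrix` with attribute
#'   `column_means`.
#' @export
region_matrix <- function(genes, tag_samples,
                          promoter = region_spec("promoter", 500, 500),
                          body = region_spec("gene_body", downstream_bp = 500),
                          pseudocount = 1, genome = NULL) {
  if (nrow(genes) == 0L || length(tag_samples) == 0L)
    stop("need >= 1 gene and >= 1 tag sample", call. = FALSE)
  if (is.null(names(tag_samples)))
    names(tag_samples) <- vapply(tag_samples, function(t)
      attr(t, "sample_label"), "")
  tabs <- list()
  for (s in names(tag_samples)) {
    for (rk in list(promoter = promoter, body = body)) {
      dt <- gene_density_table(tag_samples[[s]], genes, rk, genome)
      tabs[[paste0(s, ":", rk$kind)]] <- dt
    }
  }
  common <- Reduce(intersect, lapply(tabs, `[[`, "gene_id"))
  common <- sort(common)
  m <- vapply(tabs, function(dt) {
    v <- dt$rpm[match(common, dt$gene_id)]
    log2(v + pseudocount)
  }, numeric(length(common)))
  m <- matrix(m, nrow = length(common), dimnames = list(common, names(tabs)))
  attr(m, "column_means") <- colMeans(m)
  attr(m, "pseudocount") <- pseudocount
  class(m) <- c("region_matrix", class(m))
  m
}
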