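# Fixture generators and brute-force oracles, independent of the package's
# interval code path: per-base boolean masks and all-pairs scans on toy
# chromosomes.

rand_intervals <- function(n, chroms = c("chrA", "chrB"), G = 1e5,
                           max_len = 800) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, G - max_len))
  len <- ceiling(runif(n, 1, max_len))
  interval_set(chrom, start, start + len, sample_label = "random")
}

# per-base boolean mask of an interval set on one chromosome of length G
chrom_mask <- function(x, chrom, G) {
  m <- logical(G)
  rows <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(rows)))
    m[(rows$start[i] + 1):rows$end[i]] <- TRUE
  m
}

# merged intervals recovered from mask runs (0-based half-open)
mask_to_intervals <- function(m, chrom) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep])
}

# edge-to-edge gap between half-open intervals; 0 when overlapping/touching
pair_gap <- function(qs, qe, ss, se) {
  ifelse(qe <= ss, ss - qe, ifelse(se <= qs, qs - se, 0))
}

# all-pairs O(n*m) within-window hit flags
brute_hits <- function(query, subject, window) {
  vapply(seq_len(nrow(query)), function(i) {
    same <- subject$chrom == query$chrom[i]
    if (!any(same)) return(FALSE)
    any(pair_gap(query$start[i], query$end[i],
                 subject$start[same], subject$end[same]) <= window)
  }, logical(1))
}

brute_overlapping <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    same <- b$chrom == a$chrom[i]
    any(same & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# uniform tag set on given chromosomes (width-1 tags at integer midpoints)
uniform_tags <- function(n, chroms, G, width = 1, ...) {
  chrom <- sample(chroms, n, replace = TRUE)
  s <- floor(runif(n, 0, G - width))
  tag_set(chrom, s, s + width, ...)
}

toy_genes <- function(n, chrom = "chrA", G = 1e5, len_range = c(500, 3000),
                      margin = 6000) {
  len <- floor(runif(n, len_range[1], len_range[2]))
  start <- floor(runif(n, margin, G - margin - len_range[2]))
  gene_models(sprintf("g%03d", seq_len(n)), chrom,
              sample(c("+", "-"), n, replace = TRUE), start, start + len)
}

small_sim_config <- function(seed, ...) {
  simulation_config(seed = seed, n_chroms = 2, chrom_length_bp = 1.5e6,
                    n_genes = 200, library_size = 8e4, ...)
}
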