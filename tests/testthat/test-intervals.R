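# Interval algebra against per-base mask and all-pairs oracles, plus the
# pinned boundary conventions (touching merges; gap <= window inclusive;
# strand-aware anchored regions with clipping).

test_that("merge joins overlapping and touching intervals and is idempotent", {
  m <- merge_intervals(interval_set(c("chr1", "chr1"), c(100, 150),
                                    c(200, 300)))
  expect_equal(as.data.frame(m)[c("start", "end")],
               data.frame(start = 100, end = 300))
  m2 <- merge_intervals(interval_set(c("chr1", "chr1"), c(100, 200),
                                     c(200, 300)))
  expect_equal(m2$start, 100)
  expect_equal(m2$end, 300)
  set.seed(7)
  x <- rand_intervals(300)
  expect_identical(as.data.frame(merge_intervals(merge_intervals(x))),
                   as.data.frame(merge_intervals(x)))
})

test_that("merged coverage equals the per-base mask union on random intervals", {
  set.seed(11)
  x <- rand_intervals(500, chroms = "chrA", G = 1e5)
  m <- merge_intervals(x)
  mask <- chrom_mask(x, "chrA", 1e5)
  expect_equal(sum(m$end - m$start), sum(mask))
  expect_equal(as.data.frame(m)[c("chrom", "start", "end")],
               mask_to_intervals(mask, "chrA"),
               ignore_attr = TRUE)
})

test_that("window counting honours the inclusive edge-to-edge gap convention", {
  q <- interval_set("chr1", 1000, 1100)
  expect_true(count_within_window(q, interval_set("chr1", 1500, 1600),
                                  500)$hits)  # gap 400
  expect_false(count_within_window(q, interval_set("chr1", 1601, 1700),
                                   500)$hits) # gap 501
  expect_true(count_within_window(q, interval_set("chr1", 1600, 1700),
                                  500)$hits)  # gap 500 exactly
  # window 0 counts overlap-or-touching only
  expect_true(count_within_window(q, interval_set("chr1", 1100, 1200),
                                  0)$hits)
  expect_false(count_within_window(q, interval_set("chr1", 1101, 1200),
                                   0)$hits)
})

test_that("window counting matches the all-pairs scan and is monotone in window", {
  set.seed(13)
  q <- rand_intervals(200)
  s <- rand_intervals(200)
  prev_k <- -1
  for (w in c(0, 100, 500, 2000)) {
    res <- count_within_window(q, s, w)
    expect_identical(res$hits, brute_hits(q, s, w))
    expect_equal(res$k, sum(res$hits))
    expect_gte(res$k, prev_k)
    prev_k <- res$k
  }
})

test_that("anchored promoter regions are strand-aware, mirrored and clipped", {
  gp <- list(gene_id = "g1", chrom = "chr1", strand = "+",
             tx_start = 10000, tx_end = 20000)
  gm <- list(gene_id = "g2", chrom = "chr1", strand = "-",
             tx_start = 2000, tx_end = 10000)
  p <- region_spec("promoter", 500, 500)
  rp <- anchored_region(gp, p)
  expect_equal(c(rp$start, rp$end), c(9500, 10500))
  rm_ <- anchored_region(gm, p)
  expect_equal(c(rm_$start, rm_$end), c(9500, 10500))
  # clipping at the chromosome start
  g0 <- list(gene_id = "g3", chrom = "chr1", strand = "+",
             tx_start = 300, tx_end = 5000)
  r0 <- anchored_region(g0, region_spec("promoter", 1000, 1000))
  expect_equal(c(r0$start, r0$end), c(0, 1300))
  # clipping at the chromosome end needs a genome table
  gend <- list(gene_id = "g4", chrom = "chr1", strand = "-",
               tx_start = 9000, tx_end = 9900)
  rend <- anchored_region(gend, region_spec("promoter", 1000, 1000),
                          genome_table("chr1", 10000))
  expect_equal(c(rend$start, rend$end), c(8900, 10000))
})

test_that("gene bodies drop the TSS offset on the correct strand side", {
  sp <- region_spec("gene_body", downstream_bp = 500)
  rp <- anchored_region(list(gene_id = "g", chrom = "c", strand = "+",
                             tx_start = 1000, tx_end = 4000), sp)
  expect_equal(c(rp$start, rp$end), c(1500, 4000))
  rm_ <- anchored_region(list(gene_id = "g", chrom = "c", strand = "-",
                              tx_start = 1000, tx_end = 4000), sp)
  expect_equal(c(rm_$start, rm_$end), c(1000, 3500))
  expect_error(anchored_region(list(gene_id = "tiny", chrom = "c",
                                    strand = "+", tx_start = 0,
                                    tx_end = 400), sp), "degenerate")
})

test_that("anchored regions of mirror-image genes are mirror images", {
  set.seed(17)
  G <- 1e5
  genes <- toy_genes(40, G = G)
  mirrored <- gene_models(genes$gene_id, genes$chrom,
                          ifelse(genes$strand == "+", "-", "+"),
                          G - genes$tx_end, G - genes$tx_start)
  for (spec in list(region_spec("promoter", 700, 300),
                    region_spec("gene_body", downstream_bp = 200),
                    region_spec("upstream_flank", upstream_bp = 1500),
                    region_spec("whole_gene"))) {
    a <- anchored_regions(genes, spec)
    b <- anchored_regions(mirrored, spec)
    expect_equal(b$start[match(a$gene_id, b$gene_id)], G - a$end)
    expect_equal(b$end[match(a$gene_id, b$gene_id)], G - a$start)
  }
})

test_that("subtraction keeps whole non-overlapping intervals and partitions the set", {
  a <- interval_set("chr1", 0, 100)
  expect_equal(nrow(subtract_overlapping(a, interval_set())), 1L)
  expect_equal(nrow(subtract_overlapping(a, interval_set("chr1", 50, 60))),
               0L)
  set.seed(19)
  x <- rand_intervals(300)
  y <- rand_intervals(150)
  kept <- subtract_overlapping(x, y)
  expect_equal(nrow(kept) + sum(brute_overlapping(x, y)), nrow(x))
  expect_false(any(brute_overlapping(kept, y)))
})

test_that("overlap fraction matches the brute-force scan", {
  x <- interval_set(c("chr1", "chr2"), c(0, 0), c(10, 10))
  expect_equal(overlap_fraction(x, x), 1.0)
  y <- interval_set("chr3", 0, 10)
  expect_equal(overlap_fraction(x, y), 0.0)
  expect_error(overlap_fraction(interval_set(), x), "empty")
  set.seed(23)
  a <- rand_intervals(200)
  b <- rand_intervals(100)
  expect_equal(overlap_fraction(a, b), mean(brute_overlapping(a, b)))
})

test_that("coverage fraction matches the closed form and the mask oracle", {
  gen <- genome_table("chr1", 1e5)
  b <- interval_set("chr1", 50000, 51000)
  expect_equal(coverage_fraction(b, gen, extend = 500), 2000 / 1e5)
  # widened overlapping intervals never double-count
  b2 <- interval_set(c("chr1", "chr1"), c(1000, 1500), c(1400, 2000))
  expect_lte(coverage_fraction(b2, gen, extend = 300),
             (400 + 600 + 1200) / 1e5)
  set.seed(29)
  x <- rand_intervals(200, chroms = "chr1", G = 1e5)
  for (ext in c(0, 250)) {
    widened <- interval_set(x$chrom, pmax(x$start - ext, 0),
                            pmin(x$end + ext, 1e5))
    expect_equal(coverage_fraction(x, gen, ext),
                 sum(chrom_mask(widened, "chr1", 1e5)) / 1e5)
  }
  expect_error(coverage_fraction(interval_set("chrZ", 0, 10), gen, 0),
               "chrZ")
})
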