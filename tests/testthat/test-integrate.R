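# Decision-layer statistics against enumeration oracles and hand arithmetic.

make_density <- function(ids, rpm) {
  structure(data.frame(gene_id = ids, region_kind = "whole_gene",
                       raw_count = NA_integer_, rpm = rpm, rpkm = rpm,
                       region_length = 1000, stringsAsFactors = FALSE),
            class = c("density_table", "data.frame"))
}

test_that("DE partition applies the strict threshold and direction signs", {
  de <- read_de_table(withr::local_tempfile(lines = c(
    "gene_id\texpr_a\texpr_b\tlog2fc\tp_value",
    "up1\t1\t2\t1\t0.04",
    "edge\t1\t2\t1\t0.05",
    "dn1\t2\t1\t-1\t0.01",
    "flat\t1\t1\t0\t0.001",
    "ns\t1\t4\t2\t0.5")))
  parts <- de_partition(de, 0.05)
  expect_equal(parts$up, "up1")
  expect_equal(parts$down, "dn1")
  expect_error(de_partition(de, 0), "alpha")
  set.seed(47)
  n <- 100
  de2 <- de_table(sprintf("g%03d", 1:n), runif(n, 0, 10), runif(n, 0, 10),
                  rnorm(n), runif(n), runif(n))
  p2 <- de_partition(de2, 0.2)
  expect_equal(sort(p2$up),
               sort(de2$gene_id[de2$p_value < 0.2 & de2$log2fc > 0]))
  expect_equal(sort(p2$down),
               sort(de2$gene_id[de2$p_value < 0.2 & de2$log2fc < 0]))
})

test_that("binomial tails match closed forms and full pmf enumeration", {
  expect_equal(binomial_test(10, 10, 0.5, "greater"), 0.5^10)
  expect_equal(binomial_test(5, 10, 0.5, "two_sided"), 1.0)
  for (n in 1:20) {
    p0 <- c(0.3, 0.5, 0.71)[(n %% 3) + 1]
    pmf <- dbinom(0:n, n, p0)
    for (k in 0:n) {
      expect_equal(binomial_test(k, n, p0, "greater"), sum(pmf[(k:n) + 1]),
                   tolerance = 1e-12)
      expect_equal(binomial_test(k, n, p0, "less"), sum(pmf[0:k + 1]),
                   tolerance = 1e-12)
      expect_equal(binomial_test(k, n, p0, "two_sided"),
                   min(1, 2 * min(sum(pmf[0:k + 1]), sum(pmf[(k:n) + 1]))),
                   tolerance = 1e-12)
    }
  }
  # one-sided tails agree with stats::binom.test
  expect_equal(binomial_test(39, 120, 0.25, "greater"),
               binom.test(39, 120, 0.25, "greater")$p.value)
  expect_error(binomial_test(11, 10, 0.5), "k <= n")
})

test_that("ratio classification counts, fractions and p-values are exact", {
  a <- make_density(sprintf("g%02d", 1:10), rep(1, 10))
  b <- make_density(sprintf("g%02d", 1:10), rep(2, 10))
  cls <- classify_ratio(a, b)
  expect_equal(cls$k_higher, 10)
  expect_equal(cls$fraction_higher, 1.0)
  expect_equal(cls$binom_p, 2 * 0.5^10)
  # all ties: fraction and p undefined
  expect_message(tie <- classify_ratio(a, a), "tie")
  expect_equal(tie$n_informative, 0)
  expect_true(is.na(tie$fraction_higher))
  expect_true(is.na(tie$binom_p))
  # mismatched universes name the symmetric difference
  expect_error(classify_ratio(a, make_density("gX", 1)), "gX")
})

test_that("ratio classification is antisymmetric in the two conditions", {
  set.seed(53)
  for (rep in 1:5) {
    ids <- sprintf("g%03d", 1:80)
    a <- make_density(ids, rpois(80, 20) / 2)
    b <- make_density(ids, rpois(80, 20) / 2)
    ab <- classify_ratio(a, b)
    ba <- classify_ratio(b, a)
    expect_equal(ba$k_higher, ab$n_informative - ab$k_higher)
    expect_equal(ba$n_informative, ab$n_informative)
    if (ab$n_informative > 0) expect_equal(ba$binom_p, ab$binom_p)
  }
})

test_that("proximity test handles saturated and disjoint configurations", {
  gen <- genome_table("chr1", 1e5)
  q <- interval_set("chr1", c(10, 5000), c(500, 6000))
  whole <- interval_set("chr1", 0, 1e5)
  sat <- proximity_test(q, whole, 500, gen)
  expect_equal(sat$k, sat$n)
  expect_equal(sat$p0, 1)
  expect_equal(sat$binom_p, 1)
  gen2 <- genome_table(c("chr1", "chr2"), c(1e5, 1e5))
  far <- proximity_test(q, interval_set("chr2", 0, 100), 500, gen2)
  expect_equal(far$k, 0)
  expect_equal(far$binom_p, 1)
  expect_error(proximity_test(interval_set(), whole, 500, gen), "non-empty")
})

test_that("Welch cohort comparison matches the closed form and its conventions", {
  m <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  same <- cohort_compare(cbind(m, m)[, c(1, 1)], 1, 2)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(59)
  jit <- m + matrix(rnorm(8, sd = 1e-6), ncol = 2)
  sep <- cohort_compare(jit, "a", "b")
  expect_lt(sep$p, 1e-6)
  # hand-computed Welch statistic on a 20-value fixture
  x <- c(4.1, 5.2, 6.3, 3.9, 5.5, 4.8, 5.1, 6.0, 4.4, 5.3)
  y <- c(6.2, 7.1, 5.9, 6.8, 7.4, 6.5, 7.0, 6.1, 6.9, 7.2)
  mm <- cbind(a = x, b = y)
  got <- cohort_compare(mm, "a", "b")
  se <- sqrt(var(x) / 10 + var(y) / 10)
  t_hand <- (mean(y) - mean(x)) / se
  df_hand <- se^4 / ((var(x) / 10)^2 / 9 + (var(y) / 10)^2 / 9)
  expect_equal(got$t, t_hand)
  expect_equal(got$df, df_hand)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df_hand))
})

test_that("percentages use half-away-from-zero rounding", {
  expect_equal(fraction_summary(439, 703, 0), 62)
  expect_equal(fraction_summary(310, 439, 1), 70.6)
  expect_equal(fraction_summary(0, 10, 1), 0.0)
  expect_equal(fraction_summary(1, 8, 0), 13)    # 12.5 rounds away from zero
  expect_equal(fraction_summary(1, 800, 2), 0.13) # 0.125 likewise
  expect_error(fraction_summary(5, 0), "n must")
  # complement sums to 100 up to rounding
  set.seed(61)
  for (i in 1:20) {
    n <- sample(1000, 1)
    k <- sample(0:n, 1)
    expect_equal(fraction_summary(k, n, 1) + fraction_summary(n - k, n, 1),
                 100, tolerance = 0.11)
  }
})

test_that("hypergeometric enrichment matches pmf summation on toy configurations", {
  uni <- sprintf("g%02d", 1:20)
  res <- ora_hypergeometric(uni, list(all = uni), uni)
  expect_equal(res$p, 1.0)
  res0 <- ora_hypergeometric(uni[1:6], list(off = uni[7:10]), uni)
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p, 1.0)
  # 4-set toy configuration vs direct pmf summation
  gene_list <- uni[1:6]
  sets <- list(s1 = uni[c(1:3, 15)], s2 = uni[5:12], s3 = uni[c(2, 4, 6, 8)],
               s4 = uni[19:20])
  res4 <- ora_hypergeometric(gene_list, sets, uni)
  for (i in seq_along(sets)) {
    s <- intersect(sets[[i]], uni)
    k <- length(intersect(gene_list, s))
    ks <- k:min(length(s), length(gene_list))
    p_manual <- sum(choose(length(s), ks) *
                      choose(20 - length(s), length(gene_list) - ks) /
                      choose(20, length(gene_list)))
    expect_equal(res4$p[i], p_manual, tolerance = 1e-12)
  }
  expect_true(all(res4$q >= res4$p))
  expect_error(ora_hypergeometric("gX", sets, uni), "outside the universe")
  expect_error(ora_hypergeometric("g01", sets, character()), "empty universe")
})

test_that("BH adjustment matches its step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  set.seed(67)
  p <- runif(50)
  q <- bh_adjust(p)
  m <- length(p)
  ord <- order(p)
  q_def <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(rank(p, ties.method = "first") >= rank(p, ties.method = "first")[i])
    # definitional: q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank_j
    ranks <- rank(p, ties.method = "max")
    q_def[i] <- min(pmin(p[p >= p[i]] * m / ranks[p >= p[i]], 1))
  }
  expect_equal(q, q_def)
})
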