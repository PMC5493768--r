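# Decision layer: DE partitioning, exact binomial tests, per-gene
# condition-ratio classification, peak proximity co-localization against a
# genome-coverage null, Welch cohort comparisons, fraction reporting and
# hypergeometric over-representation analysis.

#' Partition a DE table into up- and downregulated gene sets
#'
#' Strict threshold: a gene is significant iff its p-value (or q-value) is
#' strictly below `alpha`; the sign of `log2fc` decides the direction and
#' genes with `log2fc == 0` are excluded.
#'
#' @param de a `de_table` from [read_de_table()].
#' @param alpha significance threshold in (0, 1), default 0.05.
#' @param criterion `"p"` (default) or `"q"`.
#' @return A list with character vectors `up` and `down`.
#' @export
de_partition <- function(de, alpha = 0.05, criterion = c("p", "q")) {
  criterion <- match.arg(criterion)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  pv <- if (criterion == "p") de$p_value else de$q_value
  sig <- pv < alpha
  list(up = de$gene_id[sig & de$log2fc > 0],
       down = de$gene_id[sig & de$log2fc < 0])
}

#' Exact binomial test
#'
#' Exact binomial tail probabilities. The two-sided p-value uses the
#' doubled-tail convention, `min(1, 2 * min(lower tail, upper tail))`, which
#' differs from the minimum-likelihood convention of
#' [stats::binom.test()]; one-sided tails agree with it exactly.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param p0 null success probability in (0, 1).
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @return The p-value.
#' @export
binomial_test <- function(k, n, p0,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n < 1 || k < 0 || k > n || k != floor(k) || n != floor(n))
    stop("need integers 0 <= k <= n with n >= 1", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE) # P(X >= k)
  lower <- stats::pbinom(k, n, p0)                         # P(X <= k)
  switch(alternative,
         greater = upper,
         less = lower,
         two_sided = min(1, 2 * min(lower, upper)))
}

#' Classify per-gene condition ratios and test the split
#'
#' Compares the per-gene densities of two conditions (e.g. intragenic 5hmC
#' in knockout vs wild type). A gene is `higher` iff
#' `rpm_b > rpm_a + tie_epsilon`, `lower` iff `rpm_b < rpm_a - tie_epsilon`,
#' otherwise a `tie`; ties are excluded from the binomial denominator. The
#' reported p-value is the two-sided exact binomial test of
#' `k_higher` out of `n_informative` against `p0 = 0.5`.
#'
#' @param dens_a,dens_b `density_table`s over the same gene ids (condition A
#'   = reference, e.g. WT; condition B = comparison, e.g. KO).
#' @param tie_epsilon RPM margin treated as a tie (default 0: exact equality
#'   only).
#' @return An object of class `classification_result`: list with `per_gene`
#'   (gene_id, value_a, value_b, ratio_b_over_a, class), `k_higher`,
#'   `n_informative`, `n_ties`, `fraction_higher`, `binom_p`, `null_p0`.
#' @export
classify_ratio <- function(dens_a, dens_b, tie_epsilon = 0) {
  only_a <- setdiff(dens_a$gene_id, dens_b$gene_id)
  only_b <- setdiff(dens_b$gene_id, dens_a$gene_id)
  if (length(only_a) || length(only_b))
    stop("gene sets differ; only in A: {",
         paste(utils::head(only_a, 5L), collapse = ", "), "}, only in B: {",
         paste(utils::head(only_b, 5L), collapse = ", "), "}", call. = FALSE)
  ids <- sort(dens_a$gene_id)
  a <- dens_a$rpm[match(ids, dens_a$gene_id)]
  b <- dens_b$rpm[match(ids, dens_b$gene_id)]
  cls <- ifelse(b > a + tie_epsilon, "higher",
                ifelse(b < a - tie_epsilon, "lower", "tie"))
  per_gene <- data.frame(gene_id = ids, value_a = a, value_b = b,
                         ratio_b_over_a = ifelse(a > 0, b / a,
                                                 ifelse(b > 0, Inf, NaN)),
                         class = cls, stringsAsFactors = FALSE)
  k <- sum(cls == "higher")
  n_inf <- sum(cls != "tie")
  if (sum(cls == "tie") > 0)
    message(sum(cls == "tie"), " tie(s) excluded from the binomial test")
  structure(list(
    per_gene = per_gene,
    k_higher = k,
    n_informative = n_inf,
    n_ties = sum(cls == "tie"),
    fraction_higher = if (n_inf > 0) k / n_inf else NA_real_,
    binom_p = if (n_inf > 0) binomial_test(k, n_inf, 0.5, "two_sided")
              else NA_real_,
    null_p0 = 0.5
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>\n")
  if (x$n_informative > 0) {
    cat(sprintf("  %d / %d genes higher in condition B (%.1f%%), %d tie(s)\n",
                x$k_higher, x$n_informative, 100 * x$fraction_higher,
                x$n_ties))
    cat(sprintf("  two-sided exact binomial vs p0 = %.2f: p = %.3g\n",
                x$null_p0, x$binom_p))
  } else {
    cat("  no informative genes (all ties); fraction and p undefined\n")
  }
  invisible(x)
}

#' Peak proximity co-localization test
#'
#' Counts query peaks lying within `window` bp (edge-to-edge, inclusive) of
#' any subject peak and tests enrichment with a one-sided (greater) exact
#' binomial test. The null proportion is the fraction of the genome within
#' `window` bp of the subject set ([coverage_fraction()] with
#' `extend = window`): the hit probability of a uniformly placed point.
#'
#' @param query,subject non-empty interval sets (e.g. merged TF peaks vs
#'   merged 5hmC peaks).
#' @param window proximity window in bp (default 500).
#' @param genome a [genome_table()] covering both sets.
#' @return An object of class `overlap_test`: list with `k`, `n`, `p0`,
#'   `binom_p`, `window_bp`, `hits`.
#' @export
proximity_test <- function(query, subject, window = 500, genome) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    stop("proximity test needs non-empty query and subject sets",
         call. = FALSE)
  cw <- count_within_window(query, subject, window)
  p0 <- coverage_fraction(subject, genome, extend = window)
  p0 <- min(p0, 1)
  binom_p <- if (p0 >= 1) 1 else binomial_test(cw$k, cw$n, p0, "greater")
  structure(list(k = cw$k, n = cw$n, p0 = p0, binom_p = binom_p,
                 window_bp = window, hits = cw$hits),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> %d / %d queries within %d bp of subject (%.1f%%)\n",
    x$k, x$n, x$window_bp, 100 * x$k / x$n))
  cat(sprintf("  null proportion (genome coverage) p0 = %.4f; one-sided binomial p = %.3g\n",
              x$p0, x$binom_p))
  invisible(x)
}

#' Welch comparison of two column groups of a region matrix
#'
#' Pools the per-gene values of the two column groups and applies Welch's
#' unequal-variance two-sample t-test (two-sided). When both groups are
#' constant with equal means the comparison is reported as `t = 0, p = 1`.
#'
#' @param matrix a [region_matrix()] (or any numeric matrix).
#' @param group_a_cols,group_b_cols column names or indices.
#' @return A list with `mean_a`, `mean_b`, `column_means`, `t`, `df`, `p`.
#' @export
cohort_compare <- function(matrix, group_a_cols, group_b_cols) {
  if (nrow(matrix) < 2L)
    stop("cohort comparison needs >= 2 genes", call. = FALSE)
  a <- as.vector(unclass(matrix)[, group_a_cols])
  b <- as.vector(unclass(matrix)[, group_b_cols])
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(mean_a = mean(a), mean_b = mean(b),
                  column_means = colMeans(unclass(matrix)), t = 0,
                  df = NA_real_, p = 1))
    # constant but separated: infinite t, p -> 0
    return(list(mean_a = mean(a), mean_b = mean(b),
                column_means = colMeans(unclass(matrix)),
                t = sign(mean(b) - mean(a)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(b, a, var.equal = FALSE)
  list(mean_a = mean(a), mean_b = mean(b),
       column_means = colMeans(unclass(matrix)),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Percentage with half-away-from-zero rounding
#'
#' `100 * k / n`, rounded half away from zero to `decimals` places (so
#' 310/439 prints as 70.6, not the banker's-rounding alternative).
#'
#' @param k numerator (0 <= k <= n).
#' @param n denominator (>= 1).
#' @param decimals decimal places (default 1).
#' @return The rounded percentage.
#' @export
fraction_summary <- function(k, n, decimals = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  x <- 100 * k / n
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Hypergeometric over-representation analysis
#'
#' Tests each named gene set for over-representation in a gene list via the
#' upper-tail hypergeometric distribution (probability of observing at least
#' the seen overlap), with Benjamini-Hochberg adjustment across sets. Sets
#' are intersected with the universe before testing.
#'
#' @param gene_list character vector, a subset of `universe`.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all eligible gene ids.
#' @return A data frame of class `enrichment_result`: `set_name`, `overlap`,
#'   `set_size`, `list_size`, `universe_size`, `p`, `q`.
#' @export
ora_hypergeometric <- function(gene_list, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  gene_list <- unique(gene_list)
  stray <- setdiff(gene_list, universe)
  if (length(stray))
    stop("gene_list contains ids outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  U <- length(universe)
  L <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(gene_list, s))
    # P(X >= k) for X ~ Hypergeom(|s| white, U - |s| black, L drawn)
    p <- stats::phyper(k - 1, length(s), U - length(s), L,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               list_size = L, universe_size = U, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement,
#' order-preserving (wraps [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}
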