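# Synthetic dataset generator with planted co-regulation structure.
#
# Emulates a two-condition (WT / KO) study with two enriched marks (5hmC,
# a promoter-binding TF) plus a non-enriched input track over shared gene
# models, a DE table, truth-interval peak calls, and a truth record for
# recovery scoring. Tags are drawn from an inhomogeneous Poisson process:
# the intensity is `background_rate` outside planted regions and the product
# of the planted fold factors inside them (so background_rate = 0 puts tags
# only in planted regions); segment intensities are rescaled so the expected
# total per sample equals `library_size`.

#' Simulation configuration
#'
#' Defines the synthetic study: genome and gene geometry, per-sample
#' sequencing depth, the fractions of genes planted as up/down-regulated and
#' (among the upregulated) as co-regulated — carrying both elevated KO
#' intragenic/promoter 5hmC and elevated KO promoter TF binding — and the
#' planted fold changes.
#'
#' @param seed integer seed driving all randomness.
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp length of each chromosome (bp).
#' @param n_genes number of non-overlapping genes to place.
#' @param gene_length_lognormal `c(meanlog, sdlog)` of gene length (log bp).
#' @param background_rate background intensity on the unit scale the planted
#'   folds multiply (default 1; 0 confines tags to planted regions).
#' @param library_size expected tags per sample.
#' @param frac_up,frac_down fractions of genes planted up/downregulated
#'   (`frac_up + frac_down <= 1`).
#' @param frac_co fraction of upregulated genes planted co-regulated.
#' @param hmc_fold KO/WT 5hmC intensity ratio on co-regulated gene bodies
#'   and promoters (> 0; > 1 plants enrichment).
#' @param tf_fold KO/WT promoter TF intensity ratio on co-regulated genes.
#' @param down_hmc_fold KO/WT body 5hmC ratio on downregulated genes
#'   (< 1 plants depletion; 1 disables it, giving a fully null 5hmC
#'   comparison).
#' @param body_base_fold 5hmC enrichment of every gene body over background
#'   (both conditions).
#' @param tf_base_fold TF enrichment of every promoter over background
#'   (both conditions).
#' @param expr_lfc_mean_sd `c(mean, sd)` of the planted |log2 fold change|.
#' @param peak_rate_threshold intensity multiple over background strictly
#'   above which a truth interval is emitted as a peak.
#' @param read_length_bp simulated read (tag) length.
#' @param plant_promoter_bp planted promoter half-width around the TSS (bp).
#' @param edge_margin_bp gene-free margin at chromosome ends so promoters
#'   and flanks stay on-chromosome.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_chroms = 4,
                              chrom_length_bp = 5e6,
                              n_genes = 2000,
                              gene_length_lognormal = c(log(3000), 0.5),
                              background_rate = 1,
                              library_size = 5e5,
                              frac_up = 0.25,
                              frac_down = 0.25,
                              frac_co = 0.25,
                              hmc_fold = 3,
                              tf_fold = 3,
                              down_hmc_fold = 0.5,
                              body_base_fold = 4,
                              tf_base_fold = 4,
                              expr_lfc_mean_sd = c(1.5, 0.5),
                              peak_rate_threshold = 2,
                              read_length_bp = 50,
                              plant_promoter_bp = 1000,
                              edge_margin_bp = 6000) {
  cfg <- as.list(environment())
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is required", call. = FALSE)
  if (cfg$frac_up + cfg$frac_down > 1)
    stop("frac_up + frac_down must be <= 1", call. = FALSE)
  folds <- c(cfg$hmc_fold, cfg$tf_fold, cfg$down_hmc_fold,
             cfg$body_base_fold, cfg$tf_base_fold)
  if (any(folds <= 0)) stop("fold factors must be > 0", call. = FALSE)
  if (cfg$background_rate < 0)
    stop("background_rate must be >= 0", call. = FALSE)
  if (cfg$library_size < 1 || cfg$n_genes < 1 || cfg$n_chroms < 1)
    stop("library_size, n_genes and n_chroms must be >= 1", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

# Place n_genes non-overlapping genes (plus edge margins) by broken-stick
# gap sampling within each chromosome.
place_genes <- function(cfg) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  lens <- round(pmax(stats::rlnorm(cfg$n_genes,
                                   cfg$gene_length_lognormal[1],
                                   cfg$gene_length_lognormal[2]), 200))
  chrom_of <- sort(sample(rep_len(chroms, cfg$n_genes)))
  usable <- cfg$chrom_length_bp - 2 * cfg$edge_margin_bp
  out <- vector("list", cfg$n_chroms)
  for (ci in seq_len(cfg$n_chroms)) {
    idx <- which(chrom_of == chroms[ci])
    li <- lens[idx]
    free <- usable - sum(li)
    if (free < length(li) + 1)
      stop("infeasible gene placement: reduce n_genes or lengthen ",
           "chromosomes", call. = FALSE)
    # broken-stick gaps: keeps every gene >= 1 bp apart from its neighbour
    g <- stats::runif(length(li) + 1)
    gaps <- floor(g / sum(g) * free)
    starts <- cfg$edge_margin_bp + cumsum(gaps[seq_along(li)]) +
      c(0, cumsum(li[-length(li)]))
    out[[ci]] <- data.frame(chrom = chroms[ci], tx_start = starts,
                            tx_end = starts + li,
                            stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, out)
  g$gene_id <- sprintf("gene_%04d", seq_len(nrow(g)))
  g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
  gene_models(g$gene_id, g$chrom, g$strand, g$tx_start, g$tx_end)
}

# Piecewise-constant intensity: planted regions (chrom/start/end/fold) over
# a background. Returns disjoint segments with the fold product per segment.
intensity_segments <- function(planted, genome, background_rate) {
  chroms <- names(genome)
  all_gr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(1, unclass(genome)[chroms]))
  if (nrow(planted) == 0L) {
    return(data.frame(chrom = chroms, start = 0,
                      end = unclass(genome)[chroms],
                      fold = background_rate, stringsAsFactors = FALSE))
  }
  pg <- as_granges(planted[c("chrom", "start", "end")])
  d <- GenomicRanges::disjoin(pg)
  ov <- GenomicRanges::findOverlaps(d, pg)
  logf <- rep(0, length(d))
  acc <- rowsum(log(planted$fold[S4Vectors::subjectHits(ov)]),
                S4Vectors::queryHits(ov))
  logf[as.integer(rownames(acc))] <- acc[, 1L]
  seg_planted <- cbind(granges_to_df(d), fold = exp(logf))
  bg <- granges_to_df(GenomicRanges::setdiff(all_gr, d))
  seg_bg <- if (nrow(bg)) cbind(bg, fold = background_rate) else NULL
  seg <- rbind(seg_planted, seg_bg)
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

# Draw Poisson tags along piecewise-constant segments; expected total equals
# library_size.
draw_tags <- function(segments, library_size, read_length_bp, genome) {
  w <- (segments$end - segments$start) * segments$fold
  total_w <- sum(w)
  if (total_w <= 0) # nothing has positive intensity: an empty sample
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  lambda <- w / total_w * library_size
  n_i <- stats::rpois(length(lambda), lambda)
  reps <- rep(seq_along(n_i), n_i)
  # the drawn position is the tag midpoint; the read interval is built
  # around it so the midpoint rule recovers the sampled position exactly
  pos <- segments$start[reps] +
    floor(stats::runif(length(reps)) * (segments$end - segments$start)[reps])
  s <- pmax(pos - floor(read_length_bp / 2), 0)
  e <- pmin(s + read_length_bp, unclass(genome)[segments$chrom[reps]])
  data.frame(chrom = segments$chrom[reps], start = s, end = e,
             stringsAsFactors = FALSE)
}

planted_regions_for <- function(cfg, genes, truth, mark, condition) {
  prom <- anchored_regions(
    genes, region_spec("promoter", cfg$plant_promoter_bp,
                       cfg$plant_promoter_bp), drop_degenerate = FALSE)
  body <- genes[, c("chrom", "tx_start", "tx_end")]
  names(body) <- c("chrom", "start", "end")
  co <- truth$label == "up" & truth$co_regulated
  down <- truth$label == "down"
  out <- list()
  if (mark == "5hmC") {
    out$body <- data.frame(chrom = body$chrom, start = body$start,
                           end = body$end, fold = cfg$body_base_fold)
    if (condition == "KO") {
      if (any(co)) {
        # one contiguous promoter-plus-body span per co-regulated gene so the
        # planted fold applies once (the promoter window overlaps the body)
        out$co_span <- data.frame(
          chrom = body$chrom[co],
          start = pmin(body$start[co], prom$start[co]),
          end = pmax(body$end[co], prom$end[co]), fold = cfg$hmc_fold)
      }
      if (any(down))
        out$down_body <- data.frame(chrom = body$chrom[down],
                                    start = body$start[down],
                                    end = body$end[down],
                                    fold = cfg$down_hmc_fold)
    }
  } else if (mark == "TF") {
    out$prom <- data.frame(chrom = prom$chrom, start = prom$start,
                           end = prom$end, fold = cfg$tf_base_fold)
    if (condition == "KO" && any(co))
      out$co_prom <- data.frame(chrom = prom$chrom[co],
                                start = prom$start[co], end = prom$end[co],
                                fold = cfg$tf_fold)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), fold = numeric())
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic dataset
#'
#' Writes, under `out_dir`: `genes.tsv`, `genome.tsv`, tag BED files for
#' 5hmC and TF in WT and KO plus a non-enriched input track, truth-interval
#' peak BED files for the four enriched samples, a DE table `de.tsv` with
#' planted significance (up/down genes drawn below the 0.05 threshold, null
#' genes uniform), and `truth.json` recording the planted labels, folds and
#' seed. Deterministic given the seed: the same configuration always yields
#' byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (data frame of planted labels/folds per gene), `genes` and `genome`.
#' @export
simulate_dataset <- function(config, out_dir = tempfile("simdata")) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  genome <- genome_table(sprintf("chr%d", seq_len(cfg$n_chroms)),
                         rep(cfg$chrom_length_bp, cfg$n_chroms))
  genes <- place_genes(cfg)
  n <- nrow(genes)

  # planted labels: up / down / null, co-regulated flag among the up genes
  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  lab <- rep("null", n)
  picked <- sample(n, n_up + n_down)
  lab[picked[seq_len(n_up)]] <- "up"
  if (n_down > 0) lab[picked[n_up + seq_len(n_down)]] <- "down"
  co <- rep(FALSE, n)
  up_idx <- which(lab == "up")
  n_co <- round(cfg$frac_co * n_up)
  if (n_co > 0) co[sample(up_idx, n_co)] <- TRUE

  lfc <- numeric(n)
  lfc[lab == "up"] <- pmax(stats::rnorm(sum(lab == "up"),
                                        cfg$expr_lfc_mean_sd[1],
                                        cfg$expr_lfc_mean_sd[2]), 0.1)
  lfc[lab == "down"] <- -pmax(stats::rnorm(sum(lab == "down"),
                                           cfg$expr_lfc_mean_sd[1],
                                           cfg$expr_lfc_mean_sd[2]), 0.1)
  lfc[lab == "null"] <- stats::rnorm(sum(lab == "null"), 0, 0.1)
  truth <- data.frame(
    gene_id = genes$gene_id, label = lab, co_regulated = co,
    planted_log2fc = lfc,
    planted_hmc_fold = ifelse(co, cfg$hmc_fold,
                              ifelse(lab == "down", cfg$down_hmc_fold, 1)),
    planted_tf_fold = ifelse(co, cfg$tf_fold, 1),
    stringsAsFactors = FALSE
  )

  # DE table: planted genes significant by construction, null genes uniform
  expr_a <- stats::rlnorm(n, log(10), 1)
  expr_b <- expr_a * 2^lfc
  p <- ifelse(lab == "null", stats::runif(n),
              stats::runif(n, 0, 0.05))
  de <- de_table(genes$gene_id, expr_a, expr_b, lfc, p, bh_adjust(p))

  samples <- list(
    tags_5hmc_wt = list(mark = "5hmC", condition = "WT"),
    tags_5hmc_ko = list(mark = "5hmC", condition = "KO"),
    tags_tf_wt = list(mark = "TF", condition = "WT"),
    tags_tf_ko = list(mark = "TF", condition = "KO"),
    tags_input = list(mark = "input", condition = "WT")
  )
  paths <- list(
    genes = file.path(out_dir, "genes.tsv"),
    genome = file.path(out_dir, "genome.tsv"),
    de = file.path(out_dir, "de.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  for (nm in names(samples)) {
    sm <- samples[[nm]]
    planted <- if (sm$mark == "input")
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 fold = numeric())
    else planted_regions_for(cfg, genes, truth, sm$mark, sm$condition)
    seg <- intensity_segments(planted, genome, cfg$background_rate)
    tg <- draw_tags(seg, cfg$library_size, cfg$read_length_bp, genome)
    ts <- tag_set(tg$chrom, tg$start, tg$end, sample_label = nm,
                  mark = sm$mark, condition = sm$condition,
                  library_size = max(nrow(tg), 1))
    paths[[nm]] <- file.path(out_dir, paste0(nm, ".bed"))
    write_bed(ts, paths[[nm]])
    if (sm$mark != "input") {
      # truth peaks: intensity strictly above threshold x background
      thr <- cfg$peak_rate_threshold *
        max(cfg$background_rate, .Machine$double.eps)
      hot <- seg[seg$fold > thr, , drop = FALSE]
      pk_name <- sub("^tags", "peaks", nm)
      pk <- if (nrow(hot))
        merge_intervals(interval_set(hot$chrom, hot$start, hot$end),
                        sample_label = pk_name)
      else interval_set(sample_label = pk_name)
      paths[[pk_name]] <- file.path(out_dir, paste0(pk_name, ".bed"))
      write_bed(pk, paths[[pk_name]])
    }
  }

  write_gene_models(genes, paths$genes)
  writeLines(sprintf("%s\t%d", names(genome),
                     as.integer(unclass(genome))),
             paths$genome)
  utils::write.table(as.data.frame(de), paths$de, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  jsonlite::write_json(
    list(seed = cfg$seed,
         config = unclass(cfg)[setdiff(names(cfg), "gene_length_lognormal")],
         gene_length_lognormal = cfg$gene_length_lognormal,
         genes = truth),
    paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(list(paths = paths, truth = truth, genes = genes,
                 genome = genome, config = cfg))
}

#' Score pipeline recovery of planted co-regulated genes
#'
#' A gene counts as recovered iff it is classified `higher` in the
#' intragenic 5hmC comparison AND `higher` in the promoter TF comparison.
#' Sensitivity is recovered/planted co-regulated genes; precision is
#' recovered/predicted (undefined when nothing is predicted, reported as
#' `NA`).
#'
#' @param intragenic_cls [classify_ratio()] result for intragenic 5hmC
#'   (KO vs WT).
#' @param promoter_cls [classify_ratio()] result for promoter TF binding
#'   (KO vs WT); genes absent from it are treated as not recovered.
#' @param truth truth data frame from [simulate_dataset()].
#' @return A list with `sensitivity`, `precision`, `tp`, `fp`, `fn`,
#'   `n_planted`, `n_predicted`.
#' @export
evaluate_recovery <- function(intragenic_cls, promoter_cls, truth) {
  g5 <- intragenic_cls$per_gene
  gt <- promoter_cls$per_gene
  stray <- setdiff(c(g5$gene_id, gt$gene_id), truth$gene_id)
  if (length(stray))
    stop("gene universe mismatch: classified genes absent from truth: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  hi5 <- g5$gene_id[g5$class == "higher"]
  hit <- gt$gene_id[gt$class == "higher"]
  predicted <- intersect(hi5, hit)
  planted <- truth$gene_id[truth$label == "up" & truth$co_regulated]
  tp <- length(intersect(predicted, planted))
  fp <- length(setdiff(predicted, planted))
  fn <- length(setdiff(planted, predicted))
  list(
    sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
    precision = if (length(predicted)) tp / length(predicted) else NA_real_,
    tp = tp, fp = fp, fn = fn,
    n_planted = length(planted), n_predicted = length(predicted)
  )
}
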