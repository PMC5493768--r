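# End-to-end orchestration: read inputs, run every analysis stage in order,
# and emit a deterministic JSON report plus per-stage TSVs. The report is
# self-describing: every statistic carries its null, sidedness, window and
# region definition, and the effective configuration is echoed back.

#' Pipeline run configuration
#'
#' Paths to all inputs plus the analysis constants. The defaults are the
#' study's: a 500 bp proximity window, a 1 kb-each-side promoter for the
#' promoter-binding classification, a 500 bp-each-side promoter and a
#' TSS+500-to-TES gene body for the cohort matrices, 5 kb metagene flanks,
#' a strict p < 0.05 DE threshold, and a log2 pseudocount of 1 RPM.
#'
#' @param genes,genome,de paths to the gene-model TSV/BED6, chromosome-sizes
#'   TSV and DE table.
#' @param tags_5hmc_wt,tags_5hmc_ko,tags_tf_wt,tags_tf_ko,tags_input paths
#'   to tag BED files (`tags_input` optional, `NULL` to skip).
#' @param peaks_5hmc_wt,peaks_5hmc_ko,peaks_tf_wt,peaks_tf_ko paths to peak
#'   BED files.
#' @param window_bp proximity window (default 500).
#' @param promoter_bp promoter half-width for the TF-binding classification
#'   (default 1000).
#' @param matrix_promoter_bp promoter half-width for cohort matrices
#'   (default 500).
#' @param body_offset_bp gene-body TSS offset (default 500).
#' @param flank_bp metagene flank (default 5000).
#' @param flank_bin_bp metagene flank bin width (default 100).
#' @param n_body_bins metagene body bins (default 100).
#' @param alpha DE significance threshold (default 0.05).
#' @param de_criterion `"p"` or `"q"`.
#' @param pseudocount log2 pseudocount in RPM (default 1).
#' @param tie_epsilon RPM tie margin for classifications (default 0).
#' @param cohorts optional named list of gene-id character vectors for
#'   cohort matrices and Welch comparisons.
#' @param gene_sets_gmt optional GMT path for over-representation analysis.
#' @param out_dir output directory for the report and stage TSVs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genes, genome, de,
                       tags_5hmc_wt, tags_5hmc_ko, tags_tf_wt, tags_tf_ko,
                       peaks_5hmc_wt, peaks_5hmc_ko, peaks_tf_wt,
                       peaks_tf_ko, tags_input = NULL,
                       window_bp = 500, promoter_bp = 1000,
                       matrix_promoter_bp = 500, body_offset_bp = 500,
                       flank_bp = 5000, flank_bin_bp = 100,
                       n_body_bins = 100, alpha = 0.05,
                       de_criterion = "p", pseudocount = 1,
                       tie_epsilon = 0, cohorts = NULL,
                       gene_sets_gmt = NULL, out_dir = "hmcoloc_run") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; entries in `overrides` replace
#' file values (the command-line override path).
#'
#' @param path YAML file.
#' @param overrides named list of overriding values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: DE partition; metagene 5hmC profiles on the up- and
#' downregulated gene sets (WT, KO and input when supplied); intragenic
#' (TSS-TES) 5hmC ratio classification of the upregulated genes (KO vs WT);
#' promoter TF-binding classification on the genes with higher KO 5hmC;
#' peak proximity test of merged TF peaks against merged 5hmC peaks;
#' unique-peak counts per condition and overlap fractions; cohort log2-RPM
#' matrices with Welch comparisons (when cohorts are supplied); and
#' hypergeometric over-representation analysis (when gene sets are
#' supplied). Writes `report.json` and per-stage TSVs under
#' `config$out_dir`; the report contains no timestamps, so identical inputs
#' give bitwise-identical reports.
#'
#' @param config a [run_config()].
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  genes <- stage("read_genes", read_gene_models(cfg$genes))
  genome <- stage("read_genome", read_genome_table(cfg$genome))
  de <- stage("read_de", read_de_table(cfg$de))
  tags <- list(
    hmc_wt = stage("read_tags", read_bed(cfg$tags_5hmc_wt, "tags",
                                         mark = "5hmC", condition = "WT")),
    hmc_ko = stage("read_tags", read_bed(cfg$tags_5hmc_ko, "tags",
                                         mark = "5hmC", condition = "KO")),
    tf_wt = stage("read_tags", read_bed(cfg$tags_tf_wt, "tags",
                                        mark = "TF", condition = "WT")),
    tf_ko = stage("read_tags", read_bed(cfg$tags_tf_ko, "tags",
                                        mark = "TF", condition = "KO"))
  )
  if (!is.null(cfg$tags_input))
    tags$input <- stage("read_tags", read_bed(cfg$tags_input, "tags",
                                              mark = "input"))
  peaks <- list(
    hmc_wt = stage("read_peaks", read_bed(cfg$peaks_5hmc_wt, "peaks")),
    hmc_ko = stage("read_peaks", read_bed(cfg$peaks_5hmc_ko, "peaks")),
    tf_wt = stage("read_peaks", read_bed(cfg$peaks_tf_wt, "peaks")),
    tf_ko = stage("read_peaks", read_bed(cfg$peaks_tf_ko, "peaks"))
  )

  # 1. DE partition
  parts <- stage("de_partition",
                 de_partition(de, cfg$alpha, cfg$de_criterion))
  up_genes <- genes[genes$gene_id %in% parts$up, , drop = FALSE]
  down_genes <- genes[genes$gene_id %in% parts$down, , drop = FALSE]

  # 2. metagene profiles of 5hmC over up / down gene sets
  metagene <- list()
  for (set_nm in c("up", "down")) {
    gset <- if (set_nm == "up") up_genes else down_genes
    if (nrow(gset) == 0L) next
    for (tr in intersect(c("hmc_wt", "hmc_ko", "input"), names(tags))) {
      prof <- stage("metagene", metagene_profile(
        tags[[tr]], gset, cfg$flank_bp, cfg$flank_bin_bp, cfg$n_body_bins))
      key <- paste0(set_nm, "_", tr)
      metagene[[key]] <- prof
      utils::write.table(
        as.data.frame(prof),
        file.path(cfg$out_dir, paste0("metagene_", key, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    }
  }

  # 3. intragenic (TSS-TES) 5hmC classification on upregulated genes
  whole <- region_spec("whole_gene")
  cls_5hmc <- stage("classify_intragenic_5hmc", classify_ratio(
    gene_density_table(tags$hmc_wt, up_genes, whole, genome),
    gene_density_table(tags$hmc_ko, up_genes, whole, genome),
    cfg$tie_epsilon))
  utils::write.table(
    cls_5hmc$per_gene, file.path(cfg$out_dir, "intragenic_5hmc_classes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")

  # 4. promoter TF-binding classification on the higher-5hmC subset
  higher_ids <- cls_5hmc$per_gene$gene_id[cls_5hmc$per_gene$class == "higher"]
  higher_genes <- genes[genes$gene_id %in% higher_ids, , drop = FALSE]
  prom <- region_spec("promoter", cfg$promoter_bp, cfg$promoter_bp)
  cls_tf <- if (nrow(higher_genes) > 0L)
    stage("classify_promoter_tf", classify_ratio(
      gene_density_table(tags$tf_wt, higher_genes, prom, genome),
      gene_density_table(tags$tf_ko, higher_genes, prom, genome),
      cfg$tie_epsilon))
  else NULL
  if (!is.null(cls_tf))
    utils::write.table(
      cls_tf$per_gene, file.path(cfg$out_dir, "promoter_tf_classes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")

  # 5. proximity of merged TF peaks to merged 5hmC peaks
  tf_merged <- stage("merge_peaks",
                     merge_intervals(peaks$tf_wt, peaks$tf_ko,
                                     sample_label = "TF_merged"))
  hmc_merged <- stage("merge_peaks",
                      merge_intervals(peaks$hmc_wt, peaks$hmc_ko,
                                      sample_label = "5hmC_merged"))
  prox <- stage("proximity_test",
                proximity_test(tf_merged, hmc_merged, cfg$window_bp, genome))

  # 6. unique peaks per condition and overlap fractions
  unique_wt <- subtract_overlapping(peaks$hmc_wt, peaks$hmc_ko)
  unique_ko <- subtract_overlapping(peaks$hmc_ko, peaks$hmc_wt)
  peak_summary <- list(
    n_5hmc_wt = nrow(peaks$hmc_wt), n_5hmc_ko = nrow(peaks$hmc_ko),
    n_unique_5hmc_wt = nrow(unique_wt), n_unique_5hmc_ko = nrow(unique_ko),
    pct_fewer_unique_ko = if (nrow(unique_wt) > 0)
      fraction_summary(max(nrow(unique_wt) - nrow(unique_ko), 0),
                       nrow(unique_wt), 1) else NA,
    tf_overlap_fraction_with_5hmc =
      if (nrow(tf_merged) > 0) overlap_fraction(tf_merged, hmc_merged)
      else NA
  )

  # 7. cohort matrices and Welch comparisons
  cohort_results <- list()
  if (!is.null(cfg$cohorts)) {
    samples <- list(TF_WT = tags$tf_wt, TF_KO = tags$tf_ko,
                    hmC_WT = tags$hmc_wt, hmC_KO = tags$hmc_ko)
    for (co_nm in names(cfg$cohorts)) {
      gset <- genes[genes$gene_id %in% cfg$cohorts[[co_nm]], , drop = FALSE]
      if (nrow(gset) < 2L) next
      m <- stage("region_matrix", region_matrix(
        gset, samples,
        promoter = region_spec("promoter", cfg$matrix_promoter_bp,
                               cfg$matrix_promoter_bp),
        body = region_spec("gene_body", downstream_bp = cfg$body_offset_bp),
        pseudocount = cfg$pseudocount, genome = genome))
      utils::write.table(
        data.frame(gene_id = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE),
        file.path(cfg$out_dir, paste0("matrix_", co_nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
      cmp <- list(
        tf_promoter = cohort_compare(m, "TF_WT:promoter", "TF_KO:promoter"),
        hmc_promoter = cohort_compare(m, "hmC_WT:promoter",
                                      "hmC_KO:promoter"),
        tf_body = cohort_compare(m, "TF_WT:gene_body", "TF_KO:gene_body"),
        hmc_body = cohort_compare(m, "hmC_WT:gene_body", "hmC_KO:gene_body")
      )
      cohort_results[[co_nm]] <- list(
        n_genes = nrow(m),
        column_means = as.list(attr(m, "column_means")),
        welch = lapply(cmp, function(x)
          list(mean_a = x$mean_a, mean_b = x$mean_b, t = x$t, p = x$p))
      )
    }
  }

  # 8. over-representation analysis
  ora <- NULL
  if (!is.null(cfg$gene_sets_gmt) && length(higher_ids) > 0) {
    sets <- stage("read_gmt", read_gmt(cfg$gene_sets_gmt))
    ora <- stage("ora", ora_hypergeometric(
      intersect(higher_ids, genes$gene_id), sets, genes$gene_id))
    utils::write.table(as.data.frame(ora),
                       file.path(cfg$out_dir, "ora.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
  }

  report <- list(
    config = config_echo(cfg),
    de = list(alpha = cfg$alpha, criterion = cfg$de_criterion,
              threshold_rule = "strictly below alpha",
              n_up = length(parts$up), n_down = length(parts$down)),
    metagene = lapply(metagene, function(p) list(
      n_genes = p$n_genes,
      mean_upstream = mean(p$upstream), mean_body = mean(p$body),
      mean_downstream = mean(p$downstream))),
    intragenic_5hmc = classification_report(
      cls_5hmc, "intragenic 5hmC (TSS-TES), KO vs WT",
      "two-sided exact binomial vs p0 = 0.5, ties excluded"),
    promoter_tf = if (!is.null(cls_tf)) classification_report(
      cls_tf, sprintf("promoter (%d bp each side of TSS) TF binding, KO vs WT on higher-5hmC genes",
                      cfg$promoter_bp),
      "two-sided exact binomial vs p0 = 0.5, ties excluded"),
    proximity = list(
      description = sprintf(
        "merged TF peaks within %d bp (edge-to-edge, inclusive) of merged 5hmC peaks",
        cfg$window_bp),
      null = "one-sided (greater) exact binomial; p0 = genome fraction within window of subject peaks",
      k = prox$k, n = prox$n,
      pct = fraction_summary(prox$k, prox$n, 1),
      p0 = prox$p0, binom_p = prox$binom_p),
    peaks = peak_summary,
    cohorts = if (length(cohort_results)) cohort_results,
    ora = if (!is.null(ora)) list(
      n_sets = nrow(ora),
      top = as.list(ora[which.min(ora$p), c("set_name", "overlap", "p", "q")])
    )
  )
  report <- report[!vapply(report, is.null, TRUE)]
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

classification_report <- function(cls, description, null_description) {
  list(description = description, null = null_description,
       k_higher = cls$k_higher, n_informative = cls$n_informative,
       n_ties = cls$n_ties,
       pct_higher = if (cls$n_informative > 0)
         fraction_summary(cls$k_higher, cls$n_informative, 1) else NA,
       binom_p = cls$binom_p)
}

config_echo <- function(cfg) {
  # out_dir is an output location, not an analytic input; keeping it out
  # of the echo makes reports bitwise-comparable across runs
  keep <- setdiff(names(cfg), c("cohorts", "out_dir"))
  out <- unclass(cfg)[keep]
  out$cohort_names <- names(cfg$cohorts)
  out[!vapply(out, is.null, TRUE)]
}
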