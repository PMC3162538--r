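#' Run the full SSR analysis pipeline
#'
#' Orchestrates the analysis chain: sequence input (a FASTA file or a
#' synthetic preset), SSR detection, compound grouping, ORF prediction, SSR
#' placement classification, and the landscape reports (repeat-type table,
#' motif goodness-of-fit, placement goodness-of-fit). All outputs are
#' plain-text TSV/GFF3; the resolved configuration is written alongside
#' them, so a run is reproducible from its output directory alone.
#'
#' @param config A list: either `fasta` (input path) or `sim_spec` (a
#'   [sequence_sim_spec()]); `out_dir` (created if needed); optional
#'   `dataset` label, `cfg` ([ssr_search_config()]), `min_orf_len`,
#'   `strands`, `start_rule`. Unknown keys are rejected.
#' @return Invisibly, a list with the computed objects (`summary`, `ssrs`,
#'   `compound`, `orfs`, `placements`, `repeat_table`, `motif_gof`,
#'   `placement_table`) and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  known <- c("fasta", "sim_spec", "out_dir", "dataset", "cfg",
             "min_orf_len", "strands", "start_rule")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$fasta) == is.null(config$sim_spec))
    stop("exactly one of config$fasta or config$sim_spec is required")
  cfg <- if (is.null(config$cfg)) ssr_search_config() else config$cfg
  stopifnot(inherits(cfg, "ssr_search_config"))
  min_orf_len <- if (is.null(config$min_orf_len)) 100L else
    as.integer(config$min_orf_len)
  strands <- if (is.null(config$strands)) "both" else config$strands
  start_rule <- if (is.null(config$start_rule)) "longest" else
    config$start_rule
  dataset <- if (is.null(config$dataset)) "dataset" else config$dataset

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(config$fasta)) {
    records <- read_fasta(config$fasta, dataset = dataset)
  } else {
    sim <- gen_sequences(config$sim_spec)
    records <- sim$records
    truth <- sim[c("ssr_truth", "orf_truth")]
    if (is.null(config$dataset)) dataset <- "synthetic"
  }

  summary <- summarize_dataset(records, dataset = dataset)
  ssrs_all <- detect_perfect_ssrs(records, cfg)
  grouped <- group_compound_ssrs(ssrs_all, cfg)
  orfs <- find_orfs(records, min_orf_len = min_orf_len, strands = strands,
                    start_rule = start_rule)
  placements <- classify_placement(ssrs_all, orfs)
  ofrac <- orf_fraction(orfs, summary$total_bp)
  rtab <- repeat_type_table(grouped$perfect, grouped$compound, summary,
                            unit_len_range =
                              seq(cfg$unit_len_range[1L],
                                  cfg$unit_len_range[2L]))
  motif_gof <- lapply(c(2L, 3L), function(k) {
    obs <- table(ssrs_all$motif_class[ssrs_all$unit_len == k])
    if (sum(obs) == 0L) return(NULL)
    probs <- expected_motif_probs(summary, k)
    chisq_gof(stats::setNames(as.numeric(obs), names(obs)), probs,
              label = paste0(dataset, " k=", k))
  })
  motif_gof <- motif_gof[!vapply(motif_gof, is.null, logical(1))]
  ptab <- if (ofrac > 0 && ofrac < 1)
    placement_gof(placements, ofrac,
                  unit_len_range = seq(cfg$unit_len_range[1L],
                                       cfg$unit_len_range[2L])) else NULL

  paths <- list(
    summary = file.path(config$out_dir, "dataset_summary.tsv"),
    ssr = file.path(config$out_dir, "ssr_loci.tsv"),
    gff3 = file.path(config$out_dir, "features.gff3"),
    repeat_table = file.path(config$out_dir, "repeat_type_table.tsv"),
    placement = file.path(config$out_dir, "placement.tsv"),
    motif_gof = file.path(config$out_dir, "motif_gof.tsv"),
    config = file.path(config$out_dir, "run_config.txt")
  )
  write_dataset_summary_tsv(summary, paths$summary)
  write_ssr_tsv(rbind(grouped$perfect,
                      grouped$compound[, names(grouped$perfect),
                                       drop = FALSE]),
                paths$ssr)
  write_features_gff3(ssrs_all, orfs, paths$gff3, seqs = records)
  utils::write.table(rtab, paths$repeat_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pl_out <- placements
  pl_out$start <- pl_out$start + 1L
  utils::write.table(pl_out[, c("seq_id", "start", "end", "motif_class",
                                "unit_len", "status")],
                     paths$placement, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gof_df <- do.call(rbind, lapply(motif_gof, function(g)
    data.frame(label = g$label, chi2 = g$chi2, df = g$df,
               p = format_pvalue(g$p), stringsAsFactors = FALSE)))
  if (is.null(gof_df))
    gof_df <- data.frame(label = character(), chi2 = numeric(),
                         df = integer(), p = character(),
                         stringsAsFactors = FALSE)
  utils::write.table(gof_df, paths$motif_gof, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  resolved <- c(
    dataset = dataset,
    input = if (!is.null(config$fasta)) config$fasta else
      paste0("sim_spec(seed=", config$sim_spec$seed, ")"),
    min_total_len = cfg$min_total_len, min_units = cfg$min_units,
    k_min = cfg$unit_len_range[1L], k_max = cfg$unit_len_range[2L],
    d_max = cfg$d_max, min_orf_len = min_orf_len, strands = strands,
    start_rule = start_rule)
  writeLines(paste(names(resolved), resolved, sep = "="), paths$config)

  invisible(list(summary = summary, ssrs = grouped$perfect,
                 compound = grouped$compound, orfs = orfs,
                 placements = placements, orf_fraction = ofrac,
                 repeat_table = rtab, motif_gof = motif_gof,
                 placement_table = ptab, truth = truth, paths = paths))
}
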