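# End-to-end synthetic study: simulate every modality, run each analysis
# stage, and write plain-text artifacts plus a machine-readable summary.

#' Default pipeline configuration
#'
#' Returns the resolved configuration for [run_pipeline()]. Any provided
#' element must match a known key (unknown keys are rejected), and
#' module-level settings are nested lists passed to the corresponding
#' simulator configurations.
#'
#' @param seed Master seed; each stage derives its own stream from it.
#' @param stages Named logical toggles: `trend`, `trajectory`, `calcium`,
#'   `chromatin`, `enrich`.
#' @param expression,calcium,chromatin,motifs Named lists overriding
#'   simulator defaults (see [sim_expr_config()], [sim_calcium_config()],
#'   [sim_chromatin_config()], [simulate_motif_annotation()]).
#' @param fdr_threshold Differential-significance threshold used by the
#'   trend and chromatin stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = list(),
                            expression = list(),
                            calcium = list(),
                            chromatin = list(),
                            motifs = list(),
                            fdr_threshold = 0.05) {
  default_stages <- list(trend = TRUE, trajectory = TRUE, calcium = TRUE,
                         chromatin = TRUE, enrich = TRUE)
  default_motifs <- list(n_motifs = 50, n_planted = 5,
                         enrichment_factor = 2.5, background_rate = 0.2,
                         frac_tf_expressed = 0.8)
  merge_known <- function(defaults, given, what) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown) > 0) {
      stop(sprintf("unknown %s key(s): %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(defaults, given)
  }
  sim_args <- function(fn) formals(fn)[setdiff(names(formals(fn)), "seed")]
  check_known <- function(given, fn, what) {
    unknown <- setdiff(names(given), names(formals(fn)))
    if (length(unknown) > 0) {
      stop(sprintf("unknown %s key(s): %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    given
  }
  structure(list(
    seed = as.integer(seed),
    stages = merge_known(default_stages, stages, "stage"),
    expression = check_known(expression, sim_expr_config, "expression"),
    calcium = check_known(calcium, sim_calcium_config, "calcium"),
    chromatin = check_known(chromatin, sim_chromatin_config, "chromatin"),
    motifs = merge_known(default_motifs, motifs, "motif"),
    fdr_threshold = fdr_threshold
  ), class = "pipeline_config")
}

#' Run the full synthetic maturation study
#'
#' Simulates an expression time course, calcium recordings, a chromatin
#' landscape and a motif annotation, runs every enabled analysis stage,
#' writes the standard plain-text artifacts into `outdir`, and returns
#' (and writes) a summary holding the headline quantities of each stage
#' together with recovery metrics against the planted truth. With a fixed
#' seed the summary is byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The summary list, invisibly. Artifacts written: simulated
#'   inputs (TSV/CSV/BED/JSON), per-stage result tables, `summary.json`,
#'   and the resolved `config.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  summary <- list(seed = seed)
  stage_on <- config$stages
  t_start <- proc.time()[["elapsed"]]
  note <- function(stage, t0) {
    message(sprintf("[%s] done in %.1f s", stage,
                    proc.time()[["elapsed"]] - t0))
  }

  ## --- simulate -----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  expr_cfg <- do.call(sim_expr_config,
                      c(config$expression, list(seed = seed)))
  expr_sim <- simulate_expression_timecourse(expr_cfg)
  tc <- expr_sim$timecourse
  write_matrix_tsv(tc$counts, file.path(outdir, "counts.tsv"), "gene")
  utils::write.table(tc$samples, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(tc$gene_lengths), length = tc$gene_lengths),
    file.path(outdir, "gene_lengths.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  cal_cfg <- do.call(sim_calcium_config,
                     c(config$calcium, list(seed = seed + 1L)))
  cal_sim <- simulate_calcium_traces(cal_cfg)
  write_traces_csv(cal_sim$traces, file.path(outdir, "traces.csv"))

  chr_cfg <- do.call(sim_chromatin_config,
                     c(config$chromatin, list(seed = seed + 2L)))
  chr_sim <- simulate_chromatin_landscape(chr_cfg)
  write_peaks(chr_sim$atlas, file.path(outdir, "atlas.bed"))
  write_matrix_tsv(chr_sim$counts, file.path(outdir, "peak_counts.tsv"),
                   "peak_id")

  truth_states <- chr_sim$truth$peak_states
  biv_peaks <- names(truth_states)[truth_states == "bivalent_resolving"]
  gain_peaks <- names(truth_states)[truth_states == "active_gaining"]
  motifs_cfg <- config$motifs
  planted_motifs <- list(
    bivalent_resolving = sprintf("M%03d", seq_len(motifs_cfg$n_planted)))
  mot_sim <- simulate_motif_annotation(
    chr_sim$atlas, n_motifs = motifs_cfg$n_motifs,
    groups = list(bivalent_resolving = biv_peaks,
                  active_gaining = gain_peaks),
    planted = planted_motifs,
    enrichment_factor = motifs_cfg$enrichment_factor,
    background_rate = motifs_cfg$background_rate,
    seed = seed + 3L)
  utils::write.table(mot_sim$annotation$peaks,
                     file.path(outdir, "motif_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    gene_trend_labels = as.list(expr_sim$truth$gene_trend_labels),
    sync_event_times = cal_sim$truth$sync_event_times,
    peak_states = as.list(truth_states),
    enriched_motifs = mot_sim$truth$enriched_motifs)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  note("simulate", t0)

  rpkm <- compute_rpkm(tc)
  meta <- tc$samples

  ## --- trend --------------------------------------------------------
  if (isTRUE(stage_on$trend)) {
    t0 <- proc.time()[["elapsed"]]
    present <- presence_filter(rpkm)
    de <- stage_contrasts(tc, treatment = meta$treatment[1],
                          genes = present)
    labels <- trend_labels(de, fdr_threshold = config$fdr_threshold)
    utils::write.table(labels, file.path(outdir, "trend_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth_lab <- expr_sim$truth$gene_trend_labels
    called_up <- labels$gene[grepl("^mono_up", labels$label)]
    called_down <- labels$gene[grepl("^mono_down", labels$label)]
    truth_up <- names(truth_lab)[truth_lab == "mono_up"]
    truth_down <- names(truth_lab)[truth_lab == "mono_down"]
    n_true_called <- length(intersect(called_up, truth_up)) +
      length(intersect(called_down, truth_down))
    n_called <- length(called_up) + length(called_down)
    summary$trend <- list(
      n_present = length(present),
      n_mono_up = length(called_up),
      n_mono_down = length(called_down),
      recall = n_true_called / max(1, length(truth_up) + length(truth_down)),
      fdr_empirical = if (n_called > 0) 1 - n_true_called / n_called else 0)
    note("trend", t0)
  }

  ## --- trajectory ---------------------------------------------------
  if (isTRUE(stage_on$trajectory)) {
    t0 <- proc.time()[["elapsed"]]
    vst <- variance_stabilize(tc$counts)$vst
    emb <- embed_pca(vst, top_n = 1000)
    cents <- condition_centroids(emb, meta)
    tr <- meta$treatment[1]
    scores <- maturation_score(cents, origin = paste0(tr, ".d25"),
                               control = paste0(tr, ".d50"))
    utils::write.table(scores, file.path(outdir, "maturation_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hc <- correlation_cluster(vst)
    write_dendrogram_newick(hc, file.path(outdir, "sample_dendrogram.nwk"))
    ctrl_row <- scores[scores$condition == paste0(tr, ".d50"), ]
    ord <- paste0(tr, ".", c("d25", "d50", "d75", "d100"))
    summary$trajectory <- list(
      explained_variance_pc1 = round(emb$explained_variance[1], 6),
      control_score = round(ctrl_row$score, 6),
      scores = stats::setNames(as.list(round(
        scores$score[match(ord, scores$condition)], 6)), ord))
    note("trajectory", t0)
  }

  ## --- calcium ------------------------------------------------------
  if (isTRUE(stage_on$calcium)) {
    t0 <- proc.time()[["elapsed"]]
    dff <- compute_dff(cal_sim$traces)
    spikes <- detect_spikes(dff, cal_sim$traces$frame_rate_hz)
    st <- spike_statistics(spikes)
    utils::write.table(st, file.path(outdir, "spike_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sync <- synchronous_firing_rate(spikes)
    jsonlite::write_json(
      list(sync_event_times = sync$sync_event_times,
           rate_per_min = sync$rate_per_min,
           participation_threshold = sync$participation_threshold,
           window_s = sync$window_s),
      file.path(outdir, "synchrony.json"), auto_unbox = TRUE, digits = NA)
    summary$calcium <- list(
      n_rois = nrow(dff),
      mean_amplitude = round(mean(st$amplitude, na.rm = TRUE), 6),
      mean_frequency_per_min = round(mean(st$frequency_per_min), 6),
      sync_rate_per_min = round(sync$rate_per_min, 6),
      n_sync_events = sync$n_events,
      n_sync_events_truth = length(cal_sim$truth$sync_event_times))
    note("calcium", t0)
  }

  ## --- chromatin ----------------------------------------------------
  if (isTRUE(stage_on$chromatin)) {
    t0 <- proc.time()[["elapsed"]]
    signal <- normalize_depth(chr_sim$counts,
                              totals = chr_sim$library_sizes)
    states <- call_chromatin_states(signal, chr_sim$sample_info,
                                    stages = chr_cfg$stages)
    utils::write.table(
      data.frame(peak_id = names(states$transition),
                 state = states$transition),
      file.path(outdir, "state_calls.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    recov <- mean(states$transition[biv_peaks] == "bivalent_resolving")
    summary$chromatin <- list(
      n_peaks = nrow(chr_sim$atlas),
      state_counts = as.list(table(states$transition)),
      bivalent_recovery = round(recov, 6))

    # intersect chromatin clusters with the expression time series
    gene_models <- simulate_gene_models(
      chr_sim$atlas, truth_states, expr_sim$truth$gene_trend_labels,
      seed = seed + 4L)
    annot <- annotate_peaks_to_genes(chr_sim$atlas, gene_models)
    utils::write.table(annot, file.path(outdir, "peak_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    called_biv <- names(states$transition)[
      states$transition == "bivalent_resolving"]
    if (isTRUE(stage_on$trend) && length(called_biv) > 0) {
      gene_of <- stats::setNames(annot$gene_id, annot$peak_id)
      biv_genes <- unique(stats::na.omit(gene_of[called_biv]))
      truth_lab <- expr_sim$truth$gene_trend_labels
      truth_up <- names(truth_lab)[truth_lab == "mono_up"]
      modelled <- unique(gene_models$gene_id)
      k <- length(intersect(biv_genes, truth_up))
      p_assoc <- stats::phyper(k - 1,
                               length(intersect(truth_up, modelled)),
                               length(modelled) -
                                 length(intersect(truth_up, modelled)),
                               length(biv_genes), lower.tail = FALSE)
      summary$chromatin$bivalent_monoup_hypergeom_p <- p_assoc
    }
    note("chromatin", t0)
  }

  ## --- enrich -------------------------------------------------------
  if (isTRUE(stage_on$enrich)) {
    t0 <- proc.time()[["elapsed"]]
    res <- motif_enrichment(biv_peaks, chr_sim$atlas$peak_id,
                            mot_sim$annotation,
                            group_label = "bivalent_resolving")
    # synthetic factor expression: planted-motif factors expressed, a
    # fixed fraction of the rest silenced, so the RPKM filter is active
    motif_tf <- mot_sim$annotation$motif_tf
    tf_rpkm <- with_seed(seed + 5L, {
      m <- matrix(stats::runif(nrow(motif_tf) * 4, 2, 20),
                  ncol = 4,
                  dimnames = list(motif_tf$tf_gene,
                                  c("d25", "d50", "d75", "d100")))
      silent <- stats::runif(nrow(m)) > config$motifs$frac_tf_expressed
      planted_tf <- motif_tf$tf_gene[
        motif_tf$motif_id %in% unlist(planted_motifs)]
      silent[rownames(m) %in% planted_tf] <- FALSE
      m[silent, ] <- 0.1
      m
    })
    filt <- filter_enriched_motifs(res, motif_tf, tf_rpkm)
    res$pass_filter <- res$motif_id %in% filt$motif_id
    utils::write.table(res, file.path(outdir, "motif_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    planted <- planted_motifs$bivalent_resolving
    summary$enrich <- list(
      n_motifs_tested = nrow(res),
      n_pass_filter = nrow(filt),
      planted_recall = round(
        length(intersect(filt$motif_id, planted)) / length(planted), 6),
      top_odds_ratio = if (nrow(filt) > 0) round(filt$odds_ratio[1], 6)
                       else NA)
    note("enrich", t0)
  }

  jsonlite::write_json(config_as_list(config),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("pipeline finished in %.1f s",
                  proc.time()[["elapsed"]] - t_start))
  invisible(summary)
}

config_as_list <- function(config) {
  lapply(unclass(config), function(x) {
    if (is.list(x)) lapply(x, function(y) if (is.language(y)) deparse(y) else y)
    else x
  })
}
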