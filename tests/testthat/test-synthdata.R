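# Simulator correctness: determinism, planted structure, moment checks,
# and structural consistency of the emitted truth.

test_that("expression simulator is reproducible and plants exact fractions", {
  cfg <- sim_expr_config(n_genes = 1000, frac_mono_up = 0.1, seed = 7)
  a <- simulate_expression_timecourse(cfg)
  b <- simulate_expression_timecourse(cfg)
  expect_identical(a$timecourse$counts, b$timecourse$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$gene_trend_labels == "mono_up"), 100)
  expect_equal(sum(a$truth$gene_trend_labels == "mono_down"), 100)
  # every truth label names a simulated gene
  expect_setequal(names(a$truth$gene_trend_labels),
                  rownames(a$timecourse$counts))
  # every sample column has metadata
  expect_setequal(colnames(a$timecourse$counts),
                  a$timecourse$samples$sample)
})

test_that("zero planted effect leaves all genes at a flat mean", {
  cfg <- sim_expr_config(n_genes = 300, effect_log2fc = 0, dispersion = 0.01,
                         n_replicates = 10, seed = 3)
  sim <- simulate_expression_timecourse(cfg)
  tc <- sim$timecourse
  up <- names(sim$truth$gene_trend_labels)[
    sim$truth$gene_trend_labels == "mono_up"]
  m <- tc$samples
  mean_at <- function(tp) {
    rowMeans(tc$counts[up, m$sample[m$timepoint == tp], drop = FALSE])
  }
  # planted genes indistinguishable across the trend window
  expect_equal(mean(mean_at("d100")) / mean(mean_at("d25")), 1,
               tolerance = 0.05)
})

test_that("small dispersion approaches the Poisson limit (variance ~ mean)", {
  cfg <- sim_expr_config(n_genes = 2000, frac_mono_up = 0, frac_mono_down = 0,
                         dispersion = 1e-6, base_mean_log2 = 6,
                         n_replicates = 1, treatments = "DMSO", seed = 5)
  sim <- simulate_expression_timecourse(cfg)
  x <- as.vector(sim$timecourse$counts)  # iid across genes/samples at mu=64
  mu <- 2^6
  # variance/mean ratio ~ 1 within Monte-Carlo error
  expect_equal(stats::var(x) / mean(x), 1, tolerance = 0.08)
  expect_equal(mean(x), mu, tolerance = mu * 0.02)
})

test_that("expression config rejects invalid fields by name", {
  expect_error(sim_expr_config(frac_mono_up = 0.7, frac_mono_down = 0.5),
               "frac_mono_up")
  expect_error(sim_expr_config(dispersion = 0), "dispersion")
  expect_error(sim_expr_config(n_genes = 0), "n_genes")
})

test_that("calcium simulator: degenerate all-network construction", {
  cfg <- sim_calcium_config(n_rois = 5, duration_s = 60, noise_sd = 0,
                            cell_rate_per_min = 0, sync_rate_per_min = 2,
                            sync_participation = 1, seed = 9)
  sim <- simulate_calcium_traces(cfg)
  for (roi in names(sim$truth$spike_times)) {
    expect_identical(sim$truth$spike_times[[roi]],
                     sim$truth$sync_event_times)
  }
})

test_that("calcium simulator: private events recover the Poisson rate", {
  cfg <- sim_calcium_config(n_rois = 60, duration_s = 300,
                            cell_rate_per_min = 3, sync_rate_per_min = 0,
                            min_separation_s = 0, seed = 21)
  sim <- simulate_calcium_traces(cfg)
  rate <- mean(lengths(sim$truth$spike_times)) / (300 / 60)
  se <- sqrt(3 / (60 * 5))   # Poisson rate s.e. over 60 ROIs x 5 min
  expect_lt(abs(rate - 3), 4 * se)
})

test_that("calcium simulator is reproducible and truth is in-range", {
  cfg <- sim_calcium_config(n_rois = 4, duration_s = 30, seed = 11)
  a <- simulate_calcium_traces(cfg)
  b <- simulate_calcium_traces(cfg)
  expect_identical(a$traces$F, b$traces$F)
  expect_identical(a$truth, b$truth)
  for (tt in a$truth$spike_times) {
    expect_true(all(tt >= 0 & tt <= 30))
  }
})

test_that("chromatin simulator assigns exact state counts and atlas gaps", {
  cfg <- sim_chromatin_config(n_peaks = 200,
                              state_fractions = c(bivalent_resolving = 0.25,
                                                  active_gaining = 0.25,
                                                  immature_open = 0.25,
                                                  stable = 0.25),
                              seed = 3)
  sim <- simulate_chromatin_landscape(cfg)
  expect_equal(sum(sim$truth$peak_states == "bivalent_resolving"), 50)
  expect_setequal(names(sim$truth$peak_states), sim$atlas$peak_id)
  # pairwise same-chromosome gaps strictly exceed the 500 bp merge window
  by_chrom <- split(sim$atlas, sim$atlas$chrom)
  for (df in by_chrom) {
    if (nrow(df) < 2) next
    gaps <- df$start[-1] - df$end[-nrow(df)]
    expect_true(all(gaps > 500))
  }
})

test_that("all-stable landscape yields no differential peaks", {
  cfg <- sim_chromatin_config(n_peaks = 300,
                              state_fractions = c(bivalent_resolving = 0,
                                                  active_gaining = 0,
                                                  immature_open = 0,
                                                  stable = 1),
                              n_replicates = 3, seed = 8)
  sim <- simulate_chromatin_landscape(cfg)
  si <- sim$sample_info
  # contrast NPC vs neuron within one mark using the stand-in test
  signal <- normalize_depth(sim$counts, totals = sim$library_sizes)
  de <- naive_differential_signal(
    signal,
    si$sample[si$mark == "H3K4me3" & si$stage == "NPC"],
    si$sample[si$mark == "H3K4me3" & si$stage == "neuron"])
  expect_equal(sum(de$fdr <= 0.05), 0)
})

test_that("motif simulator: forced rates give the expected odds ratio", {
  atlas <- build_peak_atlas(data.frame(
    chrom = "chr1", start = seq(0, by = 2000, length.out = 2000),
    end = seq(500, by = 2000, length.out = 2000)))
  grp <- atlas$peak_id[1:50]
  sim <- simulate_motif_annotation(atlas, n_motifs = 5,
                                   groups = list(g = grp),
                                   planted = list(g = "M001"),
                                   enrichment_factor = 5,
                                   background_rate = 0.2, seed = 13)
  res <- motif_enrichment(grp, atlas$peak_id, sim$annotation)
  # in-group rate forced to 1.0, background ~0.2 (the 50 group peaks
  # raise the atlas-wide rate slightly) -> odds ratio ~ 5
  expect_equal(res$foreground_ratio[res$motif_id == "M001"], 1.0)
  expect_equal(res$odds_ratio[res$motif_id == "M001"], 5, tolerance = 0.2)
  expect_error(
    simulate_motif_annotation(atlas, 5, list(g = grp), list(g = "M001"),
                              enrichment_factor = 1),
    "enrichment_factor")
})

test_that("gene models co-locate planted chromatin states with trends", {
  chr <- simulate_chromatin_landscape(sim_chromatin_config(n_peaks = 200,
                                                           seed = 2))
  expr <- simulate_expression_timecourse(sim_expr_config(n_genes = 500,
                                                         seed = 2))
  gm <- simulate_gene_models(chr$atlas, chr$truth$peak_states,
                             expr$truth$gene_trend_labels, seed = 2)
  expect_false(anyDuplicated(gm$gene_id) > 0)
  ann <- annotate_peaks_to_genes(chr$atlas, gm)
  biv <- names(chr$truth$peak_states)[
    chr$truth$peak_states == "bivalent_resolving"]
  genes_of_biv <- ann$gene_id[match(biv, ann$peak_id)]
  lab <- expr$truth$gene_trend_labels[stats::na.omit(genes_of_biv)]
  expect_true(mean(lab == "mono_up") > 0.9)
})
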