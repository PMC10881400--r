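# Peak atlas construction, depth normalization, differential-peak
# clustering, peak-to-gene annotation (vs all-pairs oracle), state calls
# and the expression intersection.

test_that("atlas merging follows the 500 bp rule with blacklist removal", {
  peaks <- data.frame(chrom = "chr1", start = c(100, 600, 2000),
                      end = c(200, 700, 2100))
  atlas <- build_peak_atlas(peaks)
  # gap 400 <= 500 merges; gap 1300 stays separate
  expect_equal(nrow(atlas), 2)
  expect_equal(atlas$start[1], 100)
  expect_equal(atlas$end[1], 700)
  atlas2 <- build_peak_atlas(data.frame(chrom = "chr1",
                                        start = c(100, 800),
                                        end = c(200, 900)))
  expect_equal(nrow(atlas2), 2)     # gap 600 > 500
  # blacklisted peak disappears before merging
  bl <- data.frame(chrom = "chr1", start = 550, end = 750)
  atlas3 <- build_peak_atlas(peaks, blacklist = bl)
  expect_equal(nrow(atlas3), 2)
  expect_equal(atlas3$end[1], 200)
  expect_error(build_peak_atlas(data.frame(chrom = "chr1", start = 200,
                                           end = 100)),
               "malformed")
})

test_that("atlas construction is idempotent with gaps above the merge window", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 60
    starts <- sort(sample.int(2e5, n))
    peaks <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                        start = starts,
                        end = starts + sample(50:400, n, TRUE))
    atlas <- build_peak_atlas(peaks)
    for (df in split(atlas, atlas$chrom)) {
      if (nrow(df) > 1) {
        expect_true(all(df$start[-1] - df$end[-nrow(df)] > 500))
      }
    }
    again <- build_peak_atlas(atlas[, c("chrom", "start", "end")])
    expect_equal(again$start, atlas$start)
    expect_equal(again$end, atlas$end)
    expect_equal(again$chrom, atlas$chrom)
  }
})

test_that("depth normalization scales to the reference and keeps ratios", {
  raw <- matrix(c(10, 20, 10, 20), nrow = 2,
                dimnames = list(c("p1", "p2"), c("s1", "s2")))
  sm <- normalize_depth(raw, totals = c(s1 = 5e6, s2 = 1e7))
  expect_equal(sm$normalized[, "s1"], c(p1 = 20, p2 = 40))  # x 2
  expect_equal(sm$normalized[, "s2"], c(p1 = 10, p2 = 20))  # identity
  # two samples at (1e7, 2e7) with equal raw counts: second halves
  raw2 <- raw[, c(1, 1)]
  colnames(raw2) <- c("s1", "s2")
  sm2 <- normalize_depth(raw2, totals = c(s1 = 1e7, s2 = 2e7))
  expect_equal(unname(sm2$normalized[, 2] / sm2$normalized[, 1]),
               c(0.5, 0.5))
  # within-sample ratios conserved exactly
  expect_equal(sm$normalized["p2", "s1"] / sm$normalized["p1", "s1"],
               raw["p2", "s1"] / raw["p1", "s1"])
  expect_error(normalize_depth(raw, totals = c(s1 = 0, s2 = 1e7)), "zero")
})

test_that("peak-to-gene annotation equals the all-pairs oracle", {
  set.seed(19)
  sim <- simulate_chromatin_landscape(sim_chromatin_config(n_peaks = 1000,
                                                           seed = 23))
  atlas <- sim$atlas
  n_genes <- 300
  starts <- sort(sample.int(5e7, n_genes))
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                      chrom = sample(c("chr1", "chr2", "chr3"), n_genes,
                                     TRUE),
                      start = starts,
                      end = starts + sample(2000:50000, n_genes, TRUE),
                      strand = sample(c("+", "-"), n_genes, TRUE))
  ann <- annotate_peaks_to_genes(atlas, genes)
  want <- oracle_annotate(atlas, genes)
  expect_identical(ann$gene_id, want)
})

test_that("annotation applies the documented tie-breaks", {
  atlas <- build_peak_atlas(data.frame(chrom = "chr1",
                                       start = c(1000, 9000, 30000),
                                       end = c(1500, 9500, 30500)))
  genes <- data.frame(gene_id = c("A", "B", "C"),
                      chrom = "chr1",
                      start = c(500, 800, 12000),
                      end = c(2000, 1800, 13000),
                      strand = c("+", "-", "+"))
  ann <- annotate_peaks_to_genes(atlas, genes)
  # peak 1 (mid 1250) overlaps A and B; TSS distances: A 750, B 550 -> B
  expect_equal(ann$gene_id[1], "B")
  expect_true(ann$overlap[1])
  # peak 2 (mid 9250) intergenic; nearest TSS is C at 12000
  expect_equal(ann$gene_id[2], "C")
  expect_false(ann$overlap[2])
  # no genes on the chromosome -> unannotated
  atlas2 <- build_peak_atlas(data.frame(chrom = "chrX", start = 1,
                                        end = 100))
  ann2 <- annotate_peaks_to_genes(atlas2, genes)
  expect_true(is.na(ann2$gene_id[1]))
})

test_that("planted chromatin states are recovered from the signal", {
  sim <- simulate_chromatin_landscape(sim_chromatin_config(n_peaks = 1000,
                                                           seed = 6))
  signal <- normalize_depth(sim$counts, totals = sim$library_sizes)
  calls <- call_chromatin_states(signal, sim$sample_info)
  truth <- sim$truth$peak_states
  for (state in unique(truth)) {
    idx <- names(truth)[truth == state]
    expect_gte(mean(calls$transition[idx] == state), 0.95)
  }
  # bivalent template: K4me3+K27me3 in NPC resolving to K27ac without
  # K27me3 in neurons
  biv <- names(truth)[truth == "bivalent_resolving"][1]
  expect_true(calls$presence[biv, "H3K4me3", "NPC"])
  expect_true(calls$presence[biv, "H3K27me3", "NPC"])
  expect_true(calls$presence[biv, "H3K27ac", "neuron"])
  expect_false(calls$presence[biv, "H3K27me3", "neuron"])
  # a mark missing at one stage is an input error naming the mark
  dropped <- sim$sample_info[!(sim$sample_info$mark == "H3K27ac" &
                               sim$sample_info$stage == "neuron"), ]
  expect_error(call_chromatin_states(signal, dropped), "H3K27ac")
})

test_that("differential-peak clustering recovers planted archetypes", {
  sim <- simulate_chromatin_landscape(
    sim_chromatin_config(n_peaks = 600, n_replicates = 3, seed = 12))
  si <- sim$sample_info
  signal <- normalize_depth(sim$counts, totals = sim$library_sizes)
  # peak-level contrasts NPC vs neuron per mark on normalized signal
  de <- lapply(unique(si$mark), function(mk) {
    naive_differential_signal(
      signal,
      si$sample[si$mark == mk & si$stage == "neuron"],
      si$sample[si$mark == mk & si$stage == "NPC"])
  })
  cl <- cluster_differential_peaks(signal, de, method = "ward", k = 3)
  truth <- sim$truth$peak_states[names(cl$cluster)]
  # planted membership of the dynamic archetypes is recovered: each
  # dynamic state maps to one dominant cluster (the union of contrasts at
  # 5% FDR admits a stable-peak minority by construction)
  dyn <- truth != "stable"
  tab <- table(cl$cluster[dyn], truth[dyn])
  purity <- sum(apply(tab, 2, max)) / sum(dyn)
  expect_gte(purity, 0.95)
  # the dominant clusters of the three dynamic states are distinct
  expect_equal(length(unique(apply(tab, 2, which.max))), 3)
  # stable peaks only enter the differential union at the false-call rate
  expect_lt(mean(sim$truth$peak_states[cl$differential_peaks] == "stable"),
            0.15)
})

test_that("ward clustering merge order matches the exhaustive oracle", {
  set.seed(3)
  x <- matrix(rnorm(7 * 4), nrow = 7, dimnames = list(paste0("p", 1:7),
                                                      NULL))
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  parts <- oracle_ward_partitions(x)
  for (k in 2:6) {
    expect_true(same_partition(stats::cutree(hc, k = k),
                               parts[[7 - k]]))
  }
})

test_that("empty differential set warns and returns zero clusters", {
  sm <- normalize_depth(matrix(5, 4, 4,
                               dimnames = list(paste0("p", 1:4),
                                               paste0("s", 1:4))),
                        totals = stats::setNames(rep(1e7, 4),
                                                 paste0("s", 1:4)))
  de <- list(data.frame(gene = paste0("p", 1:4), logFC = 0, pvalue = 1,
                        fdr = 1))
  expect_warning(cl <- cluster_differential_peaks(sm, de), "no differential")
  expect_equal(cl$k, 0L)
  expect_length(cl$cluster, 0)
})

test_that("cluster expression profiles use per-gene z-scores", {
  expr <- rbind(g1 = c(1, 2, 3), g2 = c(3, 2, 1), flat = c(2, 2, 2))
  colnames(expr) <- c("d25", "d50", "d75")
  clusters <- c(p1 = 1, p2 = 2, p3 = 2)
  ann <- data.frame(peak_id = c("p1", "p2", "p3"),
                    gene_id = c("g1", "g2", "flat"))
  expect_warning(
    prof <- intersect_expression_zscores(clusters, ann,
                                         de_genes = c("g1", "g2", "flat"),
                                         expr = expr),
    "flat")
  expect_equal(unname(prof$profile["1", ]), c(-1, 0, 1))
  expect_equal(unname(prof$profile["2", ]), c(1, 0, -1))
  expect_equal(unname(prof$n_genes), c(1L, 1L))
})
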