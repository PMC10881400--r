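# Simulators for every data modality the pipeline consumes. Each simulator
# plants known ground truth and returns it alongside the dataset, so the
# downstream stages can be validated end to end without external data.

#' Configuration for the expression time-course simulator
#'
#' Describes a bulk RNA-seq differentiation time course: six ordered
#' timepoints (pluripotent stem cells, neural precursors, then post-mitotic
#' neurons at days 25/50/75/100), one or more treatment arms, and replicate
#' counts. A fraction of genes is planted with a monotone log2 trend across
#' the neuronal timepoints (d25 through d100); all other genes share a flat
#' mean. Counts are negative-binomial with a single shared dispersion.
#'
#' @param n_genes Number of genes to simulate.
#' @param timepoints Ordered character vector of timepoint labels. The
#'   planted trend spans the last four (the neuronal stages).
#' @param treatments Character vector of treatment arm labels.
#' @param n_replicates Replicates per (timepoint, treatment) condition.
#' @param frac_mono_up,frac_mono_down Fractions of genes planted with a
#'   monotonically increasing / decreasing trend; must sum to at most 1.
#' @param base_mean_log2 Baseline log2 mean count shared by all genes at the
#'   start of the trend window.
#' @param effect_log2fc Planted log2 fold change added per neuronal
#'   transition (d25 to d50, d50 to d75, d75 to d100) for trend genes.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); must be positive.
#' @param gene_length_range Length-2 numeric, the bp interval gene lengths
#'   are drawn from (uniformly).
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   dataset exactly.
#' @return A list of class `sim_expr_config`.
#' @export
sim_expr_config <- function(n_genes = 2000,
                            timepoints = c("hPSC", "NPC", "d25", "d50",
                                           "d75", "d100"),
                            treatments = c("DMSO", "EZH2i"),
                            n_replicates = 3,
                            frac_mono_up = 0.1,
                            frac_mono_down = 0.1,
                            base_mean_log2 = 8,
                            effect_log2fc = 1,
                            dispersion = 0.05,
                            gene_length_range = c(500, 5000),
                            seed = 1L) {
  check_scalar_num(n_genes, "n_genes", lower = 1)
  if (length(timepoints) < 4L) {
    stop_config("timepoints", "must contain at least four labels")
  }
  check_scalar_num(n_replicates, "n_replicates", lower = 1)
  check_scalar_num(frac_mono_up, "frac_mono_up", lower = 0, upper = 1)
  check_scalar_num(frac_mono_down, "frac_mono_down", lower = 0, upper = 1)
  if (frac_mono_up + frac_mono_down > 1) {
    stop_config("frac_mono_up", "plus `frac_mono_down` must be <= 1")
  }
  check_scalar_num(effect_log2fc, "effect_log2fc", lower = 0)
  check_scalar_num(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  if (length(gene_length_range) != 2L || gene_length_range[1] <= 0 ||
      gene_length_range[2] < gene_length_range[1]) {
    stop_config("gene_length_range", "must be a positive increasing interval")
  }
  structure(list(
    n_genes = as.integer(n_genes), timepoints = timepoints,
    treatments = treatments, n_replicates = as.integer(n_replicates),
    frac_mono_up = frac_mono_up, frac_mono_down = frac_mono_down,
    base_mean_log2 = base_mean_log2, effect_log2fc = effect_log2fc,
    dispersion = dispersion, gene_length_range = gene_length_range,
    seed = as.integer(seed)
  ), class = "sim_expr_config")
}

#' Simulate an expression differentiation time course with planted trends
#'
#' Draws a gene-by-sample count matrix from a negative binomial. Genes
#' planted as `mono_up` have a mean log2 expression that increases by
#' `effect_log2fc` at each transition across the last four timepoints
#' (`mono_down` mirrored); all other genes, and all pre-neuronal timepoints,
#' sit at the flat baseline. Both treatment arms share the same means: the
#' simulator models chronological maturation, and treatment contrasts are
#' added downstream by comparing arms.
#'
#' @param config A [sim_expr_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{timecourse}{An `expression_timecourse`: `counts` (gene x
#'       sample integer matrix), `gene_lengths` (named bp vector), and
#'       `samples` (data.frame with `sample`, `timepoint`, `treatment`,
#'       `replicate`).}
#'     \item{truth}{Planted labels: `gene_trend_labels`, a named character
#'       vector over genes with values `mono_up`, `mono_down` or `none`,
#'       plus the `seed` used.}
#'   }
#' @examples
#' sim <- simulate_expression_timecourse(sim_expr_config(n_genes = 50, seed = 7))
#' table(sim$truth$gene_trend_labels)
#' @export
simulate_expression_timecourse <- function(config = sim_expr_config()) {
  stopifnot(inherits(config, "sim_expr_config"))
  tps <- config$timepoints
  trend_tps <- utils::tail(tps, 4L)   # neuronal window carrying the trend
  n <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(n))

  n_up <- floor(config$frac_mono_up * n)
  n_down <- floor(config$frac_mono_down * n)
  labels <- rep("none", n)
  if (n_up > 0) labels[seq_len(n_up)] <- "mono_up"
  if (n_down > 0) labels[n_up + seq_len(n_down)] <- "mono_down"
  names(labels) <- genes

  meta <- expand.grid(replicate = seq_len(config$n_replicates),
                      timepoint = tps, treatment = config$treatments,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("timepoint", "treatment", "replicate")]
  meta$sample <- sprintf("%s_%s_r%d", meta$treatment, meta$timepoint,
                         meta$replicate)
  meta <- meta[, c("sample", "timepoint", "treatment", "replicate")]

  # log2 mean per gene x timepoint: step along the trend window only.
  # Planted trends are centered on the baseline (up genes start below it,
  # down genes above, crossing mid-course), which keeps total library mass
  # roughly constant across timepoints so per-million scaling does not
  # induce spurious fold changes in flat genes.
  step <- match(tps, trend_tps) - 1L      # NA before d25, 0..3 within
  step[is.na(step)] <- 0L
  center <- (length(trend_tps) - 1) / 2
  dir <- ifelse(labels == "mono_up", 1, ifelse(labels == "mono_down", -1, 0))
  log2mu <- outer(dir * config$effect_log2fc, step - center) +
    config$base_mean_log2
  rownames(log2mu) <- genes
  colnames(log2mu) <- tps

  out <- with_seed(config$seed, {
    lengths <- round(stats::runif(n, config$gene_length_range[1],
                                  config$gene_length_range[2]))
    counts <- matrix(0L, nrow = n, ncol = nrow(meta),
                     dimnames = list(genes, meta$sample))
    size <- 1 / config$dispersion
    for (j in seq_len(nrow(meta))) {
      mu <- 2^log2mu[, meta$timepoint[j]]
      counts[, j] <- stats::rnbinom(n, mu = mu, size = size)
    }
    list(lengths = lengths, counts = counts)
  })
  names(out$lengths) <- genes

  tc <- structure(list(counts = out$counts, gene_lengths = out$lengths,
                       samples = meta),
                  class = "expression_timecourse")
  truth <- list(gene_trend_labels = labels, seed = config$seed)
  list(timecourse = tc, truth = truth)
}

#' Configuration for the calcium-trace simulator
#'
#' Emulates somatic GCaMP recordings of a neuronal field of view: each ROI
#' fires private Poisson events and joins network-wide events with a fixed
#' participation probability. Every event adds an instantaneous fluorescence
#' jump (amplitude in dF/F0 units, normal truncated at zero) that decays
#' exponentially on a constant baseline, plus optional Gaussian sensor
#' noise. Event times are snapped to the frame grid so planted amplitudes
#' are realized exactly at the sampled peak.
#'
#' @param n_rois Number of regions of interest (cells).
#' @param duration_s Recording length in seconds.
#' @param frame_rate_hz Acquisition rate in frames per second.
#' @param cell_rate_per_min Poisson rate of private (per-cell) events.
#' @param sync_rate_per_min Poisson rate of network-wide events.
#' @param sync_participation Probability each ROI joins a network event.
#' @param amp_mean,amp_sd Event amplitude distribution in dF/F0 units
#'   (normal truncated at 0).
#' @param decay_tau_s Exponential decay constant of the calcium transient.
#' @param min_separation_s Refractory interval per ROI: events closer than
#'   this to an earlier kept event are dropped (earlier event wins), so a
#'   planted spike count is well-defined at the recording's resolution.
#' @param baseline_f0 Baseline fluorescence (arbitrary units, > 0).
#' @param noise_sd Additive Gaussian noise on raw fluorescence, same units
#'   as `baseline_f0`.
#' @param seed Integer seed.
#' @return A list of class `sim_calcium_config`.
#' @export
sim_calcium_config <- function(n_rois = 20,
                               duration_s = 180,
                               frame_rate_hz = 5,
                               cell_rate_per_min = 2,
                               sync_rate_per_min = 1,
                               sync_participation = 0.9,
                               amp_mean = 1.0,
                               amp_sd = 0.2,
                               decay_tau_s = 2,
                               min_separation_s = 1.0,
                               baseline_f0 = 100,
                               noise_sd = 2,
                               seed = 1L) {
  check_scalar_num(n_rois, "n_rois", lower = 1)
  check_scalar_num(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar_num(frame_rate_hz, "frame_rate_hz", lower = 0,
                   strict_lower = TRUE)
  if (duration_s * frame_rate_hz < 10) {
    stop_config("duration_s", "x `frame_rate_hz` must give >= 10 frames")
  }
  check_scalar_num(cell_rate_per_min, "cell_rate_per_min", lower = 0)
  check_scalar_num(sync_rate_per_min, "sync_rate_per_min", lower = 0)
  check_scalar_num(sync_participation, "sync_participation", lower = 0,
                   upper = 1, strict_lower = TRUE)
  check_scalar_num(amp_mean, "amp_mean", lower = 0, strict_lower = TRUE)
  check_scalar_num(amp_sd, "amp_sd", lower = 0)
  check_scalar_num(decay_tau_s, "decay_tau_s", lower = 0, strict_lower = TRUE)
  check_scalar_num(min_separation_s, "min_separation_s", lower = 0)
  check_scalar_num(baseline_f0, "baseline_f0", lower = 0, strict_lower = TRUE)
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  structure(list(
    n_rois = as.integer(n_rois), duration_s = duration_s,
    frame_rate_hz = frame_rate_hz, cell_rate_per_min = cell_rate_per_min,
    sync_rate_per_min = sync_rate_per_min,
    sync_participation = sync_participation, amp_mean = amp_mean,
    amp_sd = amp_sd, decay_tau_s = decay_tau_s,
    min_separation_s = min_separation_s, baseline_f0 = baseline_f0,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_calcium_config")
}

#' Simulate ROI fluorescence traces with planted spikes and network events
#'
#' @param config A [sim_calcium_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{traces}{A `trace_set`: `time_s` (frame times), `F` (ROI x
#'       frame fluorescence matrix), `frame_rate_hz`.}
#'     \item{truth}{`spike_times` (list, one sorted numeric vector per
#'       ROI), `spike_amplitudes` (matching dF/F0 amplitudes),
#'       `sync_event_times`, and the `seed`.}
#'   }
#' @examples
#' sim <- simulate_calcium_traces(sim_calcium_config(n_rois = 4, seed = 2))
#' lengths(sim$truth$spike_times)
#' @export
simulate_calcium_traces <- function(config = sim_calcium_config()) {
  stopifnot(inherits(config, "sim_calcium_config"))
  n_frames <- floor(config$duration_s * config$frame_rate_hz)
  t_grid <- (seq_len(n_frames) - 1) / config$frame_rate_hz
  snap <- function(x) t_grid[pmin(n_frames, round(x * config$frame_rate_hz) + 1)]
  rois <- sprintf("roi%03d", seq_len(config$n_rois))

  out <- with_seed(config$seed, {
    n_sync <- stats::rpois(1, config$sync_rate_per_min * config$duration_s / 60)
    sync_times <- sort(snap(stats::runif(n_sync, 0, config$duration_s)))
    spike_times <- vector("list", config$n_rois)
    spike_amps <- vector("list", config$n_rois)
    FF <- matrix(0, nrow = config$n_rois, ncol = n_frames,
                 dimnames = list(rois, NULL))
    for (i in seq_len(config$n_rois)) {
      n_cell <- stats::rpois(1, config$cell_rate_per_min *
                                config$duration_s / 60)
      cell_times <- snap(stats::runif(n_cell, 0, config$duration_s))
      joins <- stats::runif(length(sync_times)) <= config$sync_participation
      ev <- sort(unique(c(cell_times, sync_times[joins])))
      if (length(ev) > 1 && config$min_separation_s > 0) {
        keep <- logical(length(ev))
        last <- -Inf
        for (k in seq_along(ev)) {
          if (ev[k] - last >= config$min_separation_s) {
            keep[k] <- TRUE
            last <- ev[k]
          }
        }
        ev <- ev[keep]
      }
      amps <- rnorm_pos(length(ev), config$amp_mean, config$amp_sd)
      sig <- rep(0, n_frames)
      for (k in seq_along(ev)) {
        idx <- which(t_grid >= ev[k])
        sig[idx] <- sig[idx] +
          amps[k] * exp(-(t_grid[idx] - ev[k]) / config$decay_tau_s)
      }
      noise <- if (config$noise_sd > 0) {
        stats::rnorm(n_frames, 0, config$noise_sd)
      } else {
        0
      }
      FF[i, ] <- config$baseline_f0 * (1 + sig) + noise
      spike_times[[i]] <- ev
      spike_amps[[i]] <- amps
    }
    names(spike_times) <- rois
    names(spike_amps) <- rois
    list(FF = FF, spike_times = spike_times, spike_amps = spike_amps,
         sync_times = sync_times)
  })

  traces <- structure(list(time_s = t_grid, F = out$FF,
                           frame_rate_hz = config$frame_rate_hz),
                      class = "trace_set")
  truth <- list(spike_times = out$spike_times,
                spike_amplitudes = out$spike_amps,
                sync_event_times = out$sync_times, seed = config$seed)
  list(traces = traces, truth = truth)
}

#' Configuration for the chromatin-landscape simulator
#'
#' Emulates a two-stage (neural precursor vs neuron) histone-mark landscape
#' over a peak atlas. Each peak carries one planted state:
#' \describe{
#'   \item{bivalent_resolving}{H3K4me3 + H3K27me3 in NPCs, resolving to
#'     H3K4me3 + H3K27ac (H3K27me3 lost) in neurons.}
#'   \item{active_gaining}{quiet in NPCs, gaining H3K4me3 + H3K27ac in
#'     neurons.}
#'   \item{immature_open}{active (H3K4me3 + H3K27ac) in NPCs only.}
#'   \item{stable}{background signal at both stages.}
#' }
#' Fragment counts are Poisson around `signal_high` / `signal_low`, scaled
#' to per-sample library sizes.
#'
#' @param n_peaks Number of atlas peaks.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param state_fractions Named proportions over the four states; must sum
#'   to 1. Assigned exactly (floor allocation, remainder to `stable`).
#' @param marks Histone marks profiled.
#' @param stages The two developmental stages.
#' @param n_replicates Replicates per (mark, stage).
#' @param signal_high,signal_low Mean normalized fragment counts for
#'   mark-positive / background peaks (at the 10-million-fragment reference
#'   depth).
#' @param library_sizes Optional named vector sample -> total fragments;
#'   defaults to 1e7 for every sample.
#' @param seed Integer seed.
#' @return A list of class `sim_chromatin_config`.
#' @export
sim_chromatin_config <- function(n_peaks = 2000,
                                 chrom_sizes = c(chr1 = 6e7, chr2 = 5e7,
                                                 chr3 = 4e7),
                                 state_fractions = c(bivalent_resolving = 0.15,
                                                     active_gaining = 0.15,
                                                     immature_open = 0.15,
                                                     stable = 0.55),
                                 marks = c("H3K4me3", "H3K27me3", "H3K27ac",
                                           "H3K9me3"),
                                 stages = c("NPC", "neuron"),
                                 n_replicates = 2,
                                 signal_high = 100,
                                 signal_low = 5,
                                 library_sizes = NULL,
                                 seed = 1L) {
  check_scalar_num(n_peaks, "n_peaks", lower = 1)
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop_config("chrom_sizes", "must be a named vector of positive lengths")
  }
  states <- c("bivalent_resolving", "active_gaining", "immature_open",
              "stable")
  if (!setequal(names(state_fractions), states)) {
    stop_config("state_fractions",
                sprintf("must name exactly: %s", paste(states, collapse = ", ")))
  }
  if (abs(sum(state_fractions) - 1) > 1e-8) {
    stop_config("state_fractions", "must sum to 1")
  }
  if (any(state_fractions < 0)) stop_config("state_fractions", "must be >= 0")
  if (length(stages) != 2L) stop_config("stages", "must list exactly 2 stages")
  check_scalar_num(n_replicates, "n_replicates", lower = 1)
  check_scalar_num(signal_low, "signal_low", lower = 0)
  if (signal_high <= signal_low) {
    stop_config("signal_high", "must be > `signal_low`")
  }
  structure(list(
    n_peaks = as.integer(n_peaks), chrom_sizes = chrom_sizes,
    state_fractions = state_fractions[states], marks = marks,
    stages = stages, n_replicates = as.integer(n_replicates),
    signal_high = signal_high, signal_low = signal_low,
    library_sizes = library_sizes, seed = as.integer(seed)
  ), class = "sim_chromatin_config")
}

# Which (mark, stage slot) combinations are "high" for each planted state.
# Stage slot 1 = precursor, slot 2 = neuron.
chromatin_state_templates <- function(marks, stages) {
  tmpl <- list(
    bivalent_resolving = list(c("H3K4me3", "H3K27me3"),
                              c("H3K4me3", "H3K27ac")),
    active_gaining = list(character(), c("H3K4me3", "H3K27ac")),
    immature_open = list(c("H3K4me3", "H3K27ac"), character()),
    stable = list(character(), character())
  )
  lapply(tmpl, function(x) {
    names(x) <- stages
    lapply(x, intersect, y = marks)
  })
}

#' Simulate a two-stage histone-mark landscape over a synthetic peak atlas
#'
#' Places non-overlapping peaks (pairwise gaps > 500 bp, so the atlas is a
#' fixed point of [build_peak_atlas()]), assigns each an exact planted
#' chromatin state, and draws Poisson fragment counts for every
#' (mark, stage, replicate) sample.
#'
#' @param config A [sim_chromatin_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{atlas}{A `peak_atlas` (see [build_peak_atlas()]).}
#'     \item{counts}{Peak x sample raw fragment-count matrix.}
#'     \item{sample_info}{data.frame: `sample`, `mark`, `stage`,
#'       `replicate`.}
#'     \item{library_sizes}{Named total-fragment vector used for scaling.}
#'     \item{truth}{`peak_states` (named character vector peak -> state)
#'       and the `seed`.}
#'   }
#' @export
simulate_chromatin_landscape <- function(config = sim_chromatin_config()) {
  stopifnot(inherits(config, "sim_chromatin_config"))
  gap <- 501          # strict: pairwise gaps must exceed the 500 bp merge rule
  width_range <- c(300, 800)
  n <- config$n_peaks
  chroms <- names(config$chrom_sizes)

  # peaks per chromosome, proportional to length (largest remainder)
  share <- config$chrom_sizes / sum(config$chrom_sizes)
  n_per <- floor(share * n)
  rem <- n - sum(n_per)
  if (rem > 0) {
    ord <- order(share * n - n_per, decreasing = TRUE)
    n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1L
  }
  slot <- width_range[2] + gap
  too_small <- config$chrom_sizes < n_per * slot
  if (any(too_small)) {
    stop(sprintf("cannot place %d peaks with >%d bp gaps on %s (%g bp)",
                 n_per[too_small][1], gap - 1,
                 chroms[too_small][1],
                 config$chrom_sizes[too_small][1]), call. = FALSE)
  }

  sample_info <- expand.grid(replicate = seq_len(config$n_replicates),
                             stage = config$stages, mark = config$marks,
                             stringsAsFactors = FALSE)
  sample_info <- sample_info[, c("mark", "stage", "replicate")]
  sample_info$sample <- sprintf("%s_%s_r%d", sample_info$mark,
                                sample_info$stage, sample_info$replicate)
  sample_info <- sample_info[, c("sample", "mark", "stage", "replicate")]
  lib <- config$library_sizes
  if (is.null(lib)) {
    lib <- stats::setNames(rep(1e7, nrow(sample_info)), sample_info$sample)
  }
  if (!all(sample_info$sample %in% names(lib))) {
    stop_config("library_sizes", "must name every simulated sample")
  }
  lib <- lib[sample_info$sample]

  states <- names(config$state_fractions)
  n_state <- floor(config$state_fractions * n)
  n_state["stable"] <- n_state["stable"] + (n - sum(n_state))
  tmpl <- chromatin_state_templates(config$marks, config$stages)

  out <- with_seed(config$seed, {
    bed <- do.call(rbind, lapply(chroms, function(ch) {
      k <- n_per[ch]
      if (k == 0) return(NULL)
      w <- round(stats::runif(k, width_range[1], width_range[2]))
      # jitter starts inside the free space, then lay out slots in order
      free <- config$chrom_sizes[ch] - k * slot
      x <- sort(round(stats::runif(k, 0, free)))
      start <- x + (seq_len(k) - 1L) * slot
      data.frame(chrom = ch, start = start, end = start + w,
                 stringsAsFactors = FALSE)
    }))
    state_vec <- sample(rep(states, times = n_state))
    counts <- matrix(0, nrow = n, ncol = nrow(sample_info))
    for (j in seq_len(nrow(sample_info))) {
      mk <- sample_info$mark[j]
      st <- sample_info$stage[j]
      mu_state <- vapply(states, function(s) {
        if (mk %in% tmpl[[s]][[st]]) config$signal_high else config$signal_low
      }, numeric(1))
      mu <- mu_state[state_vec] * (lib[j] / 1e7)
      counts[, j] <- stats::rpois(n, mu)
    }
    list(bed = bed, state_vec = state_vec, counts = counts)
  })

  peak_ids <- sprintf("peak%05d", seq_len(n))
  atlas <- new_peak_atlas(data.frame(chrom = out$bed$chrom,
                                     start = out$bed$start,
                                     end = out$bed$end,
                                     peak_id = peak_ids,
                                     stringsAsFactors = FALSE),
                          provenance = "simulate_chromatin_landscape")
  dimnames(out$counts) <- list(peak_ids, sample_info$sample)
  truth <- list(peak_states = stats::setNames(out$state_vec, peak_ids),
                seed = config$seed)
  list(atlas = atlas, counts = out$counts, sample_info = sample_info,
       library_sizes = lib, truth = truth)
}

#' Simulate a motif-peak annotation with planted group-specific enrichment
#'
#' Background motif presence is Bernoulli(`background_rate`) per
#' (peak, motif); a motif planted for a group is present in that group's
#' peaks at rate `min(1, enrichment_factor * background_rate)` instead.
#'
#' @param atlas A `peak_atlas`.
#' @param n_motifs Number of motifs to simulate (ids `M001`, ...). Each
#'   motif is mapped to one synthetic transcription-factor gene (`TF_M001`,
#'   ...), returned in `annotation$motif_tf`.
#' @param groups Named list: group label -> character vector of peak ids.
#'   Groups must be disjoint subsets of the atlas.
#' @param planted Named list: group label -> motif ids enriched in that
#'   group. Group names must appear in `groups`.
#' @param enrichment_factor Presence-rate multiplier for planted
#'   (group, motif) pairs; must exceed 1.
#' @param background_rate Background presence probability per (peak, motif).
#' @param seed Integer seed.
#' @return A list with elements:
#'   \describe{
#'     \item{annotation}{A `motif_annotation`: `peaks` (long data.frame
#'       `peak_id`, `motif_id`) and `motif_tf` (data.frame `motif_id`,
#'       `tf_gene`).}
#'     \item{truth}{`enriched_motifs` (the planted list) and the `seed`.}
#'   }
#' @export
simulate_motif_annotation <- function(atlas, n_motifs, groups, planted,
                                      enrichment_factor = 2.5,
                                      background_rate = 0.2,
                                      seed = 1L) {
  stopifnot(inherits(atlas, "peak_atlas"))
  check_scalar_num(n_motifs, "n_motifs", lower = 1)
  if (enrichment_factor <= 1) {
    stop_config("enrichment_factor", "must be > 1")
  }
  check_scalar_num(background_rate, "background_rate", lower = 0, upper = 1)
  peak_ids <- atlas$peak_id
  all_group_peaks <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_group_peaks)) {
    stop("`groups` must be disjoint peak sets", call. = FALSE)
  }
  if (!all(all_group_peaks %in% peak_ids)) {
    stop("`groups` contains peak ids absent from the atlas", call. = FALSE)
  }
  if (!all(names(planted) %in% names(groups))) {
    stop("`planted` names groups absent from `groups`", call. = FALSE)
  }
  motifs <- sprintf("M%03d", seq_len(n_motifs))
  bad <- setdiff(unlist(planted, use.names = FALSE), motifs)
  if (length(bad) > 0) {
    stop(sprintf("`planted` motif ids not simulated: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  p_in <- min(1, enrichment_factor * background_rate)
  pres <- with_seed(seed, {
    p <- matrix(background_rate, nrow = length(peak_ids),
                ncol = n_motifs, dimnames = list(peak_ids, motifs))
    for (g in names(planted)) {
      p[groups[[g]], planted[[g]]] <- p_in
    }
    matrix(stats::runif(length(p)) <= p, nrow = nrow(p),
           dimnames = dimnames(p))
  })
  idx <- which(pres, arr.ind = TRUE)
  ann <- data.frame(peak_id = peak_ids[idx[, 1]],
                    motif_id = motifs[idx[, 2]],
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$peak_id, ann$motif_id), , drop = FALSE]
  rownames(ann) <- NULL
  annotation <- structure(
    list(peaks = ann,
         motif_tf = data.frame(motif_id = motifs,
                               tf_gene = paste0("TF_", motifs),
                               stringsAsFactors = FALSE)),
    class = "motif_annotation")
  list(annotation = annotation,
       truth = list(enriched_motifs = planted, seed = as.integer(seed)))
}

#' Synthesize gene models linking atlas peaks to expression genes
#'
#' Builds a BED-like gene-model table that co-locates peaks with genes so
#' the chromatin and expression stages can be intersected end to end:
#' peaks planted as `bivalent_resolving` are placed inside genes planted
#' as `mono_up`, `immature_open` peaks inside `mono_down` genes, and the
#' remaining peaks inside flat (`none`) genes, as long as unused genes of
#' the matching class remain (each gene hosts at most one peak; leftover
#' peaks fall back to flat genes, and are left unmodelled when genes run
#' out).
#'
#' @param atlas A `peak_atlas`.
#' @param peak_states Named character vector peak -> planted state (from
#'   `simulate_chromatin_landscape()$truth`).
#' @param gene_trend_labels Named character vector gene -> planted trend
#'   (from `simulate_expression_timecourse()$truth`).
#' @param span_bp Gene-body half-width added around the host peak.
#' @param seed Integer seed (controls gene-to-peak pairing and strand).
#' @return data.frame gene models: `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (BED convention).
#' @export
simulate_gene_models <- function(atlas, peak_states, gene_trend_labels,
                                 span_bp = 2000, seed = 1L) {
  stopifnot(inherits(atlas, "peak_atlas"))
  pool <- list(
    mono_up = names(gene_trend_labels)[gene_trend_labels == "mono_up"],
    mono_down = names(gene_trend_labels)[gene_trend_labels == "mono_down"],
    none = names(gene_trend_labels)[gene_trend_labels == "none"]
  )
  wanted <- c(bivalent_resolving = "mono_up", immature_open = "mono_down",
              active_gaining = "none", stable = "none")
  with_seed(seed, {
    pool <- lapply(pool, sample)
    rows <- vector("list", nrow(atlas))
    for (i in seq_len(nrow(atlas))) {
      cls <- wanted[[peak_states[[atlas$peak_id[i]]]]]
      if (length(pool[[cls]]) == 0) cls <- "none"
      if (length(pool[[cls]]) == 0) next
      g <- pool[[cls]][1]
      pool[[cls]] <- pool[[cls]][-1]
      rows[[i]] <- data.frame(
        gene_id = g, chrom = atlas$chrom[i],
        start = max(0, atlas$start[i] - span_bp),
        end = atlas$end[i] + span_bp,
        strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
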