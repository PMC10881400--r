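# Chromatin stage: peak-atlas construction, depth normalization,
# differential-peak clustering, peak-to-gene annotation, chromatin-state
# transition calling, and intersection with expression z-scores.
#
# All interval coordinates follow the BED convention: 0-based, half-open.
# GenomicRanges is used internally (with the 1-based shift applied on the
# way in and out).

#' Construct a peak-atlas data.frame
#' @param df data.frame with `chrom`, `start`, `end` (BED convention) and
#'   optionally `peak_id`.
#' @param provenance Character vector naming the contributing peak sets.
#' @return A `peak_atlas` data.frame sorted by (chrom, start) with stable
#'   `peak_id`s.
#' @noRd
new_peak_atlas <- function(df, provenance = character()) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  if (is.null(df$peak_id)) {
    df$peak_id <- sprintf("peak%05d", seq_len(nrow(df)))
  }
  rownames(df) <- NULL
  structure(df[, c("chrom", "start", "end", "peak_id")],
            class = c("peak_atlas", "data.frame"),
            provenance = provenance)
}

# BED (0-based half-open) <-> GRanges (1-based closed)
bed_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Build a global peak atlas from one or more peak sets
#'
#' Peaks overlapping any blacklist interval are removed first; the
#' remaining peaks from all sets are pooled, sorted, and transitively
#' merged whenever the gap between neighbours is at most `merge_distance`
#' bp. The result is idempotent: rebuilding from the atlas returns it
#' unchanged, and no two atlas peaks on one chromosome are within
#' `merge_distance` of each other.
#'
#' @param peak_sets A data.frame of intervals (`chrom`, `start`, `end`,
#'   BED convention) or a (optionally named) list of them, e.g. from
#'   [read_peaks()].
#' @param blacklist Optional data.frame of intervals to exclude.
#' @param merge_distance Maximum gap merged across, in bp (default 500).
#' @return A `peak_atlas` data.frame (`chrom`, `start`, `end`, `peak_id`),
#'   ids assigned in genomic order.
#' @examples
#' peaks <- data.frame(chrom = "chr1", start = c(100, 600), end = c(200, 700))
#' build_peak_atlas(peaks)  # gap 400 <= 500: one merged peak 100-700
#' @export
build_peak_atlas <- function(peak_sets, blacklist = NULL,
                             merge_distance = 500) {
  check_scalar_num(merge_distance, "merge_distance", lower = 0)
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  prov <- names(peak_sets) %||% rep("", length(peak_sets))
  pooled <- do.call(rbind, lapply(peak_sets, function(df) {
    validate_intervals(df)
    df[, c("chrom", "start", "end")]
  }))
  gr <- bed_to_granges(pooled)
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    validate_intervals(blacklist)
    bl <- bed_to_granges(blacklist)
    hit <- GenomicRanges::findOverlaps(gr, bl)
    drop <- unique(S4Vectors::queryHits(hit))
    if (length(drop) > 0) gr <- gr[-drop]
  }
  if (length(gr) == 0) {
    return(new_peak_atlas(data.frame(chrom = character(), start = integer(),
                                     end = integer(),
                                     peak_id = character(),
                                     stringsAsFactors = FALSE),
                          provenance = prov))
  }
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_distance + 1)
  merged <- GenomicRanges::sort(merged)
  new_peak_atlas(data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    stringsAsFactors = FALSE
  ), provenance = prov)
}

validate_intervals <- function(df) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% colnames(df))) {
    stop("intervals need columns chrom, start, end", call. = FALSE)
  }
  bad <- which(!(df$start < df$end) | df$start < 0)
  if (length(bad) > 0) {
    stop(sprintf("malformed interval at row %d: %s:%s-%s", bad[1],
                 df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]),
         call. = FALSE)
  }
  invisible(df)
}

#' Normalize a fragment-count matrix to a common sequencing depth
#'
#' Every sample is scaled by `target / total(sample)` so all columns
#' correspond to the same number of mapped fragments (default 10 million).
#' Within-sample ratios are conserved exactly.
#'
#' @param raw Peak x sample count matrix.
#' @param totals Named per-sample total mapped fragments (> 0). Defaults
#'   to the column sums of `raw`.
#' @param target Reference depth in fragments.
#' @return A `signal_matrix`: list with `normalized` (matrix), `totals`,
#'   `target`.
#' @export
normalize_depth <- function(raw, totals = NULL, target = 1e7) {
  if (is.null(totals)) totals <- colSums(raw)
  if (is.null(names(totals))) names(totals) <- colnames(raw)
  totals <- totals[colnames(raw)]
  if (anyNA(totals) || any(totals <= 0)) {
    stop(sprintf("sample '%s' has missing or zero total fragments",
                 colnames(raw)[is.na(totals) | totals <= 0][1]),
         call. = FALSE)
  }
  structure(list(normalized = sweep(raw, 2, target / totals, "*"),
                 totals = totals, target = target),
            class = "signal_matrix")
}

#' Cluster differential peaks by signal profile
#'
#' Takes the union of peaks significant in any pairwise contrast (FDR at
#' most `fdr_threshold`), z-scores each peak's normalized signal across
#' samples, and clusters the profiles either by Ward-linkage agglomerative
#' clustering cut at `k`, or by redundancy-stopped k-means
#' ([kmeans_redundancy()]). Cluster ids are relabelled in order of
#' decreasing size.
#'
#' @param signal A `signal_matrix` from [normalize_depth()].
#' @param de_peaks List of `de_table`s over peaks (columns `gene` holding
#'   peak ids, `fdr`), one per pairwise contrast.
#' @param method `"ward"` or `"kmeans_redundancy"`.
#' @param k Number of clusters for `"ward"`.
#' @param fdr_threshold Differential significance cut (inclusive).
#' @param ... Passed on to [kmeans_redundancy()].
#' @return List: `cluster` (named peak -> cluster id, empty when no peak
#'   is differential), `k`, `differential_peaks`, and `hclust` (ward only).
#' @export
cluster_differential_peaks <- function(signal, de_peaks,
                                       method = c("ward",
                                                  "kmeans_redundancy"),
                                       k = 4, fdr_threshold = 0.05, ...) {
  method <- match.arg(method)
  diff_peaks <- unique(unlist(lapply(de_peaks, function(tab) {
    tab$gene[!is.na(tab$fdr) & tab$fdr <= fdr_threshold]
  })))
  diff_peaks <- intersect(rownames(signal$normalized), diff_peaks)
  if (length(diff_peaks) == 0) {
    warning("no differential peaks at FDR <= ", fdr_threshold,
            call. = FALSE)
    return(list(cluster = stats::setNames(integer(0), character(0)),
                k = 0L, differential_peaks = character(0)))
  }
  x <- signal$normalized[diff_peaks, , drop = FALSE]
  z <- t(scale(t(x)))
  z[!is.finite(z)] <- 0                  # constant profiles
  if (method == "ward") {
    hc <- stats::hclust(stats::dist(z), method = "ward.D2")
    cl <- stats::cutree(hc, k = min(k, nrow(z)))
  } else {
    fit <- kmeans_redundancy(z, ...)
    cl <- fit$cluster
    hc <- NULL
  }
  # order cluster ids by decreasing size
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- stats::setNames(as.integer(relabel[as.character(cl)]), names(cl))
  out <- list(cluster = cl, k = length(sizes),
              differential_peaks = diff_peaks)
  if (!is.null(hc)) out$hclust <- hc
  out
}

#' Annotate atlas peaks to genes
#'
#' A peak overlapping a gene body is assigned to that gene; if it overlaps
#' several, the gene whose TSS is nearest the peak midpoint wins (then
#' lexicographic gene id). Peaks outside all gene bodies go to the gene
#' with the nearest TSS on the same chromosome, by distance from the peak
#' midpoint. Peaks on chromosomes without genes are left unannotated (NA).
#'
#' @param atlas A `peak_atlas`.
#' @param genes data.frame gene models: `gene_id`, `chrom`, `start`, `end`
#'   (BED convention), `strand` (`+`/`-`). The TSS is the strand-aware 5'
#'   end.
#' @return data.frame: `peak_id`, `gene_id` (NA when unannotated),
#'   `overlap` (logical: intragenic), `distance` (midpoint to TSS, bp).
#' @export
annotate_peaks_to_genes <- function(atlas, genes) {
  validate_intervals(genes)
  if (is.null(genes$gene_id) || is.null(genes$strand)) {
    stop("gene models need `gene_id` and `strand` columns", call. = FALSE)
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  mid <- (atlas$start + atlas$end) / 2
  out <- data.frame(peak_id = atlas$peak_id, gene_id = NA_character_,
                    overlap = FALSE, distance = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  gr_pk <- bed_to_granges(atlas)
  gr_gn <- bed_to_granges(genes)
  # disjoint seqlevel sets (peaks on gene-less chromosomes) are expected
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_pk, gr_gn))
  ov <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  for (q in names(ov)) {
    i <- as.integer(q)
    js <- ov[[q]]
    d <- abs(mid[i] - tss[js])
    pick <- js[order(d, genes$gene_id[js])][1]
    out$gene_id[i] <- genes$gene_id[pick]
    out$overlap[i] <- TRUE
    out$distance[i] <- abs(mid[i] - tss[pick])
  }
  todo <- which(!out$overlap)
  for (i in todo) {
    js <- which(genes$chrom == atlas$chrom[i])
    if (length(js) == 0) next
    d <- abs(mid[i] - tss[js])
    pick <- js[order(d, genes$gene_id[js])][1]
    out$gene_id[i] <- genes$gene_id[pick]
    out$distance[i] <- abs(mid[i] - tss[pick])
  }
  out
}

#' Call chromatin states and stage transitions per peak
#'
#' A mark is "present" at a peak in a stage when the mean normalized
#' signal across that stage's replicates reaches the mark's presence
#' threshold (default: twice the atlas-wide median signal of the mark,
#' pooled over stages; configurable, and an explicit per-mark threshold
#' can be supplied). Transition labels over (precursor stage, neuron
#' stage):
#' \describe{
#'   \item{bivalent_resolving}{H3K4me3 and H3K27me3 present at the
#'     precursor stage; H3K27ac present and H3K27me3 absent in neurons.}
#'   \item{active_gaining}{no H3K4me3/H3K27ac at the precursor stage;
#'     H3K4me3 and H3K27ac present in neurons.}
#'   \item{immature_open}{H3K4me3 or H3K27ac present at the precursor
#'     stage; no mark present in neurons.}
#'   \item{stable}{identical presence pattern at both stages.}
#'   \item{other}{anything else.}
#' }
#' Labels are assigned in that order of precedence.
#'
#' @param signal A `signal_matrix` over the atlas.
#' @param sample_info data.frame: `sample`, `mark`, `stage`.
#' @param stages Length-2 character: (precursor stage, neuron stage).
#' @param threshold_factor Presence threshold as a multiple of the
#'   atlas-wide per-mark median.
#' @param thresholds Optional named per-mark absolute thresholds,
#'   overriding `threshold_factor`.
#' @return A `state_call` list: `presence` (peak x mark x stage logical
#'   array), `transition` (named character vector), `thresholds`.
#' @export
call_chromatin_states <- function(signal, sample_info,
                                  stages = c("NPC", "neuron"),
                                  threshold_factor = 2,
                                  thresholds = NULL) {
  if (length(stages) != 2) stop("`stages` must have length 2", call. = FALSE)
  marks <- unique(sample_info$mark)
  x <- signal$normalized
  for (st in stages) {
    for (mk in marks) {
      if (!any(sample_info$stage == st & sample_info$mark == mk)) {
        stop(sprintf("no samples for mark '%s' at stage '%s'", mk, st),
             call. = FALSE)
      }
    }
  }
  mean_sig <- array(0, dim = c(nrow(x), length(marks), 2),
                    dimnames = list(rownames(x), marks, stages))
  for (mk in marks) {
    for (si in 1:2) {
      cols <- sample_info$sample[sample_info$mark == mk &
                                 sample_info$stage == stages[si]]
      mean_sig[, mk, si] <- rowMeans(x[, cols, drop = FALSE])
    }
  }
  if (is.null(thresholds)) {
    thresholds <- vapply(marks, function(mk) {
      threshold_factor * stats::median(mean_sig[, mk, ])
    }, numeric(1))
  }
  presence <- array(sweep(mean_sig, 2, thresholds[marks], ">="),
                    dim = dim(mean_sig), dimnames = dimnames(mean_sig))
  p1 <- presence[, , 1, drop = TRUE]
  p2 <- presence[, , 2, drop = TRUE]
  if (is.null(dim(p1))) {                 # single peak
    p1 <- matrix(p1, nrow = 1, dimnames = list(rownames(x), marks))
    p2 <- matrix(p2, nrow = 1, dimnames = list(rownames(x), marks))
  }
  has <- function(p, mk) if (mk %in% colnames(p)) p[, mk] else FALSE
  bivalent <- has(p1, "H3K4me3") & has(p1, "H3K27me3") &
    has(p2, "H3K27ac") & !has(p2, "H3K27me3")
  gaining <- !has(p1, "H3K4me3") & !has(p1, "H3K27ac") &
    has(p2, "H3K4me3") & has(p2, "H3K27ac")
  immature <- (has(p1, "H3K4me3") | has(p1, "H3K27ac")) &
    rowSums(p2) == 0
  stable <- rowSums(p1 != p2) == 0
  transition <- rep("other", nrow(x))
  transition[stable] <- "stable"
  transition[immature] <- "immature_open"
  transition[gaining] <- "active_gaining"
  transition[bivalent] <- "bivalent_resolving"
  names(transition) <- rownames(x)
  structure(list(presence = presence, transition = transition,
                 thresholds = thresholds),
            class = "state_call")
}

#' Mean expression z-score profiles per peak cluster
#'
#' Z-scores each gene's timepoint-mean expression across timepoints, then
#' averages over the differentially expressed genes annotated to each
#' peak cluster. Genes with flat expression (zero sd) are excluded with a
#' warning; clusters with no qualifying genes are reported as all-NA rows.
#'
#' @param clusters Named peak -> cluster assignment (e.g.
#'   `cluster_differential_peaks()$cluster`).
#' @param annotation data.frame from [annotate_peaks_to_genes()].
#' @param de_genes Character vector of differentially expressed genes.
#' @param expr Gene x timepoint mean-expression matrix, timepoints in
#'   chronological order.
#' @return List: `profile` (cluster x timepoint mean z-score matrix),
#'   `n_genes` (qualifying genes per cluster).
#' @export
intersect_expression_zscores <- function(clusters, annotation, de_genes,
                                         expr) {
  z <- t(scale(t(expr)))
  flat <- rownames(expr)[!is.finite(rowSums(z))]
  if (length(flat) > 0) {
    warning(length(flat), " gene(s) with flat expression excluded",
            call. = FALSE)
  }
  ids <- sort(unique(clusters))
  profile <- matrix(NA_real_, nrow = length(ids), ncol = ncol(expr),
                    dimnames = list(as.character(ids), colnames(expr)))
  n_genes <- stats::setNames(integer(length(ids)), as.character(ids))
  gene_of <- stats::setNames(annotation$gene_id, annotation$peak_id)
  for (ci in seq_along(ids)) {
    pk <- names(clusters)[clusters == ids[ci]]
    gn <- unique(stats::na.omit(gene_of[pk]))
    gn <- intersect(intersect(gn, de_genes), rownames(z))
    gn <- setdiff(gn, flat)
    n_genes[ci] <- length(gn)
    if (length(gn) > 0) {
      profile[ci, ] <- colMeans(z[gn, , drop = FALSE])
    }
  }
  list(profile = profile, n_genes = n_genes)
}
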