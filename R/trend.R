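# Expression preprocessing and the monotonic trend classifier.
#
# The classifier consumes per-comparison differential tables (logFC, p, FDR)
# for the four neuronal-stage contrasts and applies boolean monotonicity
# rules in two stringencies: "strict" requires every transition to pass the
# FDR threshold, "relaxed" only the endpoint (d100 vs d25) contrast.

MONO_COMPARISONS <- c("d50_vs_d25", "d75_vs_d50", "d100_vs_d50",
                      "d100_vs_d25")

#' Convert counts to RPKM
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `counts / (length_kb * total_counts / 1e6)`, computed per sample.
#'
#' @param tc An `expression_timecourse` (see
#'   [simulate_expression_timecourse()]), or any list with `counts`
#'   (gene x sample matrix) and `gene_lengths` (named bp vector).
#' @return A gene x sample numeric matrix of RPKM values.
#' @examples
#' tc <- list(counts = matrix(100, 1, 1, dimnames = list("g", "s")),
#'            gene_lengths = c(g = 2000))
#' compute_rpkm(tc)  # 100 / (2 * 10^-4) ... with a 100-read library
#' @export
compute_rpkm <- function(tc) {
  counts <- tc$counts
  lens <- tc$gene_lengths[rownames(counts)]
  if (anyNA(lens) || any(lens <= 0)) {
    bad <- rownames(counts)[is.na(lens) | lens <= 0][1]
    stop(sprintf("gene '%s' has missing or non-positive length", bad),
         call. = FALSE)
  }
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop(sprintf("sample '%s' has zero total counts",
                 colnames(counts)[totals <= 0][1]), call. = FALSE)
  }
  sweep(counts / (lens / 1e3), 2, totals / 1e6, "/")
}

#' Filter genes by an RPKM presence threshold
#'
#' A gene is "present" in a sample when its RPKM reaches `threshold`
#' (default 1); genes present in at least one sample are retained, in their
#' input order.
#'
#' @param rpkm Gene x sample RPKM matrix.
#' @param threshold Presence threshold in RPKM units (>= 0).
#' @return Character vector of retained gene ids.
#' @export
presence_filter <- function(rpkm, threshold = 1) {
  check_scalar_num(threshold, "threshold", lower = 0)
  if (any(!is.finite(rpkm))) {
    stop("`rpkm` must be finite", call. = FALSE)
  }
  rownames(rpkm)[apply(rpkm, 1, max) >= threshold]
}

#' Differential expression between two sample groups (stand-in test)
#'
#' A deliberately simple replacement for a full negative-binomial
#' differential pipeline: log fold change is the difference of group means
#' of `log2(RPKM + 1)`, the p-value a two-sample Welch t-test on the same
#' values, and FDR Benjamini-Hochberg across genes. Externally produced
#' differential tables (e.g. from DESeq2) can be used everywhere this
#' output is consumed; see [classify_monotonic()].
#'
#' @param tc An `expression_timecourse`.
#' @param groupA,groupB Disjoint character vectors of sample ids, each with
#'   at least 2 samples. `logFC > 0` means higher in `groupA`.
#' @param comparison Optional label stored on the result.
#' @return A `de_table` data.frame: `gene`, `logFC`, `pvalue`, `fdr`, with
#'   the comparison label as attribute `comparison`.
#' @export
naive_differential <- function(tc, groupA, groupB, comparison = NULL) {
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  if (length(intersect(groupA, groupB)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  rpkm <- compute_rpkm(tc)
  missing <- setdiff(c(groupA, groupB), colnames(rpkm))
  if (length(missing) > 0) {
    stop(sprintf("unknown samples: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  # zero variance in both groups: identical means are uninformative
  # (p = 1), different means a certain difference under this naive model
  welch_log2_table(log2(rpkm[, groupA, drop = FALSE] + 1),
                   log2(rpkm[, groupB, drop = FALSE] + 1), comparison)
}

#' Differential test on an already-normalized signal matrix
#'
#' The same Welch-on-log2 stand-in as [naive_differential()], but applied
#' directly to values that are already depth-normalized (e.g. a peak x
#' sample fragment matrix from [normalize_depth()]), skipping the RPKM
#' transform that only makes sense for gene counts.
#'
#' @param x Feature x sample numeric matrix of normalized values, or a
#'   `signal_matrix` from [normalize_depth()].
#' @param groupA,groupB Disjoint sample-id vectors, each >= 2 samples.
#'   `logFC > 0` means higher in `groupA`.
#' @param comparison Optional label stored on the result.
#' @return A `de_table` data.frame (`gene` holds the feature ids).
#' @export
naive_differential_signal <- function(x, groupA, groupB,
                                      comparison = NULL) {
  if (inherits(x, "signal_matrix")) x <- x$normalized
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  if (length(intersect(groupA, groupB)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(groupA, groupB), colnames(x))
  if (length(missing) > 0) {
    stop(sprintf("unknown samples: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  welch_log2_table(log2(x[, groupA, drop = FALSE] + 1),
                   log2(x[, groupB, drop = FALSE] + 1), comparison)
}

# Shared Welch-test core over two log2-scale matrices with common rows.
welch_log2_table <- function(la, lb, comparison) {
  ma <- rowMeans(la)
  mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var)
  vb <- apply(lb, 1, stats::var)
  pv <- vapply(seq_len(nrow(la)), function(i) {
    if (va[i] == 0 && vb[i] == 0) {
      return(if (ma[i] == mb[i]) 1 else 0)
    }
    stats::t.test(la[i, ], lb[i, ], var.equal = FALSE)$p.value
  }, numeric(1))
  res <- data.frame(gene = rownames(la), logFC = ma - mb, pvalue = pv,
                    fdr = stats::p.adjust(pv, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "comparison") <- comparison
  class(res) <- c("de_table", class(res))
  res
}

#' Run the four neuronal-stage differential contrasts
#'
#' Convenience wrapper producing the comparison set the monotonic
#' classifier consumes (`d50_vs_d25`, `d75_vs_d50`, `d100_vs_d50`,
#' `d100_vs_d25`) within one treatment arm.
#'
#' @param tc An `expression_timecourse`.
#' @param treatment Treatment arm to use (default `"DMSO"`).
#' @param genes Optional gene subset (e.g. from [presence_filter()]).
#' @return Named list of `de_table`s keyed by comparison.
#' @export
stage_contrasts <- function(tc, treatment = "DMSO", genes = NULL) {
  meta <- tc$samples
  grp <- function(tp) meta$sample[meta$timepoint == tp &
                                  meta$treatment == treatment]
  tc_use <- tc
  if (!is.null(genes)) {
    tc_use$counts <- tc_use$counts[genes, , drop = FALSE]
  }
  pairs <- list(d50_vs_d25 = c("d50", "d25"), d75_vs_d50 = c("d75", "d50"),
                d100_vs_d50 = c("d100", "d50"),
                d100_vs_d25 = c("d100", "d25"))
  lapply(stats::setNames(names(pairs), names(pairs)), function(nm) {
    naive_differential(tc_use, grp(pairs[[nm]][1]), grp(pairs[[nm]][2]),
                       comparison = nm)
  })
}

# Align the four comparison tables on the union gene universe, returning a
# list of per-quantity matrices with NA where a gene is absent.
align_de_tables <- function(de) {
  need <- setdiff(MONO_COMPARISONS, names(de))
  if (length(need) > 0) {
    stop(sprintf("missing comparison table(s): %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  genes <- unique(unlist(lapply(de[MONO_COMPARISONS], `[[`, "gene")))
  pull_mat <- function(what) {
    m <- vapply(de[MONO_COMPARISONS], function(tab) {
      stats::setNames(tab[[what]], tab$gene)[genes]
    }, numeric(length(genes)))
    if (is.null(dim(m))) {             # single-gene universe
      m <- matrix(m, nrow = length(genes),
                  dimnames = list(genes, MONO_COMPARISONS))
    }
    m
  }
  list(genes = genes, logFC = pull_mat("logFC"), fdr = pull_mat("fdr"))
}

#' Classify genes as monotonically regulated across the neuronal window
#'
#' Applies the boolean monotonicity rules over the four stage contrasts.
#' With `1 = d50 vs d25`, `2 = d75 vs d50`, `3 = d100 vs d50`,
#' `4 = d100 vs d25` and FDR threshold `t` (default 0.05, inclusive):
#' \describe{
#'   \item{up, strict}{`fdr1 <= t & fdr4 <= t & fdr3 <= t & logFC1 > 0 &
#'     logFC2 > 0 & logFC4 > logFC1`}
#'   \item{up, relaxed}{`fdr4 <= t & logFC1 > 0 &
#'     (logFC4 >= logFC1 | logFC2 > 0)`}
#' }
#' Down rules mirror every sign. Strict implies relaxed. Genes missing
#' from any comparison table (or with missing values) are labelled
#' negative rather than erroring, tolerating independent per-contrast
#' filtering.
#'
#' @param de Named list of `de_table`s (columns `gene`, `logFC`, `fdr`)
#'   keyed `d50_vs_d25`, `d75_vs_d50`, `d100_vs_d50`, `d100_vs_d25`, e.g.
#'   from [stage_contrasts()] or read from external differential output.
#' @param direction `"up"` or `"down"`.
#' @param mode `"strict"` or `"relaxed"`.
#' @param fdr_threshold Significance threshold applied inclusively.
#' @return Named logical vector over the union gene universe.
#' @seealso [trend_labels()] for the combined five-way labelling.
#' @export
classify_monotonic <- function(de, direction = c("up", "down"),
                               mode = c("strict", "relaxed"),
                               fdr_threshold = 0.05) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  check_scalar_num(fdr_threshold, "fdr_threshold", lower = 0, upper = 1)
  al <- align_de_tables(de)
  s <- if (direction == "up") 1 else -1
  lfc <- s * al$logFC              # mirrored rules: flip signs once
  fdr <- al$fdr
  t <- fdr_threshold
  res <- if (mode == "strict") {
    fdr[, 1] <= t & fdr[, 4] <= t & fdr[, 3] <= t &
      lfc[, 1] > 0 & lfc[, 2] > 0 & lfc[, 4] > lfc[, 1]
  } else {
    fdr[, 4] <= t & lfc[, 1] > 0 & (lfc[, 4] >= lfc[, 1] | lfc[, 2] > 0)
  }
  res[is.na(res)] <- FALSE
  stats::setNames(res, al$genes)
}

#' Five-way monotonic trend labels
#'
#' Combines [classify_monotonic()] calls into one label per gene:
#' `mono_up_strict`, `mono_up_relaxed` (relaxed but not strict),
#' `mono_down_strict`, `mono_down_relaxed`, or `none`. Up and down labels
#' are mutually exclusive by construction (they require opposite signs of
#' the d50-vs-d25 log fold change).
#'
#' @inheritParams classify_monotonic
#' @return data.frame with columns `gene`, `label`.
#' @export
trend_labels <- function(de, fdr_threshold = 0.05) {
  us <- classify_monotonic(de, "up", "strict", fdr_threshold)
  ur <- classify_monotonic(de, "up", "relaxed", fdr_threshold)
  ds <- classify_monotonic(de, "down", "strict", fdr_threshold)
  dr <- classify_monotonic(de, "down", "relaxed", fdr_threshold)
  label <- rep("none", length(us))
  label[dr] <- "mono_down_relaxed"
  label[ds] <- "mono_down_strict"
  label[ur] <- "mono_up_relaxed"
  label[us] <- "mono_up_strict"
  data.frame(gene = names(us), label = label, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select robust maturation marker genes
#'
#' Among trend-labelled genes, retains those with (i) maximum absolute log
#' fold change above `logfc_min` in any of the four stage contrasts,
#' (ii) maximum timepoint-mean expression above `rpkm_min`, and
#' (iii) standard error of the mean at the final timepoint strictly below
#' `sem_max`.
#'
#' @param labels data.frame from [trend_labels()].
#' @param rpkm Gene x sample RPKM matrix.
#' @param de Named list of the four stage-contrast `de_table`s.
#' @param sem_d100 Named numeric: per-gene s.e.m. of RPKM at the final
#'   timepoint. Required for every labelled candidate.
#' @param samples Optional sample metadata (`sample`, `timepoint`); when
#'   given, expression is averaged per timepoint before the `rpkm_min`
#'   test, otherwise columns are treated as timepoints.
#' @param logfc_min,rpkm_min,sem_max Filter thresholds (logFC and RPKM
#'   bounds are exclusive: `> logfc_min`, `> rpkm_min`, `< sem_max`).
#' @return Character vector of marker gene ids.
#' @export
select_marker_genes <- function(labels, rpkm, de, sem_d100, samples = NULL,
                                logfc_min = 1, rpkm_min = 5, sem_max = 1) {
  cand <- labels$gene[labels$label != "none"]
  if (length(cand) == 0) return(character())
  missing_sem <- setdiff(cand, names(sem_d100))
  if (length(missing_sem) > 0) {
    stop(sprintf("missing s.e.m. for gene(s): %s",
                 paste(utils::head(missing_sem, 5), collapse = ", ")),
         call. = FALSE)
  }
  al <- align_de_tables(de)
  maxlfc <- apply(abs(al$logFC), 1, max)[match(cand, al$genes)]
  expr <- rpkm[cand, , drop = FALSE]
  if (!is.null(samples)) {
    tps <- unique(samples$timepoint)
    expr <- vapply(tps, function(tp) {
      rowMeans(rpkm[cand, samples$sample[samples$timepoint == tp],
                    drop = FALSE])
    }, numeric(length(cand)))
    if (is.null(dim(expr))) expr <- matrix(expr, nrow = length(cand))
  }
  peak <- apply(expr, 1, max)
  keep <- !is.na(maxlfc) & maxlfc > logfc_min & peak > rpkm_min &
    sem_d100[cand] < sem_max
  cand[keep]
}
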