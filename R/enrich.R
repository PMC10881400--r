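# Hypergeometric motif enrichment of peak groups against the atlas, with
# the odds-ratio and transcription-factor-expression filters.

#' Hypergeometric motif enrichment of a peak group against the atlas
#'
#' For each motif, with `N` atlas peaks of which `K` carry the motif, and
#' a group of `n` peaks of which `k` carry it: the foreground ratio is
#' `k/n`, the background ratio `K/N`, the odds ratio their quotient, and
#' the p-value the upper-tail hypergeometric probability `P(X >= k)`
#' (enrichment only). FDR is Benjamini-Hochberg across motifs within the
#' group.
#'
#' @param group Character vector of peak ids; must be a non-empty subset
#'   of `atlas_ids`.
#' @param atlas_ids Character vector of all atlas peak ids.
#' @param annot A `motif_annotation` (see [simulate_motif_annotation()]) or
#'   a data.frame with columns `peak_id`, `motif_id`.
#' @param group_label Optional label stored in the result.
#' @return An `enrichment_result` data.frame: `group`, `motif_id`, `K`,
#'   `n`, `k`, `N`, `foreground_ratio`, `background_ratio`, `odds_ratio`,
#'   `pvalue`, `fdr`.
#' @examples
#' ann <- data.frame(peak_id = paste0("p", 1:20), motif_id = "M001")
#' motif_enrichment(paste0("p", 1:10), paste0("p", 1:100), ann)
#' @export
motif_enrichment <- function(group, atlas_ids, annot, group_label = "group") {
  ann <- if (inherits(annot, "motif_annotation")) annot$peaks else annot
  if (length(group) == 0) stop("`group` is empty", call. = FALSE)
  outside <- setdiff(group, atlas_ids)
  if (length(outside) > 0) {
    stop(sprintf("group peak(s) not in atlas: %s",
                 paste(utils::head(outside, 5), collapse = ", ")),
         call. = FALSE)
  }
  ann <- ann[ann$peak_id %in% atlas_ids, , drop = FALSE]
  motifs <- sort(unique(ann$motif_id))
  if (length(motifs) == 0) {
    res <- data.frame(group = character(), motif_id = character(),
                      K = integer(), n = integer(), k = integer(),
                      N = integer(), foreground_ratio = numeric(),
                      background_ratio = numeric(), odds_ratio = numeric(),
                      pvalue = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
    class(res) <- c("enrichment_result", class(res))
    return(res)
  }
  N <- length(atlas_ids)
  n <- length(group)
  by_motif <- split(ann$peak_id, ann$motif_id)
  res <- do.call(rbind, lapply(motifs, function(m) {
    carriers <- unique(by_motif[[m]])
    K <- length(carriers)
    k <- length(intersect(carriers, group))
    data.frame(group = group_label, motif_id = m, K = K, n = n, k = k,
               N = N,
               foreground_ratio = k / n,
               background_ratio = K / N,
               odds_ratio = if (K > 0) (k / n) / (K / N) else NA_real_,
               pvalue = stats::phyper(k - 1, K, N - K, n,
                                      lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$pvalue, method = "BH")
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Filter enriched motifs by odds ratio and factor expression
#'
#' Retains (group, motif) rows whose odds ratio reaches `or_min`
#' (inclusive) and whose motif maps to at least one transcription factor
#' expressed at `rpkm_min` or more in neurons at any timepoint. Results
#' are ranked by decreasing odds ratio, ties broken by ascending p-value
#' then motif id. Raising either threshold can only shrink the result.
#'
#' @param res An `enrichment_result`.
#' @param motif_tf data.frame mapping `motif_id` to `tf_gene`. Motifs with
#'   no mapped factor are dropped with a warning.
#' @param tf_rpkm Gene x timepoint RPKM matrix for the factors.
#' @param neuron_timepoints Columns of `tf_rpkm` counted as neuronal
#'   stages; defaults to the intersection with `d25, d50, d75, d100`
#'   (all columns if none match).
#' @param or_min Minimum odds ratio (inclusive).
#' @param rpkm_min Minimum factor RPKM (inclusive).
#' @return The filtered, ranked `enrichment_result` with extra columns
#'   `tf_gene` (first qualifying factor) and `tf_max_rpkm`.
#' @export
filter_enriched_motifs <- function(res, motif_tf, tf_rpkm,
                                   neuron_timepoints = NULL,
                                   or_min = 1.2, rpkm_min = 1) {
  check_scalar_num(or_min, "or_min", lower = 0)
  check_scalar_num(rpkm_min, "rpkm_min", lower = 0)
  if (is.null(neuron_timepoints)) {
    neuron_timepoints <- intersect(c("d25", "d50", "d75", "d100"),
                                   colnames(tf_rpkm))
    if (length(neuron_timepoints) == 0) {
      neuron_timepoints <- colnames(tf_rpkm)
    }
  }
  unmapped <- setdiff(res$motif_id, motif_tf$motif_id)
  if (length(unmapped) > 0) {
    warning(length(unmapped), " motif(s) without a mapped factor dropped",
            call. = FALSE)
    res <- res[!res$motif_id %in% unmapped, , drop = FALSE]
  }
  tf_info <- t(vapply(res$motif_id, function(m) {
    tfs <- intersect(motif_tf$tf_gene[motif_tf$motif_id == m],
                     rownames(tf_rpkm))
    if (length(tfs) == 0) {
      return(c(rpkm = NA_real_, idx = NA_real_))
    }
    vals <- apply(tf_rpkm[tfs, neuron_timepoints, drop = FALSE], 1, max)
    c(rpkm = max(vals), idx = which.max(vals))
  }, c(rpkm = 0, idx = 0)))
  res$tf_max_rpkm <- tf_info[, "rpkm"]
  res$tf_gene <- vapply(seq_len(nrow(res)), function(i) {
    m <- res$motif_id[i]
    tfs <- intersect(motif_tf$tf_gene[motif_tf$motif_id == m],
                     rownames(tf_rpkm))
    if (length(tfs) == 0) NA_character_ else tfs[tf_info[i, "idx"]]
  }, character(1))
  keep <- !is.na(res$odds_ratio) & res$odds_ratio >= or_min &
    !is.na(res$tf_max_rpkm) & res$tf_max_rpkm >= rpkm_min
  out <- res[keep, , drop = FALSE]
  out <- out[order(-out$odds_ratio, out$pvalue, out$motif_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
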