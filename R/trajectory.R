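# Sample-level trajectory analysis: variance stabilization, PCA embedding,
# condition centroids, the dot-product maturation score, correlation
# clustering and redundancy-stopped k-means profiling.

#' Variance-stabilizing transform (median-of-ratios + log2)
#'
#' Normalizes counts by median-of-ratios size factors (the reference is the
#' per-gene geometric mean over samples, excluding genes with any zero
#' count from the reference set) and returns `log2(normalized + 1)`. A
#' simple, monotone stabilization suitable for embeddings that are compared
#' within one dataset.
#'
#' @param counts Non-negative gene x sample count matrix.
#' @return List with `vst` (transformed matrix) and `size_factors`.
#' @export
variance_stabilize <- function(counts) {
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  logs <- log(counts)
  ref <- rowMeans(logs)            # -Inf for genes with any zero count
  use <- is.finite(ref)
  if (!any(use)) {
    stop("no gene has all-positive counts; cannot form the size-factor reference",
         call. = FALSE)
  }
  sf <- apply(logs[use, , drop = FALSE], 2, function(lc) {
    exp(stats::median(lc - ref[use]))
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    bad <- colnames(counts)[!is.finite(sf) | sf <= 0][1]
    stop(sprintf("degenerate size factor for sample '%s'", bad),
         call. = FALSE)
  }
  list(vst = log2(sweep(counts, 2, sf, "/") + 1), size_factors = sf)
}

#' Embed samples in PCA space
#'
#' Centers each selected gene across samples and decomposes by SVD. The
#' first three components are retained for trajectory scoring. Each
#' component's sign is fixed by making its largest-magnitude gene loading
#' positive, so embeddings are fully deterministic.
#'
#' @param vst Gene x sample matrix (typically `variance_stabilize()$vst`).
#' @param top_n Number of genes to use when `selection = "by_variance"`.
#' @param selection Either `"by_variance"` (top `top_n` genes by variance
#'   across samples) or a character vector of gene ids (e.g. a
#'   differential-expression-derived list).
#' @return An `embedding_result`: `coordinates` (sample x PC1..3 matrix),
#'   `explained_variance` (all components), `selected_genes`, `rotation`.
#' @export
embed_pca <- function(vst, top_n = 1000, selection = "by_variance") {
  if (ncol(vst) < 4) {
    stop("need >= 4 samples for a 3-component embedding", call. = FALSE)
  }
  if (identical(selection, "by_variance")) {
    v <- apply(vst, 1, stats::var)
    genes <- rownames(vst)[order(v, decreasing = TRUE)]
    genes <- genes[seq_len(min(top_n, length(genes)))]
  } else {
    genes <- intersect(selection, rownames(vst))
    if (length(genes) == 0) stop("no selected genes found", call. = FALSE)
  }
  x <- vst[genes, , drop = FALSE]
  x <- x - rowMeans(x)
  sv <- svd(t(x))                       # samples x genes
  ev <- sv$d^2 / sum(sv$d^2)
  k <- min(3, length(sv$d))
  rot <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  if (k < 3) coords <- cbind(coords, matrix(0, nrow(coords), 3 - k))
  dimnames(coords) <- list(colnames(vst), c("PC1", "PC2", "PC3"))
  rownames(rot) <- genes
  structure(list(coordinates = coords, explained_variance = ev,
                 selected_genes = genes, rotation = rot),
            class = "embedding_result")
}

#' Average replicate coordinates into per-condition centroids
#'
#' @param emb An `embedding_result` (or any sample x PC coordinate matrix).
#' @param meta data.frame with `sample`, `treatment`, `timepoint`.
#' @return Matrix: one row per condition (`treatment.timepoint` rownames,
#'   with `treatment` and `timepoint` attributes), columns PC1..PC3.
#' @export
condition_centroids <- function(emb, meta) {
  coords <- if (inherits(emb, "embedding_result")) emb$coordinates else emb
  missing <- setdiff(rownames(coords), meta$sample)
  if (length(missing) > 0) {
    stop(sprintf("samples without metadata: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  m <- meta[match(rownames(coords), meta$sample), ]
  key <- paste(m$treatment, m$timepoint, sep = ".")
  cent <- t(vapply(split(seq_len(nrow(coords)), key), function(idx) {
    colMeans(coords[idx, , drop = FALSE])
  }, numeric(ncol(coords))))
  u <- !duplicated(key)
  attr(cent, "treatment") <- stats::setNames(m$treatment[u], key[u])[rownames(cent)]
  attr(cent, "timepoint") <- stats::setNames(m$timepoint[u], key[u])[rownames(cent)]
  cent
}

#' Dot-product maturation score against a control trajectory
#'
#' Sets one condition's centroid as the origin, defines each condition's
#' trajectory vector as its displacement from the origin, and scores every
#' condition by the dot product of its vector with the control condition's
#' vector (the chronological-maturation reference). The origin scores 0 and
#' the control scores the squared norm of its own vector; conditions moving
#' along the control trajectory score proportionally to how far they have
#' travelled.
#'
#' @param centroids Condition x PC matrix from [condition_centroids()].
#' @param origin Rowname of the origin condition (e.g. `"DMSO.d25"`).
#' @param control Rowname of the control condition (e.g. `"DMSO.d50"`).
#' @return data.frame: `condition`, `PC1`..`PC3` (trajectory vector),
#'   `score`.
#' @export
maturation_score <- function(centroids, origin, control) {
  for (cc in c(origin, control)) {
    if (!cc %in% rownames(centroids)) {
      stop(sprintf("condition '%s' not present in centroids", cc),
           call. = FALSE)
    }
  }
  vec <- sweep(centroids, 2, centroids[origin, ], "-")
  ctrl <- vec[control, ]
  if (sum(ctrl^2) == 0) {
    stop("control vector has zero norm; trajectory is degenerate",
         call. = FALSE)
  }
  score <- as.numeric(vec %*% ctrl)
  out <- data.frame(condition = rownames(centroids), vec,
                    score = score, stringsAsFactors = FALSE,
                    row.names = NULL)
  colnames(out)[2:(1 + ncol(vec))] <- colnames(centroids)
  out
}

#' Correlation-based hierarchical clustering of samples
#'
#' Distance is `1 - Pearson r` between sample expression profiles;
#' agglomeration uses complete linkage.
#'
#' @param expr Gene x sample matrix.
#' @param gene_subset Optional character vector restricting the genes used
#'   (e.g. maturation genes only); default all rows.
#' @return An `hclust` object.
#' @export
correlation_cluster <- function(expr, gene_subset = NULL) {
  if (!is.null(gene_subset)) {
    expr <- expr[intersect(gene_subset, rownames(expr)), , drop = FALSE]
  }
  if (ncol(expr) < 2) stop("need >= 2 samples", call. = FALSE)
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("sample '%s' has zero variance over the gene subset",
                 colnames(expr)[sds == 0][1]), call. = FALSE)
  }
  expr <- expr[, order(colnames(expr)), drop = FALSE]  # tie-stable order
  d <- stats::as.dist(1 - stats::cor(expr))
  stats::hclust(d, method = "complete")
}

#' k-means with a redundancy stopping rule
#'
#' Fits k-means for increasing k (best of `nstart` starts each) and stops
#' when clusters become redundant: some cluster holds fewer than
#' `min_frac` of the rows, or two cluster centroid profiles correlate above
#' `max_centroid_cor`. The last non-redundant solution is returned.
#'
#' @param zscores Row-profile matrix; rows are expected to be z-scored
#'   (each row mean about 0, sd about 1).
#' @param k_min,k_max Range of k to scan.
#' @param nstart Random initializations per k.
#' @param seed Integer seed (fixed seed gives a fixed partition).
#' @param min_frac Minimum cluster size as a fraction of rows.
#' @param max_centroid_cor Maximum allowed Pearson correlation between two
#'   cluster centroids.
#' @return List: `cluster` (named assignment), `centers`, `k`
#'   (chosen k), `scanned_k`.
#' @export
kmeans_redundancy <- function(zscores, k_min = 2, k_max = 10, nstart = 25,
                              seed = 1L, min_frac = 0.01,
                              max_centroid_cor = 0.95) {
  if (k_min > k_max) stop_config("k_min", "must be <= `k_max`")
  check_scalar_num(min_frac, "min_frac", lower = 0, upper = 1)
  zscores <- as.matrix(zscores)
  redundant <- function(fit, n) {
    if (any(fit$size < max(1, min_frac * n))) return(TRUE)
    if (nrow(fit$centers) >= 2 && ncol(fit$centers) >= 3) {
      cc <- suppressWarnings(stats::cor(t(fit$centers)))
      cc[!is.finite(cc)] <- 1        # constant centroids: treat as redundant
      diag(cc) <- -Inf
      if (max(cc) > max_centroid_cor) return(TRUE)
    }
    FALSE
  }
  best <- NULL
  chosen <- NA_integer_
  for (k in k_min:k_max) {
    fit <- with_seed(seed + k, {
      tryCatch(stats::kmeans(zscores, centers = k, nstart = nstart,
                             iter.max = 50),
               error = function(e) NULL)
    })
    if (is.null(fit) || redundant(fit, nrow(zscores))) {
      if (is.null(best)) {
        warning("degenerate data: redundancy at k = ", k,
                "; returning a single cluster", call. = FALSE)
        best <- list(cluster = stats::setNames(rep(1L, nrow(zscores)),
                                               rownames(zscores)),
                     centers = matrix(colMeans(zscores), nrow = 1,
                                      dimnames = list(NULL,
                                                      colnames(zscores))))
        chosen <- 1L
      }
      break
    }
    best <- list(cluster = stats::setNames(fit$cluster, rownames(zscores)),
                 centers = fit$centers)
    chosen <- k
  }
  list(cluster = best$cluster, centers = best$centers, k = chosen,
       scanned_k = k_min:k_max)
}
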