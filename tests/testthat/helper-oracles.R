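# Independent brute-force oracles used across the suite. Each evaluates
# the quantity from first principles, never through the package's own
# implementation path.

# Literal clause-by-clause evaluation of the monotonicity rules for one
# gene. Inputs indexed by comparison: 1 = d50 vs d25, 2 = d75 vs d50,
# 3 = d100 vs d50, 4 = d100 vs d25.
oracle_monotonic <- function(lfc1, lfc2, lfc3, lfc4,
                             fdr1, fdr2, fdr3, fdr4,
                             direction, mode, t = 0.05) {
  ok <- function(x) !is.na(x)
  if (direction == "up") {
    if (mode == "strict") {
      isTRUE(ok(fdr1) & fdr1 <= t) && isTRUE(ok(fdr4) & fdr4 <= t) &&
        isTRUE(ok(fdr3) & fdr3 <= t) && isTRUE(ok(lfc1) & lfc1 > 0) &&
        isTRUE(ok(lfc2) & lfc2 > 0) &&
        isTRUE(ok(lfc4) & ok(lfc1) & lfc4 > lfc1)
    } else {
      isTRUE(ok(fdr4) & fdr4 <= t) && isTRUE(ok(lfc1) & lfc1 > 0) &&
        (isTRUE(ok(lfc4) & ok(lfc1) & lfc4 >= lfc1) ||
           isTRUE(ok(lfc2) & lfc2 > 0))
    }
  } else {
    if (mode == "strict") {
      isTRUE(ok(fdr1) & fdr1 <= t) && isTRUE(ok(fdr4) & fdr4 <= t) &&
        isTRUE(ok(fdr3) & fdr3 <= t) && isTRUE(ok(lfc1) & lfc1 < 0) &&
        isTRUE(ok(lfc2) & lfc2 < 0) &&
        isTRUE(ok(lfc4) & ok(lfc1) & lfc4 < lfc1)
    } else {
      isTRUE(ok(fdr4) & fdr4 <= t) && isTRUE(ok(lfc1) & lfc1 < 0) &&
        (isTRUE(ok(lfc4) & ok(lfc1) & lfc4 <= lfc1) ||
           isTRUE(ok(lfc2) & lfc2 < 0))
    }
  }
}

# Random differential tables over a shared gene universe (logFC centered
# at 0, FDR uniform), shaped like the four stage contrasts.
random_de_tables <- function(n_genes, seed) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  comps <- c("d50_vs_d25", "d75_vs_d50", "d100_vs_d50", "d100_vs_d25")
  tabs <- lapply(comps, function(cmp) {
    data.frame(gene = genes,
               logFC = round(stats::rnorm(n_genes, 0, 1.5), 3),
               pvalue = stats::runif(n_genes),
               fdr = round(stats::runif(n_genes), 3),
               stringsAsFactors = FALSE)
  })
  names(tabs) <- comps
  tabs
}

# Exact upper-tail hypergeometric probability P(X >= k) as an explicit
# combinatorial sum of point masses.
oracle_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  if (length(j) == 0 || min(K, n) < k) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Exhaustive complete-linkage agglomeration over a distance matrix.
# Returns merge heights in order.
oracle_complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- max(d[clusters[[a]], clusters[[b]]])
        if (h < best[1]) best <- c(h, a, b)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Exhaustive Ward agglomeration: repeatedly merge the pair of clusters
# with the smallest increase in total within-cluster sum of squares.
# Returns the sequence of partitions (one per k from n-1 down to 1).
oracle_ward_partitions <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  repeat {
    if (length(clusters) == 1) break
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        ia <- clusters[[a]]; ib <- clusters[[b]]
        ma <- colMeans(x[ia, , drop = FALSE])
        mb <- colMeans(x[ib, , drop = FALSE])
        cost <- length(ia) * length(ib) / (length(ia) + length(ib)) *
          sum((ma - mb)^2)
        if (cost < best[1]) best <- c(cost, a, b)
      }
    }
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- part
  }
  partitions
}

# All-pairs peak-to-gene assignment: overlap first (ties by TSS distance
# from the peak midpoint, then gene id), otherwise nearest TSS on the
# same chromosome.
oracle_annotate <- function(atlas, genes) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  vapply(seq_len(nrow(atlas)), function(i) {
    mid <- (atlas$start[i] + atlas$end[i]) / 2
    same <- genes$chrom == atlas$chrom[i]
    ovl <- same & genes$start < atlas$end[i] & atlas$start[i] < genes$end
    pool <- if (any(ovl)) which(ovl) else which(same)
    if (length(pool) == 0) return(NA_character_)
    d <- abs(mid - tss[pool])
    genes$gene_id[pool[order(d, genes$gene_id[pool])][1]]
  }, character(1))
}

# Partition-agreement helper: TRUE when two labelings induce the same
# partition up to relabeling.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Match detected event times to truth within a tolerance (default: the
# detector's refractory period, within which events are unambiguous);
# returns counts for recall / false-discovery computation. Greedy
# one-to-one matching.
match_events <- function(detected, truth, tol_s = 1.0) {
  used <- rep(FALSE, length(truth))
  hits <- 0L
  for (t_det in detected) {
    d <- abs(truth - t_det)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(n_matched = hits, n_detected = length(detected),
       n_truth = length(truth))
}
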