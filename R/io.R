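# Readers and writers for the plain-text interchange formats (BED,
# narrowPeak, TSV, CSV, JSON, Newick).

#' Read a BED or ENCODE narrowPeak file
#'
#' Coordinates are kept in the BED convention (0-based, half-open).
#' Comment (`#`) and `track`/`browser` lines are skipped. For narrowPeak,
#' the extra columns (score, strand, signalValue, pValue, qValue, summit)
#' are preserved.
#'
#' @param path File path (tab-separated).
#' @param format `"bed"` or `"narrowPeak"`.
#' @return data.frame with `chrom`, `start`, `end`, and `name` plus the
#'   narrowPeak columns when present.
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  parse_row <- function(f, lineno) {
    if (length(f) < 3) {
      stop(sprintf("%s:%d: fewer than 3 columns", path, lineno),
           call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
      stop(sprintf("%s:%d: non-integer coordinates", path, lineno),
           call. = FALSE)
    }
    if (s >= e || s < 0) {
      stop(sprintf("%s:%d: invalid interval %s:%s-%s", path, lineno,
                   f[1], f[2], f[3]), call. = FALSE)
    }
    NULL
  }
  for (i in seq_along(fields)) parse_row(fields[[i]], idx[i])
  ncols <- lengths(fields)
  get <- function(j, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= j) f[j] else default,
           character(1))
  }
  out <- data.frame(chrom = get(1),
                    start = as.integer(as.numeric(get(2))),
                    end = as.integer(as.numeric(get(3))),
                    name = get(4), stringsAsFactors = FALSE)
  if (format == "narrowPeak" && all(ncols >= 10)) {
    out$score <- as.numeric(get(5))
    out$strand <- get(6)
    out$signalValue <- as.numeric(get(7))
    out$pValue <- as.numeric(get(8))
    out$qValue <- as.numeric(get(9))
    out$summit <- as.integer(as.numeric(get(10)))
  }
  out
}

#' Write intervals as BED
#'
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally a
#'   name column (`name` or `peak_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  nm <- peaks$name %||% peaks$peak_id
  df <- data.frame(peaks$chrom, peaks$start, peaks$end)
  if (!is.null(nm)) df$name <- nm
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a numeric matrix as TSV (row names in the first column)
#' @param x Matrix.
#' @param path File path.
#' @param rowname_col Header for the first column.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_matrix_tsv <- function(x, path, rowname_col = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- rowname_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read ROI fluorescence traces as CSV
#'
#' Layout: one row per frame, first column `time_s`, one column per ROI.
#' @param traces A `trace_set`.
#' @param path File path.
#' @return `path` (writer); a `trace_set` (reader).
#' @export
write_traces_csv <- function(traces, path) {
  df <- data.frame(time_s = traces$time_s, t(traces$F),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  t_s <- df[[1]]
  FF <- t(as.matrix(df[, -1, drop = FALSE]))
  dt <- stats::median(diff(t_s))
  structure(list(time_s = t_s, F = FF, frame_rate_hz = 1 / dt),
            class = "trace_set")
}

#' Export an hclust dendrogram as Newick
#'
#' @param hc An `hclust` object, e.g. from [correlation_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
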