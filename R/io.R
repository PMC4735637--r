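#' Read a sync-format pooled counts file
#'
#' Parses the tab-separated "sync" dialect used for pooled resequencing:
#' columns `chrom`, `pos` (1-based), `ref`, then one `A:T:C:G:N:del` count
#' sextuplet per sample. Malformed lines are reported with their line
#' numbers.
#'
#' @param path File path.
#' @param samples Optional sample names (default `sample1`, `sample2`, ...).
#' @return Long tibble `chrom`, `pos`, `ref`, `sample`, `A`, `T`, `C`, `G`,
#'   `N`, `del`.
#' @export
read_sync <- function(path, samples = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warn("empty sync file: returning zero sites.")
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  sample = character(), A = integer(), T = integer(),
                  C = integer(), G = integer(), N = integer(),
                  del = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (length(unique(n_col)) != 1 || n_col[1] < 4) {
    bad <- which(n_col != stats::na.omit(unique(n_col))[1] | n_col < 4)
    abort(paste0("malformed sync line(s): wrong column count at line(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else ""))
  }
  n_samp <- n_col[1] - 3L
  samples <- samples %||% paste0("sample", seq_len(n_samp))
  if (length(samples) != n_samp) {
    abort("`samples` must name every count column.")
  }
  mat <- do.call(rbind, fields)
  counts_parsed <- lapply(seq_len(n_samp), function(j) {
    parts <- strsplit(mat[, 3 + j], ":", fixed = TRUE)
    bad <- which(lengths(parts) != 6)
    if (length(bad)) {
      abort(paste0("malformed count sextuplet for sample '", samples[j],
                   "' at line(s) ", paste(head(bad, 5), collapse = ", ")))
    }
    cm <- matrix(as.integer(unlist(parts)), ncol = 6, byrow = TRUE)
    colnames(cm) <- c("A", "T", "C", "G", "N", "del")
    cm
  })
  purrr::map_dfr(seq_len(n_samp), function(j) {
    dplyr::bind_cols(
      tibble(chrom = mat[, 1], pos = as.integer(mat[, 2]),
             ref = toupper(mat[, 3]), sample = samples[j]),
      as_tibble(counts_parsed[[j]])
    )
  })
}

#' Write pooled counts in sync format
#'
#' Inverse of [read_sync()]: one row per site, one `A:T:C:G:N:del` column
#' per sample, no header. Round-trips losslessly through [read_sync()].
#'
#' @param counts Long pooled-counts tibble.
#' @param path Output path.
#' @param samples Column order (default: order of appearance).
#' @return `path`, invisibly.
#' @export
write_sync <- function(counts, path, samples = NULL) {
  samples <- samples %||% unique(counts$sample)
  wide <- NULL
  for (s in samples) {
    sub <- counts[counts$sample == s, ]
    sub <- sub[order(sub$chrom, sub$pos), ]
    col <- sprintf("%d:%d:%d:%d:%d:%d", sub$A, sub$T, sub$C, sub$G,
                   sub$N, sub$del)
    if (is.null(wide)) {
      wide <- tibble(chrom = sub$chrom, pos = sub$pos, ref = sub$ref)
    }
    wide[[s]] <- col
  }
  readr::write_tsv(wide, path, col_names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' Converts 1-based inclusive intervals to the 0-based half-open BED
#' convention.
#'
#' @param intervals Tibble with `start`, `end` (1-based inclusive) and
#'   optionally `chrom` and a score-like column.
#' @param path Output path.
#' @param chrom Chromosome name used when `intervals` has no `chrom` column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, chrom = "X") {
  bed <- tibble(
    chrom = if ("chrom" %in% names(intervals)) intervals$chrom else chrom,
    start = as.integer(intervals$start - 1L),
    end = as.integer(intervals$end)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", progress = FALSE)
  tibble(chrom = bed$chrom, start = bed$start + 1L, end = bed$end)
}
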