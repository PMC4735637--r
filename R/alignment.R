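#' Haplotype alignment container
#'
#' A light container for an aligned set of haplotype sequences: a character
#' matrix (rows = sequences, columns = aligned sites, IUPAC nucleotides plus
#' `-` for gaps), unique sequence ids, optional per-sequence population
#' labels, an optional outgroup id (excluded from ingroup statistics), and an
#' optional annotated subregion (e.g. enhancer coordinates within the
#' alignment, 1-based inclusive).
#'
#' @param seqs Character matrix of single characters (rows = sequences), or a
#'   character vector of equal-length sequence strings.
#' @param ids Sequence identifiers (unique). Defaults to existing rownames or
#'   names.
#' @param population Optional per-sequence population labels.
#' @param outgroup Optional id of the outgroup sequence.
#' @param subregion Optional `c(start, end)` subregion annotation.
#' @return An object of class `haplo_alignment`.
#' @export
haplo_alignment <- function(seqs, ids = NULL, population = NULL,
                            outgroup = NULL, subregion = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    if (length(unique(nchar(seqs))) != 1) {
      abort("all sequences must have equal aligned length.")
    }
    ids <- ids %||% names(seqs)
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  } else {
    seqs <- toupper(as.matrix(seqs))
    ids <- ids %||% rownames(seqs)
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(seqs)))
  if (anyDuplicated(ids)) abort("sequence ids must be unique.")
  if (length(ids) != nrow(seqs)) abort("`ids` length must match sequences.")
  rownames(seqs) <- ids
  if (!is.null(outgroup) && !outgroup %in% ids) {
    abort("`outgroup` id not present in the alignment.")
  }
  if (!is.null(population) && length(population) != nrow(seqs)) {
    abort("`population` must have one label per sequence.")
  }
  if (!is.null(subregion)) {
    subregion <- as.integer(subregion[1:2])
    if (subregion[1] < 1 || subregion[2] > ncol(seqs) ||
        subregion[1] > subregion[2]) {
      abort("`subregion` must lie inside the alignment.")
    }
    names(subregion) <- c("start", "end")
  }
  structure(
    list(seqs = seqs, ids = ids,
         population = if (is.null(population)) NULL else
           setNames(as.character(population), ids),
         outgroup = outgroup, subregion = subregion),
    class = "haplo_alignment"
  )
}

#' @export
print.haplo_alignment <- function(x, ...) {
  cat("<haplo_alignment> ", length(x$ids), " sequences x ",
      ncol(x$seqs), " sites\n", sep = "")
  if (!is.null(x$outgroup)) cat("  outgroup: ", x$outgroup, "\n", sep = "")
  if (!is.null(x$subregion)) {
    cat("  subregion: ", x$subregion[1], "-", x$subregion[2], "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.matrix.haplo_alignment <- function(x, ...) x$seqs

# ids of the ingroup (outgroup dropped)
ingroup_ids <- function(aln) setdiff(aln$ids, aln$outgroup)

# TRUE where a character is an unambiguous base
is_base <- function(x) x %in% DNA_BASES

#' Read and write haplotype alignments as FASTA
#'
#' Thin wrappers around \pkg{ape}'s FASTA routines returning/accepting
#' [haplo_alignment] objects.
#'
#' @param path File path.
#' @param outgroup,population,subregion Passed to [haplo_alignment()].
#' @return `read_alignment()` returns a [haplo_alignment];
#'   `write_alignment()` returns `path` invisibly.
#' @export
read_alignment <- function(path, outgroup = NULL, population = NULL,
                           subregion = NULL) {
  dna <- ape::read.FASTA(path)
  mat <- toupper(as.character(as.matrix(dna)))
  haplo_alignment(mat, ids = labels(dna), population = population,
                  outgroup = outgroup, subregion = subregion)
}

#' @param aln A [haplo_alignment].
#' @rdname read_alignment
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$seqs, 1, paste0, collapse = "")
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", aln$ids[i]), seqs[[i]])
  }
  writeLines(lines, path)
  invisible(path)
}
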