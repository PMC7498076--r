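#' Gap-aware multi-sequence alignment of the surveyed region
#'
#' Rows are accessions, columns alignment positions over `{A,C,G,T,-,N}`.
#' `positions` maps each column to its reference coordinate (`NA` for columns
#' that exist only in inserted sequence).
#'
#' @param seqs Character vector of equal-length sequences, or a character
#'   matrix with one row per accession and single characters as entries.
#' @param labels Unique accession identifiers (defaults to names of `seqs`).
#' @param positions Optional integer vector, one per column: reference
#'   coordinate of the column (NA for insertion columns). Defaults to
#'   `1:ncol`.
#' @return An object of class `region_alignment`.
#' @export
region_alignment <- function(seqs, labels = NULL, positions = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(labels)) labels <- rownames(mat)
  } else {
    if (is.null(labels)) labels <- names(seqs)
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1L) abort("alignment rows differ in length")
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  }
  if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(mat)))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) abort("alignment labels must be unique")
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) abort(paste0("alignment contains invalid characters: ", paste(bad, collapse = ",")))
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  positions <- as.integer(positions)
  if (length(positions) != ncol(mat)) abort("positions must have one entry per column")
  rownames(mat) <- labels
  structure(
    list(mat = mat, labels = labels, positions = positions),
    class = "region_alignment"
  )
}

#' @export
print.region_alignment <- function(x, ...) {
  cat(sprintf(
    "<region_alignment> %d sequences x %d columns (%d variable)\n",
    nrow(x$mat), ncol(x$mat), n_variable_columns(x)
  ))
  invisible(x)
}

#' @export
dim.region_alignment <- function(x) dim(x$mat)

#' Number of variable (segregating) columns, ignoring gaps and N
#' @param a A [region_alignment()].
#' @return Integer count.
#' @export
n_variable_columns <- function(a) {
  sum(apply(a$mat, 2, function(col) {
    al <- unique(col[col %in% c("A", "C", "G", "T")])
    length(al) > 1L
  }))
}

#' Subset an alignment by accession labels and/or reference window
#'
#' @param a A [region_alignment()].
#' @param labels Optional labels to keep (in the given order).
#' @param window Optional length-2 vector of reference coordinates; columns
#'   whose mapped position falls in the window (insertion columns excluded)
#'   are kept.
#' @return A [region_alignment()].
#' @export
subset_alignment <- function(a, labels = NULL, window = NULL) {
  mat <- a$mat
  pos <- a$positions
  if (!is.null(labels)) {
    missing_l <- setdiff(labels, a$labels)
    if (length(missing_l)) abort(paste0("unknown labels: ", paste(missing_l, collapse = ",")))
    mat <- mat[labels, , drop = FALSE]
  }
  if (!is.null(window)) {
    keep <- !is.na(pos) & pos >= window[1] & pos <= window[2]
    mat <- mat[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  region_alignment(mat, labels = rownames(mat), positions = pos)
}

#' Tidy view of an alignment
#'
#' @param x A [region_alignment()].
#' @param ... Unused.
#' @return A tibble with columns `label`, `column`, `position`, `base`.
#' @method as_tibble region_alignment
#' @export
as_tibble.region_alignment <- function(x, ...) {
  tibble(
    label = rep(x$labels, times = ncol(x$mat)),
    column = rep(seq_len(ncol(x$mat)), each = nrow(x$mat)),
    position = rep(x$positions, each = nrow(x$mat)),
    base = as.vector(x$mat)
  )
}

#' Read an aligned FASTA into a region alignment
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param positions Optional reference coordinates of the columns.
#' @return A [region_alignment()].
#' @export
read_alignment_fasta <- function(path, positions = NULL) {
  ss <- Biostrings::readBStringSet(path)
  region_alignment(setNames(as.character(ss), names(ss)), positions = positions)
}

#' Write a region alignment as FASTA (wrapped at 60 columns)
#'
#' @param a A [region_alignment()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(a, path) {
  seqs <- apply(a$mat, 1, paste0, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- a$labels
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

aln_to_DNAbin <- function(a) {
  m <- tolower(a$mat)
  m[m == "n"] <- "n"
  ape::as.DNAbin(m)
}
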