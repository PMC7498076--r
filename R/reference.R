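#' Reference region sequence
#'
#' A thin container for the surveyed slice of a reference genome: the
#' sequence itself plus the genomic coordinate of its first base, so that all
#' interfaces can speak 1-based reference coordinates (the convention of VCF
#' and of the haplotype rule table) while the sequence is stored locally.
#'
#' @param seq Character scalar over `A`, `C`, `G`, `T`, `N`.
#' @param chrom Chromosome name.
#' @param start 1-based genomic coordinate of the first base of `seq`.
#' @return An object of class `reference_region`.
#' @export
reference_region <- function(seq, chrom = "chr6", start = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    abort("reference sequence contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(seq = seq, chrom = chrom, start = as.integer(start)),
    class = "reference_region"
  )
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf(
    "<reference_region> %s:%d-%d (%d bp)\n",
    x$chrom, x$start, x$start + nchar(x$seq) - 1L, nchar(x$seq)
  ))
  invisible(x)
}

#' @export
length.reference_region <- function(x) nchar(x$seq)

ref_end <- function(reference) reference$start + nchar(reference$seq) - 1L

#' Extract reference bases by genomic coordinate
#'
#' @param reference A [reference_region()].
#' @param start,end 1-based inclusive genomic coordinates.
#' @return Character scalar.
#' @export
ref_slice <- function(reference, start, end) {
  if (start < reference$start || end > ref_end(reference) || start > end) {
    abort(sprintf(
      "requested slice %d-%d outside reference %d-%d",
      start, end, reference$start, ref_end(reference)
    ))
  }
  substr(reference$seq, start - reference$start + 1L, end - reference$start + 1L)
}

#' Read a FASTA file into a reference region
#'
#' Coordinates may be carried in the FASTA header as `name:start` (the form
#' written by [write_fasta_reference()]); otherwise the region starts at 1.
#'
#' @param path FASTA file.
#' @return A [reference_region()].
#' @export
read_fasta_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) abort("expected a single-sequence FASTA for the reference region")
  nm <- names(ss)[1]
  chrom <- nm
  start <- 1L
  if (grepl(":", nm)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    chrom <- parts[1]
    start <- suppressWarnings(as.integer(parts[2]))
    if (is.na(start)) start <- 1L
  }
  reference_region(as.character(ss[[1]]), chrom = chrom, start = start)
}

#' Write a reference region to FASTA
#'
#' The header encodes the genomic offset as `chrom:start` so a round trip
#' preserves coordinates. Lines wrap at 60 columns.
#'
#' @param reference A [reference_region()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_reference <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference$seq)
  names(ss) <- sprintf("%s:%d", reference$chrom, reference$start)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
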