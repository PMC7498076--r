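#' Read a text SAM file into a tidy read table
#'
#' A minimal reader for headered text SAM at desk scale (Rsamtools consumes
#' only binary BAM; the screens here operate on signature-exact text SAM
#' emitted by the simulator or by `samtools view`). Reads mapped with
#' `MAPQ < mapq_min` are dropped; their retained mates are flagged
#' `mate_filtered`.
#'
#' @param path SAM file with at least one `@` header line.
#' @param mapq_min Minimum mapping quality for mapped reads (default 0, i.e.
#'   keep everything; the published phylogenetic input used 20).
#' @return A tibble with one row per retained read: `qname`, `flag`,
#'   `chrom`, `pos`, `mapq`, `cigar`, `mate_chrom`, `mate_pos`, `tlen`,
#'   `seq`, plus decoded flags `unmapped`, `mate_unmapped`, `reverse`,
#'   `mate_reverse`, `proper_pair`, `first_in_pair` and `mate_filtered`.
#' @export
read_sam <- function(path, mapq_min = 0) {
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  if (!any(hdr)) abort("SAM file has no header lines")
  body <- lines[!hdr]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(empty_reads())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    abort(sprintf("malformed SAM row (fewer than 11 fields) at body line %d",
                  which(nf < 11L)[1]))
  }
  f <- function(k) vapply(fields, `[[`, character(1), k)
  reads <- tibble(
    qname = f(1),
    flag = as.integer(f(2)),
    chrom = f(3),
    pos = as.integer(f(4)),
    mapq = as.integer(f(5)),
    cigar = f(6),
    mate_chrom = f(7),
    mate_pos = as.integer(f(8)),
    tlen = as.integer(f(9)),
    seq = f(10)
  )
  bad_cigar <- !grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", reads$cigar)
  if (any(bad_cigar)) {
    abort(sprintf("unparseable CIGAR for read '%s'",
                  reads$qname[which(bad_cigar)[1]]))
  }
  reads <- decode_flags(reads)
  dropped <- !reads$unmapped & reads$mapq < mapq_min
  dropped_key <- paste(reads$qname[dropped],
                       ifelse(reads$first_in_pair[dropped], "2", "1"))
  kept <- reads[!dropped, , drop = FALSE]
  key <- paste(kept$qname, ifelse(kept$first_in_pair, "1", "2"))
  kept$mate_filtered <- key %in% dropped_key
  kept
}

decode_flags <- function(reads) {
  fl <- reads$flag
  reads$unmapped <- bitwAnd(fl, 4L) > 0L
  reads$mate_unmapped <- bitwAnd(fl, 8L) > 0L
  reads$reverse <- bitwAnd(fl, 16L) > 0L
  reads$mate_reverse <- bitwAnd(fl, 32L) > 0L
  reads$proper_pair <- bitwAnd(fl, 2L) > 0L
  reads$first_in_pair <- bitwAnd(fl, 64L) > 0L
  reads
}

empty_reads <- function() {
  decode_flags(tibble(
    qname = character(), flag = integer(), chrom = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    mate_chrom = character(), mate_pos = integer(), tlen = integer(),
    seq = character()
  )) %>% mutate(mate_filtered = logical(0))
}

#' Write a read table as text SAM
#'
#' @param reads Read tibble as produced by [simulate_read_pairs()] or
#'   [read_sam()].
#' @param path Output file.
#' @param reference A [reference_region()] for the `@SQ` header line.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, reference) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", reference$chrom, ref_end(reference)),
    "@PG\tID:hd1survey\tPN:hd1survey"
  )
  body <- character(0)
  if (nrow(reads)) {
    body <- sprintf(
      "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
      reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
      reads$cigar, reads$mate_chrom, reads$mate_pos, reads$tlen, reads$seq
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse a CIGAR string into its operations
#'
#' @param cigar CIGAR string (`"*"` gives zero rows).
#' @return Tibble with columns `len` (integer) and `op` (character).
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(tibble(len = integer(), op = character()))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  tibble(len = lens, op = ops)
}

# reference bases consumed by an alignment
cigar_ref_span <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}
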