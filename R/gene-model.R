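#' Gene model for the surveyed locus
#'
#' Exon and CDS geometry of a (single-transcript) gene inside a surveyed
#' window, in 1-based closed genomic coordinates. The CDS intervals must be
#' contained in the exons, non-overlapping and sorted, and their total length
#' must be a whole number of codons.
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble/data frame with columns `start`, `end`.
#' @param cds Tibble/data frame with columns `start`, `end`.
#' @param region Length-2 integer vector: the surveyed window (start, end).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(chrom, strand, exons, cds, region) {
  exons <- tibble::as_tibble(exons)[, c("start", "end")]
  cds <- tibble::as_tibble(cds)[, c("start", "end")]
  check_intervals <- function(x, what) {
    if (any(x$start > x$end)) abort(sprintf("%s interval with start > end", what))
    if (nrow(x) > 1L) {
      x2 <- x[order(x$start), ]
      if (any(x2$start[-1] <= x2$end[-nrow(x2)])) {
        abort(sprintf("%s intervals overlap", what))
      }
    }
    x[order(x$start), ]
  }
  exons <- check_intervals(exons, "exon")
  cds <- check_intervals(cds, "CDS")
  # each CDS interval must lie inside some exon
  inside <- vapply(seq_len(nrow(cds)), function(i) {
    any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
  }, logical(1))
  if (!all(inside)) abort("CDS intervals must be contained in exons")
  cds_len <- sum(cds$end - cds$start + 1L)
  if (cds_len %% 3L != 0L) {
    abort(sprintf("total CDS length (%d) is not divisible by 3", cds_len))
  }
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  region <- as.integer(region)
  if (length(region) != 2L || region[1] > region[2]) abort("bad region window")
  structure(
    list(chrom = chrom, strand = strand, exons = exons, cds = cds, region = region),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s(%s) %d exon(s), CDS %d nt (%d codons), region %d-%d\n",
    x$chrom, x$strand, nrow(x$exons), cds_length(x), cds_length(x) %/% 3L,
    x$region[1], x$region[2]
  ))
  invisible(x)
}

cds_length <- function(gene) sum(gene$cds$end - gene$cds$start + 1L)

gene_span <- function(gene) c(min(gene$exons$start), max(gene$exons$end))

#' Map a genomic position to its 1-based CDS offset
#'
#' Strand-aware: on the minus strand CDS coordinates run from the rightmost
#' CDS base. Returns `NA` for positions outside the CDS.
#'
#' @param gene A [gene_model()].
#' @param pos Integer vector of genomic positions.
#' @return Integer vector of CDS offsets (NA outside CDS).
#' @export
cds_offset <- function(gene, pos) {
  cds <- gene$cds
  widths <- cds$end - cds$start + 1L
  starts0 <- cumsum(c(0L, widths[-length(widths)]))  # plus-strand prefix
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(cds))) {
    hit <- pos >= cds$start[i] & pos <= cds$end[i]
    out[hit] <- starts0[i] + (pos[hit] - cds$start[i] + 1L)
  }
  if (gene$strand == "-") {
    total <- sum(widths)
    out <- ifelse(is.na(out), NA_integer_, total - out + 1L)
  }
  out
}

#' Classify genomic positions into gene compartments
#'
#' Compartments are `CDS`, `intron`, `UTR` (exonic non-coding), `upstream`
#' and `downstream`, relative to the gene's strand.
#'
#' @param gene A [gene_model()].
#' @param pos Integer vector of genomic positions.
#' @return Character vector of compartments.
#' @export
gene_compartment <- function(gene, pos) {
  span <- gene_span(gene)
  in_exon <- vapply(pos, function(p) any(p >= gene$exons$start & p <= gene$exons$end), logical(1))
  in_cds <- vapply(pos, function(p) any(p >= gene$cds$start & p <= gene$cds$end), logical(1))
  out <- character(length(pos))
  out[in_cds] <- "CDS"
  out[in_exon & !in_cds] <- "UTR"
  inside <- pos >= span[1] & pos <= span[2]
  out[inside & !in_exon] <- "intron"
  before <- pos < span[1]
  after <- pos > span[2]
  if (gene$strand == "+") {
    out[before] <- "upstream"; out[after] <- "downstream"
  } else {
    out[before] <- "downstream"; out[after] <- "upstream"
  }
  out
}

#' Read a gene model from a GFF3 file
#'
#' Consumes the gene/exon/CDS subset of GFF3 written by
#' [write_gene_model()] (or any GFF3 carrying one gene with those feature
#' types). The surveyed region is taken from a `region` feature when present,
#' else from the gene span.
#'
#' @param path GFF3 file.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  pick <- function(t) {
    g <- gr[typ == t]
    tibble(start = GenomicRanges::start(g), end = GenomicRanges::end(g))
  }
  gene_row <- gr[typ == "gene"]
  if (length(gene_row) != 1L) abort("expected exactly one gene feature in GFF3")
  region_row <- gr[typ == "region"]
  region <- if (length(region_row) == 1L) {
    c(GenomicRanges::start(region_row), GenomicRanges::end(region_row))
  } else {
    c(GenomicRanges::start(gene_row), GenomicRanges::end(gene_row))
  }
  gene_model(
    chrom = as.character(GenomicRanges::seqnames(gene_row))[1],
    strand = as.character(GenomicRanges::strand(gene_row))[1],
    exons = pick("exon"),
    cds = pick("CDS"),
    region = region
  )
}

#' Write a gene model as GFF3
#'
#' @param gene A [gene_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(gene, path) {
  span <- gene_span(gene)
  rows <- dplyr::bind_rows(
    tibble(type = "region", start = gene$region[1], end = gene$region[2]),
    tibble(type = "gene", start = span[1], end = span[2]),
    tibble(type = "exon", start = gene$exons$start, end = gene$exons$end),
    tibble(type = "CDS", start = gene$cds$start, end = gene$cds$end)
  )
  widths <- gene$cds$end - gene$cds$start + 1L
  before <- cumsum(c(0L, widths[-length(widths)]))
  if (gene$strand == "-") {
    before <- rev(cumsum(c(0L, rev(widths)[-length(widths)])))
  }
  phase <- rep(NA_integer_, nrow(rows))
  phase[rows$type == "CDS"] <- (3L - before %% 3L) %% 3L
  gr <- GenomicRanges::GRanges(
    seqnames = gene$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = gene$strand,
    type = rows$type,
    source = "hd1survey",
    phase = phase
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
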