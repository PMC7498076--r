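#' Read a VCF file into a tidy variant table
#'
#' Parsing is delegated to `VariantAnnotation::readVcf()`; this wrapper then
#' flattens to one row per ALT allele (multi-allelic sites are split), and
#' interprets per-sample `GT`/`GQ`/`AD` into the genotype classes and
#' quality fields the downstream filters need. Missing FORMAT subfields are
#' recorded as `NA` (with a warning), not treated as errors: the
#' high-quality-SNP filter later fails them conservatively.
#'
#' @param path VCF (v4.x) file.
#' @param sample Sample name to extract. May be omitted for single-sample
#'   files; an error is raised for multi-sample files with no selector.
#' @param accession Accession label to stamp on the rows (defaults to the
#'   sample name).
#' @return A tibble with columns `accession`, `chrom`, `pos`, `ref`, `alt`,
#'   `genotype` (`hom_ref`/`het`/`hom_alt`/`missing`), `gq`, `ad_alt`.
#' @export
read_vcf <- function(path, sample = NULL, accession = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  if (length(samples) == 0L) abort("VCF carries no sample columns")
  if (is.null(sample)) {
    if (length(samples) > 1L) {
      abort("multi-sample VCF: name the sample to extract via `sample=`")
    }
    sample <- samples[1]
  }
  if (!sample %in% samples) abort(sprintf("sample '%s' not in VCF", sample))
  si <- match(sample, samples)
  if (is.null(accession)) accession <- sample

  n <- length(vcf)
  if (n == 0L) return(empty_variants())

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)  # DNAStringSetList
  g <- VariantAnnotation::geno(vcf)
  has_gt <- "GT" %in% names(g)
  has_gq <- "GQ" %in% names(g)
  has_ad <- "AD" %in% names(g)
  if (!has_gt || !has_gq || !has_ad) {
    warn(paste0("FORMAT fields absent in VCF: ",
                paste(setdiff(c("GT", "GQ", "AD"), names(g)), collapse = ","),
                " (set to missing)"))
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    alt_i <- as.character(alts[[i]])
    alt_i <- alt_i[!alt_i %in% c("", ".")]
    if (length(alt_i) == 0L) next
    gt <- if (has_gt) as.character(g$GT[i, si]) else NA_character_
    gq <- if (has_gq) suppressWarnings(as.numeric(g$GQ[i, si])) else NA_real_
    ad <- if (has_ad) g$AD[[i, si]] else NULL
    alleles <- if (!is.na(gt) && gt != ".") strsplit(gt, "[/|]")[[1]] else c(".", ".")
    rows <- lapply(seq_along(alt_i), function(j) {
      geno <- classify_genotype(alleles, j)
      ad_alt <- if (!is.null(ad) && length(ad) >= j + 1L) {
        suppressWarnings(as.numeric(ad[j + 1L]))
      } else NA_real_
      tibble(
        accession = accession, chrom = chrom[i], pos = as.integer(pos[i]),
        ref = refs[i], alt = alt_i[j], genotype = geno, gq = gq, ad_alt = ad_alt
      )
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty_variants() else res
}

empty_variants <- function() {
  tibble(
    accession = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), genotype = character(),
    gq = numeric(), ad_alt = numeric()
  )
}

classify_genotype <- function(alleles, j) {
  if (any(alleles == ".")) return("missing")
  a <- suppressWarnings(as.integer(alleles))
  if (any(is.na(a))) return("missing")
  hits <- sum(a == j)
  if (hits == length(a) && length(a) > 0L) "hom_alt"
  else if (hits > 0L) "het"
  else if (all(a == 0L)) "hom_ref"
  else "hom_ref"  # homozygous for a different alt: not this allele
}

#' Write a tidy variant table as single-sample VCF v4.2
#'
#' Inverse of [read_vcf()] on the fields the pipeline carries: `GT:GQ:AD`
#' FORMAT with the reference depth written as 0 (it is not tracked).
#'
#' @param variants Variant tibble (see [read_vcf()]).
#' @param path Output file.
#' @param sample Sample column name (defaults to the accession).
#' @param reference Optional [reference_region()], used for the contig header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample = NULL, reference = NULL) {
  if (is.null(sample)) {
    sample <- if (nrow(variants) && "accession" %in% names(variants)) {
      variants$accession[1]
    } else "sample1"
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=hd1survey",
    if (!is.null(reference)) {
      sprintf("##contig=<ID=%s,length=%d>", reference$chrom, ref_end(reference))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  body <- character(0)
  if (nrow(variants)) {
    v <- dplyr::arrange(variants, .data$pos)
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:GQ:AD\t%s:%s:%s",
      v$chrom, v$pos, v$ref, v$alt,
      gt_map[v$genotype],
      ifelse(is.na(v$gq), ".", format(v$gq, trim = TRUE, scientific = FALSE)),
      ifelse(is.na(v$ad_alt), ".,.", paste0("0,", format(v$ad_alt, trim = TRUE)))
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Normalize variant records against the reference
#'
#' Indels are parsimony-trimmed and left-aligned to their leftmost
#' equivalent representation (the VCF anchor-base convention is preserved);
#' SNPs pass through unchanged. The operation is idempotent. An error is
#' raised when a record's REF allele disagrees with the reference sequence.
#'
#' @param variants Variant tibble.
#' @param reference A [reference_region()].
#' @return The tibble with `pos`, `ref`, `alt` normalized.
#' @export
normalize_variants <- function(variants, reference) {
  if (nrow(variants) == 0L) return(variants)
  fixed <- purrr::pmap(
    list(variants$pos, variants$ref, variants$alt),
    function(pos, ref, alt) normalize_one(pos, ref, alt, reference)
  )
  variants$pos <- purrr::map_int(fixed, "pos")
  variants$ref <- purrr::map_chr(fixed, "ref")
  variants$alt <- purrr::map_chr(fixed, "alt")
  variants
}

normalize_one <- function(pos, ref, alt, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  observed <- ref_slice(reference, pos, pos + nchar(ref) - 1L)
  if (observed != ref) {
    abort(sprintf("REF allele '%s' at %d disagrees with reference '%s'",
                  ref, pos, observed))
  }
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(pos = as.integer(pos), ref = ref, alt = alt))
  }
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    if (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
      if (length(r) == 0L || length(a) == 0L) {
        if (pos == reference$start) {
          abort("indel abuts the start of the reference region; cannot left-align")
        }
        pos <- pos - 1L
        b <- strsplit(ref_slice(reference, pos, pos), "")[[1]]
        r <- c(b, r); a <- c(b, a)
      }
    } else if (length(r) >= 2L && length(a) >= 2L && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos <- pos + 1L
    } else {
      break
    }
  }
  list(pos = as.integer(pos), ref = paste0(r, collapse = ""),
       alt = paste0(a, collapse = ""))
}

#' Keep only high-quality homozygous-alternate calls
#'
#' The published screen keeps a call only when it is (1) homozygous for the
#' alternate allele, (2) has genotype quality strictly above `min_gq` and
#' (3) alternate-allele depth strictly above `min_ad`. Records with missing
#' genotype, GQ or AD fail the filter (they are dropped, not errors). Row
#' order is preserved and the filter is idempotent.
#'
#' @param variants Variant tibble.
#' @param min_gq Genotype-quality threshold (default 20; strict `>`).
#' @param min_ad Alternate-depth threshold (default 4; strict `>`).
#' @return Filtered tibble.
#' @export
filter_high_quality <- function(variants, min_gq = 20, min_ad = 4) {
  keep <- !is.na(variants$genotype) & variants$genotype == "hom_alt" &
    !is.na(variants$gq) & variants$gq > min_gq &
    !is.na(variants$ad_alt) & variants$ad_alt > min_ad
  variants[keep, , drop = FALSE]
}

#' Build a region alignment from cohort variant calls
#'
#' One row per accession: the reference slice of `region` with each
#' accession's homozygous SNPs substituted. The dialect is SNP-only:
#' sites touched by an indel are written `N` in the carrier (gaps are
#' treated as missing data downstream), as are sites with missing or
#' heterozygous genotype, so every row keeps reference length.
#'
#' @param variants Variant tibble with an `accession` column (normally
#'   normalized and passed through [filter_high_quality()], except for the
#'   missing-genotype rows one wishes to mask as `N`).
#' @param reference A [reference_region()].
#' @param region Length-2 vector, 1-based inclusive window.
#' @param accessions Labels for the rows; defaults to the accessions present
#'   in `variants`. Accessions with no variants get a pure-reference row.
#' @return A [region_alignment()] whose `positions` are genomic coordinates.
#' @export
vcf_to_alignment <- function(variants, reference, region,
                             accessions = NULL) {
  if (is.null(accessions)) accessions <- unique(variants$accession)
  if (length(accessions) == 0L) abort("no accessions to align")
  width <- region[2] - region[1] + 1L
  refrow <- strsplit(ref_slice(reference, region[1], region[2]), "")[[1]]
  rows <- matrix(rep(refrow, length(accessions)),
                 nrow = length(accessions), byrow = TRUE)
  rownames(rows) <- accessions
  if (nrow(variants)) {
    inside <- variants$pos >= region[1] & variants$pos <= region[2]
    if (any(!inside)) {
      warn(sprintf("%d variant(s) outside region skipped", sum(!inside)))
    }
    v <- variants[inside, , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      acc <- v$accession[i]
      if (!acc %in% accessions) next
      col0 <- v$pos[i] - region[1] + 1L
      is_snp <- nchar(v$ref[i]) == 1L && nchar(v$alt[i]) == 1L
      if (is_snp && identical(v$genotype[i], "hom_alt")) {
        rows[acc, col0] <- v$alt[i]
      } else if (is_snp) {
        rows[acc, col0] <- "N"   # missing/het genotype: mask
      } else {
        # indel: mask the reference footprint (deleted span, or the anchor)
        span <- col0:min(col0 + nchar(v$ref[i]) - 1L, width)
        rows[acc, span] <- "N"
      }
    }
  }
  region_alignment(rows, labels = accessions,
                   positions = seq(region[1], region[2]))
}
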