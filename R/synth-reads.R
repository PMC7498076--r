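#' Simulate paired-end reads from a mutant genome, placed by construction
#'
#' Fragments are sampled uniformly along the mutant genome with insert
#' lengths from a truncated normal; each read is then *placed* against the
#' reference (no aligner) using the known variant set: a read lying fully
#' inside non-reference inserted sequence is emitted unmapped with a mapped
#' mate; a read overlapping an insertion boundary is emitted mapped with the
#' non-reference part soft-clipped; reads spanning small indels carry the
#' corresponding `I`/`D` CIGAR operations; ordinary pairs get correct
#' POS/PNEXT/TLEN. This reproduces the alignment signatures the insertion
#' screens consume, hermetically.
#'
#' @param genome Mutant [reference_region()] (as from [plant_haplotype()]).
#' @param reference The ungapped reference [reference_region()].
#' @param variants Normalized variant records that produced `genome`
#'   (indels only matter; SNPs are already in the sequence).
#' @param depth Mean coverage (default 30).
#' @param insert_mu,insert_sigma Insert-size model (bp; default 250/25,
#'   covering the expected 200-300 bp separation).
#' @param read_len Read length (default 100).
#' @param seed Integer seed.
#' @param window Optional reference window `c(start, end)`: only fragments
#'   overlapping it are generated (depth within the window is preserved).
#' @param prefix Read-name prefix.
#' @return A read tibble in the shape of [read_sam()] output.
#' @export
simulate_read_pairs <- function(genome, reference, variants = NULL,
                                depth = 30, insert_mu = 250,
                                insert_sigma = 25, read_len = 100L,
                                seed = 1L, window = NULL,
                                prefix = "frag") {
  set.seed(seed)
  G <- nchar(genome$seq)
  max_insert <- as.integer(ceiling(insert_mu + 4 * insert_sigma))
  if (G < max_insert) abort("genome shorter than the largest insert")

  ref_pos <- genome_to_ref_map(genome, reference, variants)

  if (!is.null(window)) {
    gidx <- which(!is.na(ref_pos) & ref_pos >= window[1] & ref_pos <= window[2])
    if (length(gidx) == 0L) abort("window not covered by the genome")
    lo <- max(1L, min(gidx) - max_insert)
    hi <- min(G - max_insert, max(gidx))
  } else {
    lo <- 1L; hi <- G - max_insert
  }
  span <- hi - lo + 1L
  if (span <= 0L) abort("genome too short for the requested window")
  n_frags <- max(0L, as.integer(round(depth * span / (2 * read_len))))
  if (n_frags == 0L) return(empty_reads())

  # truncate at mu +/- 2 sigma (and at 2*read_len): the screens' premise is
  # that ordinary pairs sit "about 200 to 300 bp" apart, so the generator
  # never emits a concordant pair outside that band
  ins_lo <- max(2L * read_len, as.integer(floor(insert_mu - 2 * insert_sigma)))
  ins_hi <- as.integer(ceiling(insert_mu + 2 * insert_sigma))
  starts <- sample.int(span, n_frags, replace = TRUE) + lo - 1L
  inserts <- as.integer(round(rnorm(n_frags, insert_mu, insert_sigma)))
  while (any(bad <- inserts < ins_lo | inserts > ins_hi)) {
    inserts[bad] <- as.integer(round(rnorm(sum(bad), insert_mu, insert_sigma)))
  }
  ends <- starts + inserts - 1L

  a1 <- starts; b1 <- starts + read_len - 1L
  a2 <- ends - read_len + 1L; b2 <- ends
  seq1 <- substring(genome$seq, a1, b1)
  seq2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(genome$seq, a2, b2))
  ))

  # classify reads: a "clean" read has no insertion base and no ref jump
  isna <- is.na(ref_pos)
  na_cum <- cumsum(isna)
  jump <- c(FALSE, (isna[-G] | isna[-1]) |
              (ref_pos[-1] - ref_pos[-G] != 1L))
  jump[is.na(jump)] <- TRUE
  jump_cum <- cumsum(jump)
  clean <- function(a, b) (na_cum[b] - na_cum[a] + isna[a]) == 0L &
    (jump_cum[b] - jump_cum[a]) == 0L
  cl1 <- clean(a1, b1); cl2 <- clean(a2, b2)

  place <- function(a, b, cl) {
    pos <- integer(length(a)); cig <- character(length(a))
    pos[cl] <- ref_pos[a[cl]]
    cig[cl] <- sprintf("%dM", read_len)
    for (i in which(!cl)) {
      p <- place_read(ref_pos, a[i], b[i])
      if (is.null(p)) { pos[i] <- NA_integer_; cig[i] <- "*" }
      else { pos[i] <- p$pos; cig[i] <- p$cigar }
    }
    list(pos = pos, cigar = cig)
  }
  r1 <- place(a1, b1, cl1)
  r2 <- place(a2, b2, cl2)

  un1 <- is.na(r1$pos); un2 <- is.na(r2$pos)
  keep <- !(un1 & un2)  # drop pairs fully inside inserted sequence
  both <- !un1 & !un2
  span2 <- rep(NA_integer_, n_frags)
  span2[both & r2$cigar == sprintf("%dM", read_len)] <- read_len
  todo <- which(both & is.na(span2))
  span2[todo] <- vapply(r2$cigar[todo], cigar_ref_span, 1L)
  end2 <- ifelse(both, r2$pos + span2 - 1L, NA)
  tlen <- ifelse(both, end2 - r1$pos + 1L, 0L)
  qn <- sprintf("%s%06d", prefix, seq_len(n_frags))

  flag1 <- 1L + ifelse(both, 2L, 0L) + ifelse(un1, 4L, 0L) +
    ifelse(un2, 8L, 0L) + 32L + 64L
  flag2 <- 1L + ifelse(both, 2L, 0L) + ifelse(un2, 4L, 0L) +
    ifelse(un1, 8L, 0L) + 16L + 128L

  mkrow <- function(flag, pos, cigar, other_pos, un, sq, tl) {
    tibble(
      qname = qn, flag = as.integer(flag), chrom = genome$chrom,
      pos = as.integer(ifelse(un, other_pos, pos)),
      mapq = as.integer(ifelse(un, 0L, 60L)),
      cigar = ifelse(un, "*", cigar),
      mate_chrom = "=",
      mate_pos = as.integer(ifelse(is.na(other_pos), pos, other_pos)),
      tlen = as.integer(tl), seq = sq
    )
  }
  out <- dplyr::bind_rows(
    mkrow(flag1, r1$pos, r1$cigar, r2$pos, un1, seq1, tlen)[keep, ],
    mkrow(flag2, r2$pos, r2$cigar, r1$pos, un2, seq2, -tlen)[keep, ]
  )
  out <- out[order(out$qname), , drop = FALSE]
  out <- decode_flags(out)
  out$mate_filtered <- FALSE
  out
}

# per-base map from mutant-genome index to reference coordinate (NA inside
# inserted sequence)
genome_to_ref_map <- function(genome, reference, variants) {
  G <- nchar(genome$seq)
  if (is.null(variants) || nrow(variants) == 0L) {
    return(seq.int(genome$start, genome$start + G - 1L))
  }
  v <- variants[nchar(variants$ref) != nchar(variants$alt), , drop = FALSE]
  if (nrow(v) == 0L) return(seq.int(genome$start, genome$start + G - 1L))
  v <- v[order(v$pos), , drop = FALSE]
  ref_cursor <- reference$start
  out <- vector("list", 2L * nrow(v) + 1L)
  k <- 0L
  for (i in seq_len(nrow(v))) {
    dlen <- nchar(v$ref[i]) - 1L   # deleted bases after the anchor
    ilen <- nchar(v$alt[i]) - 1L   # inserted bases after the anchor
    if (dlen > 0L && ilen > 0L) abort("complex substitutions not supported")
    k <- k + 1L
    out[[k]] <- seq.int(ref_cursor, v$pos[i])  # through the anchor base
    ref_cursor <- v$pos[i] + 1L
    if (dlen > 0L) {
      ref_cursor <- ref_cursor + dlen
    } else if (ilen > 0L) {
      k <- k + 1L
      out[[k]] <- rep(NA_integer_, ilen)
    }
  }
  k <- k + 1L
  out[[k]] <- seq.int(ref_cursor, ref_end(reference))
  res <- unlist(out[seq_len(k)])
  if (length(res) != G) abort("variant set inconsistent with mutant genome length")
  res
}

# CIGAR + POS for a read spanning genome indices a..b, or NULL if unmapped
place_read <- function(ref_pos, a, b) {
  seg <- ref_pos[a:b]
  mapped <- !is.na(seg)
  if (!any(mapped)) return(NULL)
  r <- rle(mapped)
  ops <- character(0); lens <- integer(0)
  idx <- cumsum(c(1L, r$lengths))
  first_mapped_run <- which(r$values)[1]
  last_mapped_run <- rev(which(r$values))[1]
  prev_ref <- NA_integer_
  for (k in seq_along(r$values)) {
    li <- r$lengths[k]
    if (!r$values[k]) {
      op <- if (k < first_mapped_run || k > last_mapped_run) "S" else "I"
      ops <- c(ops, op); lens <- c(lens, li)
    } else {
      run_start <- idx[k]
      run_ref <- seg[run_start:(run_start + li - 1L)]
      j <- 1L
      while (j <= li) {
        if (!is.na(prev_ref)) {
          gap <- run_ref[j] - prev_ref - 1L
          if (gap > 0L) { ops <- c(ops, "D"); lens <- c(lens, gap) }
        }
        j2 <- j
        while (j2 < li && run_ref[j2 + 1L] == run_ref[j2] + 1L) j2 <- j2 + 1L
        ops <- c(ops, "M"); lens <- c(lens, j2 - j + 1L)
        prev_ref <- run_ref[j2]
        j <- j2 + 1L
      }
    }
  }
  # merge adjacent identical ops
  keep_ops <- character(0); keep_lens <- integer(0)
  for (k in seq_along(ops)) {
    if (length(keep_ops) && keep_ops[length(keep_ops)] == ops[k]) {
      keep_lens[length(keep_lens)] <- keep_lens[length(keep_lens)] + lens[k]
    } else {
      keep_ops <- c(keep_ops, ops[k]); keep_lens <- c(keep_lens, lens[k])
    }
  }
  list(
    pos = seg[mapped][1],
    cigar = paste0(keep_lens, keep_ops, collapse = "")
  )
}
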