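#' Screen configuration for the read-evidence insertion detectors
#'
#' Defaults follow the published expectation that paired reads should sit
#' about 200-300 bp apart; the remaining thresholds are exposed
#' configuration (the original screen's exact values are unpublished).
#'
#' @param window Half-width of the breakpoint window, bp (default 300, the
#'   upper bound of the expected insert range: discordant mates of a true
#'   insertion cluster within one insert length of the breakpoint, so a
#'   wider window only dilutes the supporting fraction).
#' @param insert_range Expected insert-size range `c(lo, hi)` (default
#'   `c(200, 300)`).
#' @param clip_min Minimum soft-clip length counted as evidence (default 20).
#' @param k_min Minimum supporting reads to call `present` (default 3).
#' @param f_min Minimum supporting fraction to call `present`; `absent`
#'   requires the fraction to be at most `f_min / 2` with at least `k_min`
#'   reads in the window (default 0.2: half the geometric expectation of
#'   about 0.4 for a homozygous carrier, see the methods vignette).
#' @param clip_tol Maximum distance between a soft-clip boundary and the
#'   breakpoint for the clip to count (default 10).
#' @param ins_tol Length tolerance around the expected insertion CIGAR op
#'   in [screen_small_insertion()] (default 2).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(window = 300L, insert_range = c(200L, 300L),
                          clip_min = 20L, k_min = 3L, f_min = 0.2,
                          clip_tol = 10L, ins_tol = 2L) {
  if (window <= 0L) abort("window must be > 0")
  if (insert_range[1] >= insert_range[2]) abort("insert_range lo must be < hi")
  structure(
    list(window = as.integer(window), insert_range = as.integer(insert_range),
         clip_min = as.integer(clip_min), k_min = as.integer(k_min),
         f_min = f_min, clip_tol = as.integer(clip_tol),
         ins_tol = as.integer(ins_tol)),
    class = "screen_config"
  )
}

#' Screen for a large insertion from discordant read pairs
#'
#' Counts, among reads whose leftmost position falls within `window` of the
#' breakpoint, those carrying an "unreasonable unpaired read" signature:
#' an unmapped mate, a template length outside the expected insert range,
#' or a long soft-clip whose boundary abuts the breakpoint. The three-way
#' call (`present` / `absent` / `inconclusive`) never lets low coverage
#' silently mean absence.
#'
#' @param reads Read tibble (from [read_sam()] or [simulate_read_pairs()]).
#' @param breakpoint Reference coordinate of the insertion point.
#' @param cfg A [screen_config()].
#' @return A one-row tibble: `site`, `n_window_reads`, `n_discordant`,
#'   `n_clipped`, `discordant_fraction`, `call`.
#' @export
screen_large_insertion <- function(reads, breakpoint, cfg = screen_config()) {
  reads <- reads[!reads$unmapped, , drop = FALSE]
  win <- abs(reads$pos - breakpoint) <= cfg$window
  w <- reads[win, , drop = FALSE]
  n <- nrow(w)
  if (n == 0L) {
    return(tibble(site = breakpoint, n_window_reads = 0L, n_discordant = 0L,
                  n_clipped = 0L, discordant_fraction = NA_real_,
                  call = "inconclusive"))
  }
  disc <- w$mate_unmapped |
    (!w$mate_unmapped & w$tlen != 0L &
       (abs(w$tlen) < cfg$insert_range[1] | abs(w$tlen) > cfg$insert_range[2]))
  clip <- !disc & clipped_at(w, breakpoint, cfg)
  finish_call(breakpoint, n, sum(disc), sum(clip), cfg)
}

#' Screen for a small (e.g. 36-bp) insertion from CIGAR evidence
#'
#' A supporting read either spans the site with an insertion CIGAR
#' operation of the expected length (within `cfg$ins_tol`), or carries a
#' soft-clip of at least `cfg$clip_min` whose boundary abuts the site.
#' Unlike the large-insertion screen, the evaluated read set is the reads
#' that *span* the site (plus boundary-clipped reads), not every read in
#' the window: for an event shorter than a read only spanning reads can
#' carry evidence, so a window-wide denominator would cap the supporting
#' fraction of even a perfect carrier far below any usable threshold.
#'
#' @param reads Read tibble.
#' @param site Reference coordinate of the insertion point.
#' @param ins_len Expected insertion length (default 36).
#' @param cfg A [screen_config()].
#' @return A one-row tibble as in [screen_large_insertion()]
#'   (`n_window_reads` holds the evaluated spanning reads; supporting
#'   `I`-op reads are reported in `n_discordant`).
#' @export
screen_small_insertion <- function(reads, site, ins_len = 36L,
                                   cfg = screen_config()) {
  reads <- reads[!reads$unmapped, , drop = FALSE]
  win <- abs(reads$pos - site) <= cfg$window
  w <- reads[win, , drop = FALSE]
  if (nrow(w)) {
    has_iop <- rep(FALSE, nrow(w))
    cand <- which(grepl("I", w$cigar, fixed = TRUE))
    has_iop[cand] <- purrr::map_lgl(w$cigar[cand], function(cg) {
      ops <- cigar_ops(cg)
      any(ops$op == "I" & abs(ops$len - ins_len) <= cfg$ins_tol)
    })
    span <- rep(NA_integer_, nrow(w))
    plain <- grepl("^[0-9]+M$", w$cigar)
    span[plain] <- as.integer(sub("M", "", w$cigar[plain]))
    span[!plain] <- vapply(w$cigar[!plain], cigar_ref_span, 1L)
    spanning <- w$pos <= site & (w$pos + span - 1L) > site
    clip <- clipped_at(w, site, cfg)
    evaluated <- spanning | clip
    supp <- has_iop & spanning
    w <- w[evaluated, , drop = FALSE]
    n <- nrow(w)
  } else n <- 0L
  if (n == 0L) {
    return(tibble(site = site, n_window_reads = 0L, n_discordant = 0L,
                  n_clipped = 0L, discordant_fraction = NA_real_,
                  call = "inconclusive"))
  }
  finish_call(site, n, sum(supp[evaluated]),
              sum(clip[evaluated] & !supp[evaluated]), cfg)
}

clipped_at <- function(w, site, cfg) {
  out <- rep(FALSE, nrow(w))
  cand <- which(grepl("S", w$cigar, fixed = TRUE))
  out[cand] <- purrr::map_lgl(cand, function(i) {
    ops <- cigar_ops(w$cigar[i])
    if (nrow(ops) == 0L) return(FALSE)
    lead <- ops$op[1] == "S" && ops$len[1] >= cfg$clip_min &&
      abs(w$pos[i] - 1L - site) <= cfg$clip_tol
    span <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
    trail <- ops$op[nrow(ops)] == "S" && ops$len[nrow(ops)] >= cfg$clip_min &&
      abs(w$pos[i] + span - 1L - site) <= cfg$clip_tol
    lead || trail
  })
  out
}

finish_call <- function(site, n, n_disc, n_clip, cfg) {
  frac <- (n_disc + n_clip) / n
  call <- if (n_disc + n_clip >= cfg$k_min && frac >= cfg$f_min) "present"
    else if (frac <= cfg$f_min / 2 && n >= cfg$k_min) "absent"
    else "inconclusive"
  tibble(site = site, n_window_reads = n, n_discordant = n_disc,
         n_clipped = n_clip, discordant_fraction = frac, call = call)
}

#' Detect long terminal repeats by prefix/suffix self-alignment
#'
#' Finds the best-scoring local alignment (match +1, mismatch -1, gap -2)
#' between the 5' half and the 3' half of a sequence — the dot-matrix
#' signature of an LTR retrotransposon. Reports the aligned repeat length
#' on each side and the percent identity, or no detection when the
#' alignment is shorter than `min_len` or less identical than
#' `min_identity`.
#'
#' @param seq Character scalar (the insertion element).
#' @param min_len Minimum repeat length (default 100).
#' @param min_identity Minimum percent identity (default 90).
#' @return A one-row tibble `left_len`, `right_len`, `identity`, `detected`.
#' @export
detect_terminal_repeats <- function(seq, min_len = 100L, min_identity = 90) {
  n <- nchar(seq)
  if (n < 2L * min_len) abort("sequence shorter than twice min_len")
  half <- n %/% 2L
  left <- substr(seq, 1L, half)
  right <- substr(seq, n - half + 1L, n)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  al <- Biostrings::pairwiseAlignment(
    left, right, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  left_len <- Biostrings::end(Biostrings::pattern(al)) -
    Biostrings::start(Biostrings::pattern(al)) + 1L
  right_len <- Biostrings::end(Biostrings::subject(al)) -
    Biostrings::start(Biostrings::subject(al)) + 1L
  identity <- Biostrings::pid(al)
  detected <- left_len >= min_len && right_len >= min_len &&
    identity >= min_identity
  tibble(
    left_len = if (detected) as.integer(left_len) else NA_integer_,
    right_len = if (detected) as.integer(right_len) else NA_integer_,
    identity = if (detected) identity else NA_real_,
    detected = detected
  )
}
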