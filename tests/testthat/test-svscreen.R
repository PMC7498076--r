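carrier_reads <- function(seed, depth = 30) {
  pl <- plant_haplotype(the_ref, rule_row("type19"), accession = "c",
                        seed = seed)
  simulate_read_pairs(pl$genome, the_ref, pl$variants, depth = depth,
                      seed = seed + 1000L, window = c(9336532, 9339532))
}

noncarrier_reads <- function(seed, depth = 30) {
  simulate_read_pairs(the_ref, the_ref, NULL, depth = depth,
                      seed = seed + 2000L, window = c(9336532, 9339532))
}

test_that("the large-insertion screen separates carriers from non-carriers", {
  bp <- 9338032L
  for (s in 1:5) {
    expect_equal(screen_large_insertion(carrier_reads(s), bp)$call, "present")
    expect_equal(screen_large_insertion(noncarrier_reads(s), bp)$call, "absent")
  }
  # no reads at all: inconclusive, never absent
  expect_equal(screen_large_insertion(empty_sam_tbl(), bp)$call, "inconclusive")
  # invariance to read order
  r <- carrier_reads(9)
  shuffled <- r[sample.int(nrow(r)), ]
  expect_equal(screen_large_insertion(shuffled, bp),
               screen_large_insertion(r, bp))
  # config validation
  expect_error(screen_config(window = 0), "window")
  expect_error(screen_config(insert_range = c(300, 200)), "insert_range")
})

test_that("the small-insertion screen keys on spanning insertion CIGARs", {
  site <- 9336699L
  anchor <- ref_slice(the_ref, site, site)
  set.seed(3)
  ins <- paste(sample(c("A", "C", "G", "T"), 36, TRUE), collapse = "")
  v <- tibble::tibble(accession = "k", chrom = "chr6", pos = site,
                      ref = anchor, alt = paste0(anchor, ins),
                      genotype = "hom_alt", gq = 60, ad_alt = 30)
  off <- site - the_ref$start + 1L
  g <- reference_region(
    paste0(substr(the_ref$seq, 1, off), ins,
           substr(the_ref$seq, off + 1, nchar(the_ref$seq))),
    the_ref$chrom, the_ref$start)
  for (s in 1:5) {
    kas <- simulate_read_pairs(g, the_ref, v, depth = 25, seed = s,
                               window = c(site - 1200, site + 1200))
    nip <- simulate_read_pairs(the_ref, the_ref, NULL, depth = 25,
                               seed = s + 50, window = c(site - 1200, site + 1200))
    expect_equal(screen_small_insertion(kas, site)$call, "present")
    expect_equal(screen_small_insertion(nip, site)$call, "absent")
  }
})

test_that("insertion ops outside the length tolerance do not support the call", {
  # hand-built reads: 30-bp I ops under tolerance 2 at a 36-bp query
  site <- 500L
  reads <- decode_flag_tbl(tibble::tibble(
    qname = sprintf("r%02d", 1:10), flag = 99L, chrom = "c",
    pos = as.integer(site - 50L + 0:9), mapq = 60L,
    cigar = "40M30I30M", mate_chrom = "=",
    mate_pos = as.integer(site + 100L), tlen = 250L, seq = "A"
  ))
  call <- screen_small_insertion(reads, site, ins_len = 36L)
  expect_equal(call$n_discordant, 0L)
  expect_equal(call$call, "absent")
  # the same reads support a 30-bp query
  expect_equal(screen_small_insertion(reads, site, ins_len = 30L)$call,
               "present")
})

test_that("detect_terminal_repeats finds exact and degenerate LTR pairs", {
  # exact 448-bp termini on the 1901-bp element
  el <- make_ltr_element(seed = 11)
  tr <- detect_terminal_repeats(el, min_len = 100, min_identity = 90)
  expect_equal(tr$left_len, 448L)
  expect_equal(tr$right_len, 448L)
  expect_equal(tr$identity, 100)
  # reverse complement: mirrored lengths, same identity
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(el)))
  tr_rc <- detect_terminal_repeats(rc, min_len = 100, min_identity = 90)
  expect_equal(tr_rc$left_len, tr$right_len)
  expect_equal(tr_rc$right_len, tr$left_len)
  expect_equal(tr_rc$identity, tr$identity)

  # termini of unequal length at ~97% identity, as in the paired genomic
  # copies of the same element family
  set.seed(12)
  ltr <- sample(c("A", "C", "G", "T"), 452, replace = TRUE)
  right <- ltr
  drop <- sort(sample(30:420, 6))       # 6 interior deletions -> 446 bp
  mis <- sample(setdiff(30:420, drop), 8)
  for (m in mis) right[m] <- setdiff(c("A", "C", "G", "T"), right[m])[1]
  right <- right[-drop]
  mid <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  el2 <- paste0(c(ltr, mid, right), collapse = "")
  tr2 <- detect_terminal_repeats(el2, min_len = 100, min_identity = 90)
  expect_true(tr2$detected)
  expect_equal(tr2$left_len, 452L, tolerance = 0.01)
  expect_equal(tr2$right_len, 446L, tolerance = 0.01)
  expect_lt(abs(tr2$identity - 97), 2)

  # uniform random sequence: nothing at 90% identity / 100 bp
  set.seed(13)
  rnd <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  expect_false(detect_terminal_repeats(rnd, min_len = 100,
                                       min_identity = 90)$detected)
  expect_error(detect_terminal_repeats("ACGT", min_len = 100), "shorter")
})
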