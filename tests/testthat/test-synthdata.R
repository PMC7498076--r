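test_that("make_reference is deterministic and carries the published rule sites", {
  l1 <- make_reference(seed = 1)
  l2 <- make_reference(seed = 1)
  expect_identical(l1$reference$seq, l2$reference$seq)
  # all rule reference alleles present at their coordinates
  for (i in seq_len(nrow(the_rules))) {
    r <- the_rules[i, ]
    if (!is.na(r$ref)) {
      expect_equal(ref_slice(the_ref, r$pos, r$pos + nchar(r$ref) - 1L), r$ref,
                   label = r$type_label)
    }
  }
  # geometry: two exons, CDS a whole number of codons, ORF translates fully
  expect_equal(nrow(the_gene$exons), 2L)
  tr <- translate_cds(the_gene, the_ref)
  expect_equal(tr$stop_index, tr$n_codons)  # only the terminal stop
  expect_equal(substr(tr$protein, 1, 1), "M")
})

test_that("rule sites fall in compartments consistent with their consequence class", {
  # SNP stop rules annotate as stop_gained; indel FS rules in CDS frameshift
  for (lab in c("type12", "type20", "type21", "type22")) {
    r <- rule_row(lab)
    v <- tibble::tibble(accession = "a", chrom = "chr6", pos = r$pos,
                        ref = r$ref, alt = r$change_payload,
                        genotype = "hom_alt", gq = 60, ad_alt = 30)
    ann <- annotate_variants(v, the_gene, the_ref)
    expect_equal(ann$effect, "stop_gained", label = lab)
  }
  for (lab in c("type2", "type3", "type7", "type13")) {
    pl <- plant_haplotype(the_ref, rule_row(lab))
    ann <- annotate_variants(pl$variants, the_gene, the_ref)
    expect_equal(ann$compartment, "CDS", label = lab)
    expect_equal(ann$effect, "frameshift", label = lab)
  }
})

test_that("gene model round-trips through GFF3", {
  p <- tempfile(fileext = ".gff3")
  write_gene_model(the_gene, p)
  g2 <- read_gene_model(p)
  expect_equal(g2$exons, the_gene$exons)
  expect_equal(g2$cds, the_gene$cds)
  expect_equal(g2$region, the_gene$region)
  expect_equal(g2$strand, the_gene$strand)
})

test_that("plant_haplotype applies exactly the rule's change", {
  # 4-bp deletion: genome shorter by 4, deletion VCF record emitted
  pl7 <- plant_haplotype(the_ref, rule_row("type7"))
  expect_equal(nchar(pl7$genome$seq), nchar(the_ref$seq) - 4L)
  expect_equal(nchar(pl7$variants$ref) - nchar(pl7$variants$alt), 4L)
  expect_equal(pl7$variants$pos + 1L, rule_row("type7")$pos)
  # wildtype: untouched genome, no variants
  wt <- plant_haplotype(the_ref, NULL)
  expect_identical(wt$genome$seq, the_ref$seq)
  expect_equal(nrow(wt$variants), 0L)
  expect_equal(wt$truth$type_label, "wildtype")
  # 1.9-kb insertion: genome longer by 1901, element has exact 448-bp LTRs
  pl19 <- plant_haplotype(the_ref, rule_row("type19"), seed = 4)
  expect_equal(nchar(pl19$genome$seq), nchar(the_ref$seq) + 1901L)
  element <- substr(pl19$variants$alt, 2L, nchar(pl19$variants$alt))
  tr <- detect_terminal_repeats(element, min_len = 100, min_identity = 90)
  expect_equal(tr$left_len, 448L)
  expect_equal(tr$right_len, 448L)
  expect_equal(tr$identity, 100)
})

test_that("simulated non-carrier read pairs are all proper with in-range inserts", {
  reads <- simulate_read_pairs(the_ref, the_ref, NULL, depth = 10, seed = 5,
                               window = c(9337000, 9339000))
  expect_gt(nrow(reads), 100L)
  expect_true(all(reads$proper_pair))
  expect_true(all(!reads$unmapped & !reads$mate_unmapped))
  expect_true(all(abs(reads$tlen) >= 200 & abs(reads$tlen) <= 300))
  expect_true(all(grepl("^[0-9]+M$", reads$cigar)))
})

test_that("large-insertion carriers yield unmapped-with-mapped-mate reads near
           the breakpoint at about the expected rate", {
  depth <- 60
  pl <- plant_haplotype(the_ref, rule_row("type19"), seed = 6)
  reads <- simulate_read_pairs(pl$genome, the_ref, pl$variants, depth = depth,
                               seed = 7, window = c(9337032, 9339032))
  anchored <- reads[!reads$unmapped & reads$mate_unmapped, ]
  expect_gt(nrow(anchored), 0L)
  expect_true(all(abs(anchored$pos - 9338032) <= 300 + 100))
  # expectation: fragment starts within ~2*(insert - read_len) of a boundary
  expected <- depth * (250 - 100) / 100
  expect_gt(nrow(anchored), expected * 0.5)
  expect_lt(nrow(anchored), expected * 1.5)
})

test_that("36-bp insertion carriers produce 36I CIGAR reads over the site", {
  site <- 9336699L
  anchor <- ref_slice(the_ref, site, site)
  set.seed(1)
  insseq <- paste(sample(c("A", "C", "G", "T"), 36, TRUE), collapse = "")
  v <- tibble::tibble(accession = "k", chrom = "chr6", pos = site,
                      ref = anchor, alt = paste0(anchor, insseq),
                      genotype = "hom_alt", gq = 60, ad_alt = 30)
  off <- site - the_ref$start + 1L
  g <- reference_region(paste0(substr(the_ref$seq, 1, off), insseq,
                               substr(the_ref$seq, off + 1, nchar(the_ref$seq))),
                        the_ref$chrom, the_ref$start)
  reads <- simulate_read_pairs(g, the_ref, v, depth = 30, seed = 8,
                               window = c(site - 1000, site + 1000))
  iops <- grepl("36I", reads$cigar, fixed = TRUE)
  expect_gt(sum(iops), 0L)
})

test_that("neutral coalescent alignments match E[S] = theta * a1 and are
           deterministic under seed", {
  theta <- 5; n <- 10; reps <- 500
  S <- vapply(seq_len(reps), function(r) {
    a <- simulate_neutral_alignment(n, theta, region_len = 2000L, seed = r)
    diversity_stats(a)$S
  }, numeric(1))
  a1 <- sum(1 / seq_len(n - 1))
  se <- sd(S) / sqrt(reps)
  expect_lt(abs(mean(S) - theta * a1), 3 * se)
  # n = 2: k equals S exactly per replicate
  for (r in 1:20) {
    a <- simulate_neutral_alignment(2L, 3, region_len = 500L, seed = r)
    st <- diversity_stats(a)
    expect_equal(st$k, as.numeric(st$S))
  }
  # determinism
  expect_identical(simulate_neutral_alignment(6L, 4, 300L, seed = 9)$mat,
                   simulate_neutral_alignment(6L, 4, 300L, seed = 9)$mat)
})

test_that("generate_cohort honors the spec counts, labels and seeds", {
  spec <- tibble::tibble(
    type_label = c("type7", "type13", "wildtype"),
    count = c(5L, 8L, 12L),
    origin = c("Indonesia", "Indonesia", "Laos"),
    subpop = c("indica", "japonica", "indica"),
    traditional = TRUE
  )
  cfg <- synth_config(seed = 3, cohort_spec = spec)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$truth), 25L)
  expect_equal(sum(ch$truth$type_label == "type7"), 5L)
  expect_equal(sum(ch$truth$type_label == "wildtype"), 12L)
  # classification recovers every planted label
  calls <- classify_accessions(ch$variants, accessions = ch$metadata$accession)
  merged <- dplyr::left_join(ch$truth, calls, by = "accession")
  expect_true(all(ifelse(merged$type_label == "wildtype",
                         merged$types == "", merged$types == merged$type_label)))
  # different seed: same truth labels, different background variants
  ch2 <- generate_cohort(synth_config(seed = 4, cohort_spec = spec))
  expect_equal(ch2$truth$type_label, ch$truth$type_label)
  expect_false(identical(ch2$variants, ch$variants))
  # unknown type label errors
  bad <- spec
  bad$type_label[1] <- "type99"
  expect_error(generate_cohort(synth_config(seed = 1, cohort_spec = bad)),
               "unknown type_label")
})
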