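test_that("the three published early-stop SNPs annotate at their residues", {
  v <- tibble::tibble(
    accession = "a", chrom = "chr6",
    pos = c(9338273L, 9337150L, 9337112L),
    ref = c("A", "C", "C"), alt = c("T", "T", "A"),
    genotype = "hom_alt", gq = 60, ad_alt = 30
  )
  ann <- annotate_variants(v, the_gene, the_ref)
  expect_equal(ann$effect, rep("stop_gained", 3))
  expect_equal(ann$residue_index, c(368L, 206L, 193L))
  expect_equal(ann$aa_from, c("R", "Q", "S"))  # Arg368, Gln206, Ser193
  expect_equal(ann$aa_to, rep("*", 3))
})

test_that("a synthetic 3-codon CDS reports stop_gained at residue 2", {
  r <- reference_region("TTATGAAATGGTT", start = 1L)  # ATG AAA TGG at 3..11
  g <- gene_model("c", "+", exons = tibble::tibble(start = 3L, end = 11L),
                  cds = tibble::tibble(start = 3L, end = 11L),
                  region = c(1L, 13L))
  v <- tibble::tibble(accession = "a", chrom = "c", pos = 6L, ref = "A",
                      alt = "T", genotype = "hom_alt", gq = 60, ad_alt = 30)
  ann <- annotate_variants(v, g, r)
  expect_equal(ann$effect, "stop_gained")  # AAA -> TAA
  expect_equal(ann$residue_index, 2L)
})

test_that("translate_cds follows the standard code and reports the first stop", {
  r <- reference_region("ATGGCTTAA", start = 1L)
  g <- gene_model("c", "+", exons = tibble::tibble(start = 1L, end = 9L),
                  cds = tibble::tibble(start = 1L, end = 9L),
                  region = c(1L, 9L))
  tr <- translate_cds(g, r)
  expect_equal(tr$protein, "MA")
  expect_equal(tr$stop_index, 3L)
  # reverse strand: translating the reverse complement gives the same protein
  rc <- reference_region(paste(rev(strsplit(chartr("ACGT", "TGCA",
                                                   "ATGGCTTAA"), "")[[1]]),
                               collapse = ""), start = 1L)
  gm <- gene_model("c", "-", exons = tibble::tibble(start = 1L, end = 9L),
                   cds = tibble::tibble(start = 1L, end = 9L),
                   region = c(1L, 9L))
  expect_equal(translate_cds(gm, rc)$protein, "MA")
  # internal N errors with a position
  rn <- reference_region("ATGNCTTAA", start = 1L)
  expect_error(translate_cds(g, rn), "N at")
})

test_that("CDS indels are frameshift exactly when length mod 3 is nonzero", {
  for (len in 1:6) {
    pos <- 9338100L  # inside exon-2 CDS
    anchor <- ref_slice(the_ref, pos, pos)
    del <- tibble::tibble(accession = "a", chrom = "chr6", pos = pos,
                          ref = ref_slice(the_ref, pos, pos + len),
                          alt = anchor, genotype = "hom_alt",
                          gq = 60, ad_alt = 30)
    ann <- annotate_variants(del, the_gene, the_ref)
    expect_equal(ann$effect,
                 if (len %% 3 == 0) "inframe_indel" else "frameshift",
                 label = sprintf("del len %d", len))
  }
  # the 36-bp exon-1 insertion at a codon boundary: in-frame, +12 residues
  site <- 9336699L
  anchor <- ref_slice(the_ref, site, site)
  ins <- paste(rep("GCT", 12L), collapse = "")  # 12 alanine codons, no stop
  v <- tibble::tibble(accession = "a", chrom = "chr6", pos = site,
                      ref = anchor, alt = paste0(anchor, ins),
                      genotype = "hom_alt", gq = 60, ad_alt = 30)
  ann <- annotate_variants(v, the_gene, the_ref)
  expect_equal(ann$effect, "inframe_indel")
  # an in-frame 36-bp insertion adds exactly 36/3 = 12 residues: translate
  # the mutant genome with the exon-1 CDS widened by the insertion
  off <- site - the_ref$start + 1L
  mutant <- reference_region(
    paste0(substr(the_ref$seq, 1, off), ins,
           substr(the_ref$seq, off + 1, nchar(the_ref$seq))),
    the_ref$chrom, the_ref$start)
  g2 <- gene_model("chr6", "+",
                   exons = tibble::tibble(
                     start = the_gene$exons$start + c(0L, 36L),
                     end = the_gene$exons$end + 36L),
                   cds = tibble::tibble(
                     start = the_gene$cds$start + c(0L, 36L),
                     end = the_gene$cds$end + 36L),
                   region = the_gene$region)
  tr_mut <- suppressWarnings(translate_cds(g2, mutant))
  tr_wild <- translate_cds(the_gene, the_ref)
  expect_equal(nchar(tr_mut$protein) - nchar(tr_wild$protein), 12L)
})

test_that("variants outside the surveyed region and boundary-spanning indels error", {
  out <- tibble::tibble(accession = "a", chrom = "chr6", pos = 9400000L,
                        ref = "A", alt = "T", genotype = "hom_alt",
                        gq = 60, ad_alt = 30)
  expect_error(annotate_variants(out, the_gene, the_ref), "outside")
  # deletion spanning the exon1/intron boundary
  pos <- the_gene$cds$end[1] - 2L
  span <- tibble::tibble(accession = "a", chrom = "chr6", pos = pos,
                         ref = ref_slice(the_ref, pos, pos + 10L),
                         alt = ref_slice(the_ref, pos, pos),
                         genotype = "hom_alt", gq = 60, ad_alt = 30)
  expect_error(annotate_variants(span, the_gene, the_ref), "boundary")
})

test_that("annotation agrees with a brute-force mutate-and-translate oracle", {
  set.seed(42)
  n_checked <- 0L
  wild <- translate_cds(the_gene, the_ref)
  cds_pos <- unlist(purrr::map2(the_gene$cds$start, the_gene$cds$end, seq))
  for (i in seq_len(500)) {
    pos <- sample(cds_pos, 1L)
    refb <- ref_slice(the_ref, pos, pos)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    v <- tibble::tibble(accession = "a", chrom = "chr6", pos = pos,
                        ref = refb, alt = altb, genotype = "hom_alt",
                        gq = 60, ad_alt = 30)
    ann <- annotate_variants(v, the_gene, the_ref)
    # oracle: mutate the genome, translate the whole CDS, diff the proteins
    off <- pos - the_ref$start + 1L
    gseq <- the_ref$seq
    substr(gseq, off, off) <- altb
    mut <- suppressWarnings(translate_cds(
      the_gene, reference_region(gseq, the_ref$chrom, the_ref$start)))
    oracle_effect <- if (!is.na(mut$stop_index) &&
                         mut$stop_index < wild$stop_index) "stop_gained"
      else if (identical(mut$protein, wild$protein)) "synonymous"
      else "missense"
    expect_equal(ann$effect, oracle_effect,
                 label = sprintf("SNP %s>%s at %d", refb, altb, pos))
    if (oracle_effect == "stop_gained") {
      expect_equal(ann$residue_index, mut$stop_index)
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 500L)
})

test_that("annotate_variants is pure", {
  v <- tibble::tibble(accession = "a", chrom = "chr6", pos = 9338243L,
                      ref = "C", alt = "T", genotype = "hom_alt",
                      gq = 60, ad_alt = 30)
  expect_identical(annotate_variants(v, the_gene, the_ref),
                   annotate_variants(v, the_gene, the_ref))
})
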