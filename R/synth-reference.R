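#' Synthetic-cohort configuration
#'
#' Collects every knob of the synthetic-data generators with the defaults
#' of the emulated survey: a chr6-like window of 22,194 bp
#' (9,326,376..9,348,569, the gene plus or minus 10 kb), paired-end
#' fragments of 250 +/- 25 bp (the expected 200-300 bp separation),
#' 100-bp reads at 30x, and a neutral background mutation parameter.
#'
#' @param seed Integer master seed; fixes every downstream random draw.
#' @param cohort_spec Tibble with columns `type_label` (`"wildtype"` or a
#'   rule label such as `"type7"`), `count`, `origin`, `subpop`,
#'   `traditional` (logical).
#' @param depth Mean read coverage.
#' @param insert_mu,insert_sigma Insert-size model (bp), truncated normal.
#' @param read_len Read length (bp).
#' @param theta Population mutation parameter per region for the neutral
#'   background / coalescent simulations.
#' @param region Surveyed window (genomic coordinates).
#' @param chrom Chromosome name.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         cohort_spec = default_cohort_spec(),
                         depth = 30,
                         insert_mu = 250,
                         insert_sigma = 25,
                         read_len = 100L,
                         theta = 8,
                         region = c(9326376L, 9348569L),
                         chrom = "chr6") {
  stopifnot(depth >= 0, insert_sigma > 0)
  if (insert_mu - 3 * insert_sigma <= read_len) {
    abort("insert_mu - 3*insert_sigma must exceed read_len")
  }
  if (any(cohort_spec$count < 0)) abort("cohort counts must be >= 0")
  structure(
    list(seed = as.integer(seed), cohort_spec = tibble::as_tibble(cohort_spec),
         depth = depth, insert_mu = insert_mu, insert_sigma = insert_sigma,
         read_len = as.integer(read_len), theta = theta,
         region = as.integer(region), chrom = chrom),
    class = "synth_config"
  )
}

#' @rdname synth_config
#' @export
default_cohort_spec <- function() {
  tibble(
    type_label = c("type7", "type13", "type12", "type19", "wildtype"),
    count = c(10L, 20L, 5L, 5L, 60L),
    origin = c("Indonesia", "Indonesia", "Laos", "Taiwan", "Philippines"),
    subpop = c("indica", "japonica", "japonica", "japonica", "indica"),
    traditional = TRUE
  )
}

# Geometry of the synthetic Hd1-like locus (plus strand, two exons).
# Derived once from the published residue anchors: Ser193 at 9337112,
# Gln206 at 9337150, early stop 368 at 9338273 and codon-phase arithmetic.
hd1_geometry <- function() {
  list(
    chrom = "chr6",
    region = c(9326376L, 9348569L),
    exon1 = c(9336485L, 9337320L),
    exon2 = c(9337958L, 9338409L),
    cds1 = c(9336535L, 9337320L),   # 786 nt
    cds2 = c(9337958L, 9338359L),   # 402 nt -> 1188 nt = 396 codons
    small_ins_site = 9336699L       # codon boundary after residue 55, exon 1
  )
}

# Codons pinned so that the ten rule sites carry their published reference
# alleles and consequence classes, plus left-alignment guards for the
# deletion rules (the base before each deleted tract differs from the base
# at its right edge, so normalized coordinates equal rule coordinates).
pinned_codons <- function() {
  c(
    "1" = "ATG",
    "106" = "GAA", "107" = "CTG",        # 9336853 C (type 3, 1-bp del)
    "189" = "GAT", "190" = "GTG",        # 9337102 G (type 2, 1-bp del)
    "193" = "TCG",                       # 9337112 C->A => TAG (type 22)
    "206" = "CAA",                       # 9337150 C->T => TAA (type 21)
    "236" = "GCA",                       # 9337242 (type 18 43-bp del site)
    "250" = "GGT",                       # guard for the 43-bp del right edge
    "278" = "CTT", "279" = "TGG",        # 9338004-6 TTT (type 13, 2-bp del)
    "287" = "GAC",                       # 9338032 (type 19 insertion anchor)
    "350" = "CAA", "351" = "GAC",        # 9338220-3 AAGA (type 7, 4-bp del)
    "358" = "CGA",                       # 9338243 C->T => TGA (type 12)
    "368" = "AGA",                       # 9338273 A->T => TGA (type 20)
    "396" = "TAA"                        # terminal stop
  )
}

non_stop_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

#' Generate the synthetic reference region and its gene model
#'
#' Builds a random reference window with an embedded two-exon gene that
#' mimics the surveyed rice locus. In the (default) rule-mimic mode the ten
#' rule positions carry their published reference alleles and fall in the
#' published gene compartments: SNP-stop sites sit at the codon phases that
#' turn the reference codon into a stop, and deletion tracts are flanked so
#' that left-aligned representations coincide with rule coordinates.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param table1_mimic Keep the rule-site geometry (default `TRUE`). With
#'   `FALSE` a generic two-exon gene is embedded in a window of
#'   `region_len` bp, for structural tests.
#' @param region_len Window length for the generic mode.
#' @return A list with `reference` (a [reference_region()]) and `gene`
#'   (a [gene_model()]).
#' @export
make_reference <- function(seed = 1L, table1_mimic = TRUE, region_len = 6000L) {
  if (!table1_mimic) return(make_generic_reference(seed, region_len))
  geo <- hd1_geometry()
  set.seed(seed)
  width <- geo$region[2] - geo$region[1] + 1L
  seq <- sample(c("A", "C", "G", "T"), width, replace = TRUE)

  # lay down the CDS as codons
  codons <- sample(non_stop_codons(), 396L, replace = TRUE)
  pin <- pinned_codons()
  codons[as.integer(names(pin))] <- pin
  cds_seq <- strsplit(paste0(codons, collapse = ""), "")[[1]]
  stopifnot(length(cds_seq) == 1188L)
  idx1 <- (geo$cds1[1]:geo$cds1[2]) - geo$region[1] + 1L
  idx2 <- (geo$cds2[1]:geo$cds2[2]) - geo$region[1] + 1L
  seq[idx1] <- cds_seq[1:786]
  seq[idx2] <- cds_seq[787:1188]

  reference <- reference_region(paste0(seq, collapse = ""),
                                chrom = geo$chrom, start = geo$region[1])
  gene <- gene_model(
    chrom = geo$chrom, strand = "+",
    exons = tibble(start = c(geo$exon1[1], geo$exon2[1]),
                   end = c(geo$exon1[2], geo$exon2[2])),
    cds = tibble(start = c(geo$cds1[1], geo$cds2[1]),
                 end = c(geo$cds1[2], geo$cds2[2])),
    region = geo$region
  )
  list(reference = reference, gene = gene)
}

make_generic_reference <- function(seed, region_len) {
  set.seed(seed)
  region_len <- as.integer(region_len)
  if (region_len < 2000L) abort("region_len too short for the generic gene")
  seq <- sample(c("A", "C", "G", "T"), region_len, replace = TRUE)
  # generic gene: two exons in the middle, CDS a multiple of 3
  cds1 <- c(region_len %/% 3L, region_len %/% 3L + 299L)          # 300 nt
  cds2 <- c(cds1[2] + 201L, cds1[2] + 401L)                        # 201 nt
  codons <- sample(non_stop_codons(), 167L, replace = TRUE)
  codons[1] <- "ATG"; codons[167] <- "TAA"
  cds_seq <- strsplit(paste0(codons, collapse = ""), "")[[1]]
  seq[cds1[1]:cds1[2]] <- cds_seq[1:300]
  seq[cds2[1]:cds2[2]] <- cds_seq[301:501]
  reference <- reference_region(paste0(seq, collapse = ""),
                                chrom = "chrS", start = 1L)
  gene <- gene_model(
    chrom = "chrS", strand = "+",
    exons = tibble(start = c(cds1[1] - 20L, cds2[1]),
                   end = c(cds1[2], cds2[2] + 20L)),
    cds = tibble(start = c(cds1[1], cds2[1]), end = c(cds1[2], cds2[2])),
    region = c(1L, region_len)
  )
  list(reference = reference, gene = gene)
}

#' Build a synthetic LTR-retrotransposon insertion element
#'
#' The published 1901-bp element carries 448-bp long terminal repeats with
#' exact identity; this generator reproduces that structure with a random
#' internal (pol-like) body. Lowering `ltr_identity` plants mismatches in
#' the right-hand copy.
#'
#' @param total_len Element length (default 1901).
#' @param ltr_len Terminal repeat length (default 448).
#' @param ltr_identity Fraction of identical bases between the two repeats
#'   (default 1 = exact identity).
#' @param seed Integer seed.
#' @return Character scalar of length `total_len`.
#' @export
make_ltr_element <- function(total_len = 1901L, ltr_len = 448L,
                             ltr_identity = 1, seed = 1L) {
  if (total_len < 2L * ltr_len + 1L) abort("element too short for its LTRs")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ltr <- sample(bases, ltr_len, replace = TRUE)
  right <- ltr
  n_mis <- round((1 - ltr_identity) * ltr_len)
  if (n_mis > 0) {
    at <- sample(seq(5L, ltr_len - 4L), n_mis)  # keep termini intact
    right[at] <- vapply(right[at], function(b) sample(setdiff(bases, b), 1), "")
  }
  internal <- sample(bases, total_len - 2L * ltr_len, replace = TRUE)
  paste0(c(ltr, internal, right), collapse = "")
}

#' Plant a haplotype rule into the reference
#'
#' Applies one rule's change to the reference, returning the mutant genome,
#' a truth record and the expected (already normalized) VCF-style variant
#' record. Large insertions (>= 1 kb payloads) insert a synthetic
#' LTR-retrotransposon element built by [make_ltr_element()].
#'
#' @param reference A [reference_region()].
#' @param rule One row of a rule table (see [hd1_rules()]); `NULL` for
#'   wildtype.
#' @param zygosity `"hom"` or `"het"`.
#' @param accession Accession label for the emitted records.
#' @param seed Seed for the insertion element body.
#' @param gq,ad_alt Quality values stamped on the emitted record.
#' @return A list with `genome` (a [reference_region()] in mutant
#'   coordinates), `truth` (one-row tibble) and `variants` (tibble, empty
#'   for wildtype).
#' @export
plant_haplotype <- function(reference, rule = NULL, zygosity = "hom",
                            accession = "acc1", seed = 1L,
                            gq = 60, ad_alt = 30) {
  if (!zygosity %in% c("hom", "het")) abort("zygosity must be 'hom' or 'het'")
  if (is.null(rule) || (is.data.frame(rule) && nrow(rule) == 0L)) {
    return(list(
      genome = reference,
      truth = tibble(accession = accession, type_label = "wildtype",
                     zygosity = NA_character_, ins_start = NA_integer_,
                     ins_end = NA_integer_),
      variants = empty_variants()
    ))
  }
  rule <- as.list(rule[1, ])
  pos <- rule$pos
  if (pos < reference$start || pos > ref_end(reference)) {
    abort("rule position outside reference")
  }
  genotype <- if (zygosity == "hom") "hom_alt" else "het"
  ins_start <- NA_integer_; ins_end <- NA_integer_

  if (rule$change_kind == "snp") {
    obs <- ref_slice(reference, pos, pos)
    if (!is.na(rule$ref) && obs != rule$ref) {
      abort(sprintf("reference base %s at %d does not match rule ref %s",
                    obs, pos, rule$ref))
    }
    off <- pos - reference$start + 1L
    gseq <- reference$seq
    substr(gseq, off, off) <- rule$change_payload
    vref <- obs; valt <- rule$change_payload; vpos <- pos
  } else if (rule$change_kind == "del") {
    len <- as.integer(rule$change_payload)
    if (pos + len - 1L > ref_end(reference)) abort("deletion exceeds reference")
    anchor <- ref_slice(reference, pos - 1L, pos - 1L)
    deleted <- ref_slice(reference, pos, pos + len - 1L)
    off <- pos - reference$start + 1L
    gseq <- paste0(substr(reference$seq, 1L, off - 1L),
                   substr(reference$seq, off + len, nchar(reference$seq)))
    vref <- paste0(anchor, deleted); valt <- anchor; vpos <- pos - 1L
  } else if (rule$change_kind == "ins") {
    len <- as.integer(rule$change_payload)
    element <- if (len >= 1000L) {
      make_ltr_element(total_len = len, seed = seed)
    } else {
      set.seed(seed)
      paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }
    anchor <- ref_slice(reference, pos, pos)
    off <- pos - reference$start + 1L
    gseq <- paste0(substr(reference$seq, 1L, off),
                   element,
                   substr(reference$seq, off + 1L, nchar(reference$seq)))
    vref <- anchor; valt <- paste0(anchor, element); vpos <- pos
    ins_start <- pos + 1L; ins_end <- pos + len  # mutant-genome footprint anchor
  } else {
    abort(sprintf("unknown change_kind '%s'", rule$change_kind))
  }

  list(
    genome = reference_region(gseq, chrom = reference$chrom,
                              start = reference$start),
    truth = tibble(accession = accession, type_label = rule$type_label,
                   zygosity = zygosity, ins_start = ins_start,
                   ins_end = ins_end),
    variants = tibble(
      accession = accession, chrom = reference$chrom, pos = as.integer(vpos),
      ref = vref, alt = valt, genotype = genotype,
      gq = gq, ad_alt = ad_alt
    )
  )
}
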