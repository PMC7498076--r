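#' Generate a full labeled synthetic cohort
#'
#' Produces every input the survey pipeline consumes: per-accession variant
#' records (planted haplotype rules plus shared neutral background SNPs over
#' the surveyed window), a metadata table with origin/subpopulation/
#' traditional labels, and the ground-truth record for every accession.
#' Background SNPs are drawn from one neutral coalescent genealogy across
#' the cohort (so diversity statistics behave like resequencing data) and
#' avoid rule sites by a +/- 5 bp exclusion zone. Read pairs are not
#' generated here (they are per-accession and only needed by the screens);
#' use [simulate_read_pairs()] on the `genome` of a planted accession.
#'
#' @param config A [synth_config()].
#' @param reference,gene Optional pre-built locus from [make_reference()];
#'   built from `config$seed` when omitted.
#' @return A list with `variants` (tibble over all accessions), `metadata`,
#'   `truth`, `reference`, `gene`.
#' @export
generate_cohort <- function(config = synth_config(), reference = NULL,
                            gene = NULL) {
  spec <- config$cohort_spec
  if (nrow(spec) == 0L) abort("cohort_spec is empty")
  rules <- hd1_rules(chrom = config$chrom)
  unknown <- setdiff(setdiff(spec$type_label, "wildtype"), rules$type_label)
  if (length(unknown)) {
    abort(paste0("unknown type_label in cohort_spec: ",
                 paste(unknown, collapse = ",")))
  }
  if (is.null(reference) || is.null(gene)) {
    locus <- make_reference(seed = config$seed)
    reference <- locus$reference; gene <- locus$gene
  }

  counts <- rep(seq_len(nrow(spec)), times = spec$count)
  n_acc <- length(counts)
  acc <- sprintf("acc%04d", seq_len(n_acc))
  metadata <- tibble(
    accession = acc,
    origin = spec$origin[counts],
    subpop = spec$subpop[counts],
    traditional = spec$traditional[counts]
  )

  # planted variants + truth
  planted <- vector("list", n_acc)
  truth <- vector("list", n_acc)
  for (i in seq_len(n_acc)) {
    tl <- spec$type_label[counts[i]]
    rule <- if (tl == "wildtype") NULL else rules[rules$type_label == tl, ]
    pl <- plant_haplotype(reference, rule, zygosity = "hom",
                          accession = acc[i], seed = config$seed + i)
    planted[[i]] <- pl$variants
    truth[[i]] <- pl$truth
  }

  # shared neutral background SNPs over the region, avoiding rule sites
  bg <- background_snps(config, reference, rules, acc)

  list(
    variants = dplyr::bind_rows(dplyr::bind_rows(planted), bg) %>%
      dplyr::arrange(.data$accession, .data$pos),
    metadata = metadata,
    truth = dplyr::bind_rows(truth),
    reference = reference,
    gene = gene
  )
}

background_snps <- function(config, reference, rules, acc) {
  n_acc <- length(acc)
  set.seed(config$seed + 10007L)
  gen <- coalescent_branches(n_acc)
  n_mut <- rpois(1L, config$theta / 2 * sum(gen$length))
  region <- config$region
  excl <- unlist(lapply(rules$pos, function(p) (p - 5L):(p + 5L)))
  candidates <- setdiff(seq.int(region[1], region[2]), excl)
  n_mut <- min(n_mut, length(candidates))
  if (n_mut == 0L) return(empty_variants())
  sites <- sample(candidates, n_mut)
  branch <- sample.int(length(gen$length), n_mut, replace = TRUE,
                       prob = gen$length)
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n_mut)
  for (m in seq_len(n_mut)) {
    carriers <- gen$leaves[[branch[m]]]
    refb <- ref_slice(reference, sites[m], sites[m])
    altb <- sample(setdiff(bases, refb), 1L)
    rows[[m]] <- tibble(
      accession = acc[carriers], chrom = config$chrom, pos = sites[m],
      ref = refb, alt = altb, genotype = "hom_alt", gq = 60, ad_alt = 30
    )
  }
  dplyr::bind_rows(rows)
}

#' Construct a synthetic stand-in for the published per-accession variant
#' matrices of the two widespread haplotypes
#'
#' The original supplementary matrices (the 40 type-7 and 262 type-13
#' landraces over the -1 kb..+1 kb gene fragment) are not redistributable
#' here; this generator builds a SYNTHETIC matrix with the same printed
#' summary structure: 41 variable sites over the combined 302 landraces
#' (22 of them inside the ORF), 5 distinct type-7 haplotype groups with the
#' two most frequent covering 34 of 40 accessions, and 156 distinct type-13
#' groups with the two most frequent covering 28 of 262.
#'
#' @param seed Integer seed.
#' @return A list with `type7`, `type13` (character matrices of alleles,
#'   rownames = accessions, colnames = site positions), `positions` (the 41
#'   site coordinates) and `orf_sites` (logical, site inside the ORF).
#' @export
synth_s7_like_matrix <- function(seed = 1L) {
  set.seed(seed)
  geo <- hd1_geometry()
  gene_lo <- geo$exon1[1] - 1000L
  gene_hi <- geo$exon2[2] + 1000L
  orf <- c(geo$cds1, geo$cds2)
  in_orf <- function(p) (p >= geo$cds1[1] & p <= geo$cds1[2]) |
    (p >= geo$cds2[1] & p <= geo$cds2[2])
  # 41 sites, exactly 22 inside the ORF
  orf_pool <- c(geo$cds1[1]:geo$cds1[2], geo$cds2[1]:geo$cds2[2])
  non_pool <- setdiff(gene_lo:gene_hi, orf_pool)
  positions <- sort(c(sample(orf_pool, 22L), sample(non_pool, 19L)))
  L <- length(positions)
  refrow <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  flip <- function(b) vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")

  # distinct haplotype patterns as mutations away from a type base pattern
  make_patterns <- function(n_groups, base_sites) {
    base <- refrow
    base[base_sites] <- flip(base[base_sites])
    pats <- list(base)
    used <- list(base_sites)
    while (length(pats) < n_groups) {
      extra <- sample(setdiff(seq_len(L), base_sites),
                      sample.int(3L, 1L))
      key <- sort(extra)
      if (any(vapply(used, function(u) identical(u, key), TRUE))) next
      p <- base
      p[extra] <- flip(p[extra])
      pats[[length(pats) + 1L]] <- p
      used[[length(used) + 1L]] <- key
    }
    pats
  }
  sizes7 <- c(20L, 14L, 3L, 2L, 1L)                      # 5 groups, top 2 = 34
  sizes13 <- c(15L, 13L, rep(2L, 80L), rep(1L, 74L))     # 156 groups, top 2 = 28
  stopifnot(sum(sizes7) == 40L, sum(sizes13) == 262L, length(sizes13) == 156L)
  pats7 <- make_patterns(5L, base_sites = 1:2)
  pats13 <- make_patterns(156L, base_sites = 3:4)
  expand <- function(pats, sizes, prefix) {
    rows <- do.call(rbind, pats[rep(seq_along(sizes), times = sizes)])
    rownames(rows) <- sprintf("%s_%03d", prefix, seq_len(nrow(rows)))
    colnames(rows) <- positions
    rows
  }
  m7 <- expand(pats7, sizes7, "t7")
  m13 <- expand(pats13, sizes13, "t13")
  # ensure all 41 columns are variable over the combined matrix
  comb <- rbind(m7, m13)
  for (j in seq_len(L)) {
    if (length(unique(comb[, j])) == 1L) {
      # make the last singleton type-13 accession carry a private allele
      m13[nrow(m13), j] <- flip(m13[nrow(m13), j])
    }
  }
  list(type7 = m7, type13 = m13, positions = positions,
       orf_sites = in_orf(positions))
}
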