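#' Translate the coding sequence of a gene model
#'
#' Splices the CDS intervals out of the reference (reverse-complementing on
#' the minus strand), translates with the standard genetic code, and stops
#' at the first stop codon, reporting its residue index.
#'
#' @param gene A [gene_model()].
#' @param genome A [reference_region()] covering the gene (reference or a
#'   mutant genome in the same coordinates).
#' @return A list with `protein` (character, translation up to but excluding
#'   the first stop), `stop_index` (1-based residue index of the first stop
#'   codon, or `NA` if none), and `n_codons`.
#' @export
translate_cds <- function(gene, genome) {
  cds_seq <- spliced_cds(gene, genome)
  if (grepl("N", cds_seq, fixed = TRUE)) {
    abort(sprintf("CDS contains N at offset %d",
                  as.integer(regexpr("N", cds_seq, fixed = TRUE))))
  }
  n_codons <- nchar(cds_seq) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_seq), if.fuzzy.codon = "X",
    no.init.codon = TRUE
  ))
  if (substr(aa, 1, 1) != "M") {
    warn("CDS does not begin with a start codon")
  }
  stop_at <- regexpr("*", aa, fixed = TRUE)
  stop_index <- if (stop_at > 0) as.integer(stop_at) else NA_integer_
  protein <- if (!is.na(stop_index)) substr(aa, 1L, stop_index - 1L) else aa
  list(protein = protein, stop_index = stop_index, n_codons = n_codons)
}

spliced_cds <- function(gene, genome) {
  pieces <- purrr::map2_chr(gene$cds$start, gene$cds$end,
                            function(s, e) ref_slice(genome, s, e))
  s <- paste0(pieces, collapse = "")
  if (gene$strand == "-") s <- reverse_complement(s)
  s
}

#' Annotate variants with gene-model-aware consequences
#'
#' A deliberately restricted effect annotator covering what the haplotype
#' survey needs: the gene compartment of each variant (`CDS`, `intron`,
#' `UTR`, `upstream`, `downstream`) and for coding variants the functional
#' impact. CDS SNPs get `synonymous` / `missense` / `stop_gained` by codon
#' recomputation; CDS indels get `frameshift` or `inframe_indel` by length
#' modulo 3. `stop_gained` residues are named by the pre-mutation codon
#' index (the "early stop at Arg368" convention: the reference residue at
#' the position of the new stop).
#'
#' @param variants Normalized variant tibble (see [normalize_variants()]).
#' @param gene A [gene_model()].
#' @param reference A [reference_region()] covering the gene.
#' @return The input tibble with columns `compartment`, `effect`,
#'   `residue_index`, `aa_from`, `aa_to` appended.
#' @export
annotate_variants <- function(variants, gene, reference) {
  ann <- purrr::pmap(
    list(variants$pos, variants$ref, variants$alt),
    function(pos, ref, alt) annotate_one(pos, ref, alt, gene, reference)
  )
  dplyr::bind_cols(
    variants,
    tibble(
      compartment = purrr::map_chr(ann, "compartment"),
      effect = purrr::map_chr(ann, "effect"),
      residue_index = purrr::map_int(ann, "residue_index"),
      aa_from = purrr::map_chr(ann, "aa_from"),
      aa_to = purrr::map_chr(ann, "aa_to")
    )
  )
}

annotate_one <- function(pos, ref, alt, gene, reference) {
  if (pos < gene$region[1] || pos > gene$region[2]) {
    abort(sprintf("variant at %d outside surveyed region %d-%d",
                  pos, gene$region[1], gene$region[2]))
  }
  is_snp <- nchar(ref) == 1L && nchar(alt) == 1L
  # position of the first altered base: SNP = pos; anchored indel = pos + 1
  eff_pos <- if (is_snp) pos else pos + 1L
  comp <- gene_compartment(gene, eff_pos)
  none <- list(compartment = comp, effect = "noncoding",
               residue_index = NA_integer_, aa_from = NA_character_,
               aa_to = NA_character_)
  if (comp != "CDS") return(none)

  if (is_snp) {
    return(annotate_cds_snp(pos, ref, alt, gene, reference))
  }
  # anchored indel inside CDS
  del_len <- nchar(ref) - 1L
  ins_len <- nchar(alt) - 1L
  if (del_len > 0L) {
    span <- c(pos + 1L, pos + del_len)
    in_one <- any(span[1] >= gene$cds$start & span[2] <= gene$cds$end)
    if (!in_one) abort(sprintf(
      "indel at %d spans a CDS interval boundary; refusing to annotate", pos))
  }
  shift <- abs(del_len - ins_len) %% 3L != 0L
  off <- cds_offset(gene, eff_pos)
  list(
    compartment = "CDS",
    effect = if (shift) "frameshift" else "inframe_indel",
    residue_index = as.integer(ceiling(off / 3)),
    aa_from = NA_character_, aa_to = NA_character_
  )
}

annotate_cds_snp <- function(pos, ref, alt, gene, reference) {
  off <- cds_offset(gene, pos)
  codon_idx <- as.integer(ceiling(off / 3))
  phase <- (off - 1L) %% 3L + 1L
  cds_seq <- spliced_cds(gene, reference)
  codon <- substr(cds_seq, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  base <- if (gene$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  mutant <- codon
  substr(mutant, phase, phase) <- base
  aa_from <- codon_aa(codon)
  aa_to <- codon_aa(mutant)
  effect <- if (aa_to == "*") "stop_gained"
            else if (aa_from == aa_to) "synonymous"
            else "missense"
  list(compartment = "CDS", effect = effect, residue_index = codon_idx,
       aa_from = aa_from, aa_to = aa_to)
}

codon_aa <- function(codon) {
  # plain table lookup: translate() would apply initiator-codon semantics
  # (CTG/TTG -> M) to a standalone codon
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (is.na(aa)) abort(sprintf("cannot translate codon '%s'", codon))
  aa
}

#' Write consequence annotations as TSV
#'
#' @param annotated Output of [annotate_variants()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotated, path) {
  cols <- intersect(
    c("accession", "pos", "ref", "alt", "compartment", "effect",
      "residue_index", "aa_from", "aa_to"),
    names(annotated)
  )
  readr::write_tsv(annotated[, cols], path)
  invisible(path)
}
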