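#' Built-in loss-of-function haplotype rules for Hd1
#'
#' The ten published loss-of-function *hd1* haplotype rules on the IRGSP-1.0
#' Nipponbare frame. Each rule names the reference position of the causal
#' change, the kind of change (SNP, deletion or insertion), its payload (the
#' alternate base for SNPs; the length in bp for indels) and its protein
#' consequence class (frameshift `FS` or premature stop `STOP`):
#'
#' * types 2, 3: 1-bp deletions (frameshift)
#' * type 7: 4-bp deletion (frameshift)
#' * type 12: C-to-T stop
#' * type 13: 2-bp deletion (the Kasalath allele; frameshift)
#' * type 18: 43-bp deletion (frameshift; the deleted sequence is absent
#'   from the Nipponbare reference, so this rule is classified by rule only
#'   and never consequence-annotated)
#' * type 19: 1.9-kb LTR-retrotransposon insertion in exon 2 (frameshift)
#' * types 20, 21, 22: SNPs creating early stops at residues 368, 206, 193
#'
#' @param chrom Chromosome name the rule coordinates live on.
#' @return A tibble with columns `type_label`, `chrom`, `pos`, `ref`,
#'   `change_kind`, `change_payload`, `consequence_class`.
#' @export
hd1_rules <- function(chrom = "chr6") {
  tibble(
    type_label = paste0("type", c(2, 3, 7, 12, 13, 18, 19, 20, 21, 22)),
    chrom = chrom,
    pos = c(9337102L, 9336853L, 9338220L, 9338243L, 9338004L,
            9337242L, 9338032L, 9338273L, 9337150L, 9337112L),
    ref = c("G", "C", "AAGA", "C", "TT", NA, NA, "A", "C", "C"),
    change_kind = c("del", "del", "del", "snp", "del",
                    "del", "ins", "snp", "snp", "snp"),
    change_payload = c("1", "1", "4", "T", "2", "43", "1901", "T", "T", "A"),
    consequence_class = c("FS", "FS", "FS", "STOP", "FS",
                          "FS", "FS", "STOP", "STOP", "STOP")
  )
}

#' Read a haplotype rule table (TSV)
#'
#' Expected columns: `type_label`, `chrom`, `pos`, `ref`, `change_kind`
#' (`snp`/`del`/`ins`), `change_payload`, `consequence_class`.
#'
#' @param path TSV file.
#' @return Rule tibble as from [hd1_rules()].
#' @export
read_rule_table <- function(path) {
  rules <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             pos = readr::col_integer(),
                             change_payload = readr::col_character(),
                             .default = readr::col_character()
                           ))
  required <- c("type_label", "chrom", "pos", "change_kind",
                "change_payload", "consequence_class")
  missing_cols <- setdiff(required, names(rules))
  if (length(missing_cols)) {
    abort(paste0("rule table missing columns: ", paste(missing_cols, collapse = ",")))
  }
  if (!"ref" %in% names(rules)) rules$ref <- NA_character_
  bad <- setdiff(unique(rules$change_kind), c("snp", "del", "ins"))
  if (length(bad)) abort(paste0("unknown change_kind: ", paste(bad, collapse = ",")))
  if (anyDuplicated(rules$type_label)) abort("rule type labels must be unique")
  tibble::as_tibble(rules)
}

#' Write a haplotype rule table (TSV)
#'
#' @param rules Rule tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(rules, path) {
  readr::write_tsv(rules, path)
  invisible(path)
}

#' Indel length implied by a rule
#' @noRd
rule_indel_len <- function(rule_row) {
  as.integer(rule_row$change_payload)
}
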