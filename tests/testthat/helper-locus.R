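# shared fixtures, built once per test run
the_locus <- make_reference(seed = 1L)
the_ref <- the_locus$reference
the_gene <- the_locus$gene
the_rules <- hd1_rules()

rule_row <- function(label) the_rules[the_rules$type_label == label, ]

# a minimal single-sample VCF file from raw body lines
write_mini_vcf <- function(body, path = tempfile(fileext = ".vcf"),
                           sample = "s1",
                           format_lines = c(
                             '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
                             '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
                             '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">')) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    format_lines,
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    body
  ), path)
  path
}

# random cleaned alignment (A/C/G/T only)
random_alignment <- function(n, L, n_var = max(1L, L %/% 5L)) {
  mat <- matrix(sample(c("A", "C", "G", "T"), 1L)[rep(1L, n * L)], n, L)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(base, each = n), n, L)
  var_cols <- sample.int(L, min(n_var, L))
  for (j in var_cols) {
    carriers <- sample.int(n, sample.int(n - 1L, 1L))
    mat[carriers, j] <- sample(setdiff(c("A", "C", "G", "T"), base[j]), 1L)
  }
  rownames(mat) <- paste0("s", seq_len(n))
  region_alignment(mat)
}

empty_variant_tbl <- function() {
  tibble::tibble(accession = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 genotype = character(), gq = numeric(), ad_alt = numeric())
}

empty_sam_tbl <- function() hd1survey:::empty_reads()

decode_flag_tbl <- function(x) {
  x <- hd1survey:::decode_flags(x)
  x$mate_filtered <- FALSE
  x
}
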