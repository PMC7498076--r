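#' Classify accessions against the loss-of-function haplotype rules
#'
#' Applies the rule table to normalized variant records, accession by
#' accession. A rule matches when chromosome and position agree and the
#' change matches in kind and payload: SNP rules require the exact
#' alternate base; deletion rules match on (position, length) only — the
#' first deleted base of the normalized record must sit at the rule
#' position; insertion rules with payloads of 1 kb and larger match any
#' insertion of at least `ins_min_len` within `ins_pos_tol` of the rule
#' position (short-read callers rarely emit the full element), and may also
#' be satisfied by a read-evidence screen call passed via `sv_calls` (the
#' union of the two routes is taken). Zygosity is propagated; accessions
#' matching several rules are flagged `multi`; a missing genotype at a rule
#' site makes that rule *unevaluable* (reported, distinct from absent).
#'
#' @param variants Normalized variant tibble with an `accession` column.
#' @param rules Rule tibble (default [hd1_rules()]).
#' @param sv_calls Optional tibble `accession`, `type_label`, `call` from
#'   the structural screens; rows with `call == "present"` count as
#'   homozygous matches.
#' @param accessions Accession labels to report (defaults to those present
#'   in `variants` and `sv_calls`).
#' @param ins_min_len Minimum emitted insertion length accepted for the
#'   large-insertion rule (default 1000).
#' @param ins_pos_tol Position tolerance for insertion rules (default 10).
#' @return A tibble with one row per accession: `accession`, `matches`
#'   (list-column of `type_label`, `zygosity`), `types` (comma-joined
#'   labels), `functional` (`LOF`, `heterozygous-LOF`, `functional`),
#'   `multi`, `unevaluable` (comma-joined rule labels).
#' @export
classify_accessions <- function(variants, rules = hd1_rules(),
                                sv_calls = NULL, accessions = NULL,
                                ins_min_len = 1000L, ins_pos_tol = 10L) {
  if (is.null(accessions)) {
    accessions <- union(unique(variants$accession),
                        if (!is.null(sv_calls)) unique(sv_calls$accession))
  }
  out <- purrr::map(accessions, function(a) {
    v <- variants[variants$accession == a, , drop = FALSE]
    sv <- if (!is.null(sv_calls)) {
      sv_calls[sv_calls$accession == a & sv_calls$call == "present", ,
               drop = FALSE]
    }
    classify_one(a, v, rules, sv, ins_min_len, ins_pos_tol)
  })
  dplyr::bind_rows(out)
}

#' @rdname classify_accessions
#' @param accession Single accession label (for `classify_accession`).
#' @export
classify_accession <- function(variants, rules = hd1_rules(),
                               sv_calls = NULL, accession = NULL, ...) {
  if (is.null(accession)) {
    accession <- if (nrow(variants)) variants$accession[1] else "accession"
  }
  classify_accessions(variants, rules, sv_calls, accessions = accession, ...)
}

classify_one <- function(acc, v, rules, sv, ins_min_len, ins_pos_tol) {
  matches <- list(); uneval <- character(0)
  for (r in seq_len(nrow(rules))) {
    rule <- rules[r, ]
    hit <- match_rule(v, rule, ins_min_len, ins_pos_tol)
    if (identical(hit, "unevaluable")) {
      uneval <- c(uneval, rule$type_label)
    } else if (!is.null(hit)) {
      matches[[length(matches) + 1L]] <- tibble(
        type_label = rule$type_label, zygosity = hit
      )
    } else if (!is.null(sv) && rule$type_label %in% sv$type_label) {
      matches[[length(matches) + 1L]] <- tibble(
        type_label = rule$type_label, zygosity = "hom"
      )
    }
  }
  m <- if (length(matches)) dplyr::distinct(dplyr::bind_rows(matches)) else
    tibble(type_label = character(), zygosity = character())
  functional <- if (nrow(m) == 0L) "functional"
    else if (any(m$zygosity == "hom")) "LOF"
    else "heterozygous-LOF"
  tibble(
    accession = acc,
    matches = list(m),
    types = paste(m$type_label, collapse = ","),
    functional = functional,
    multi = length(unique(m$type_label)) > 1L,
    unevaluable = paste(uneval, collapse = ",")
  )
}

# returns zygosity ("hom"/"het"), "unevaluable", or NULL
match_rule <- function(v, rule, ins_min_len, ins_pos_tol) {
  if (nrow(v) == 0L) return(NULL)
  v <- v[v$chrom == rule$chrom, , drop = FALSE]
  if (nrow(v) == 0L) return(NULL)
  ref_len <- nchar(v$ref); alt_len <- nchar(v$alt)
  hit <- switch(
    rule$change_kind,
    snp = which(v$pos == rule$pos & ref_len == 1L & alt_len == 1L &
                  v$alt == rule$change_payload),
    del = which(v$pos + 1L == rule$pos & alt_len == 1L &
                  ref_len - alt_len == as.integer(rule$change_payload)),
    ins = {
      want <- as.integer(rule$change_payload)
      if (want >= 1000L) {
        which(abs(v$pos - rule$pos) <= ins_pos_tol & ref_len == 1L &
                alt_len - ref_len >= ins_min_len)
      } else {
        which(v$pos == rule$pos & ref_len == 1L &
                alt_len - ref_len == want)
      }
    }
  )
  if (length(hit) == 0L) return(NULL)
  g <- v$genotype[hit]
  if (any(g == "hom_alt")) "hom"
  else if (any(g == "het")) "het"
  else if (any(g == "missing")) "unevaluable"
  else NULL
}

#' Collapse accessions into distinct region haplotypes
#'
#' Accessions with identical allele vectors across all sites form one
#' group. Groups are numbered by descending size, ties broken by the
#' lexicographically smallest member label ("first" group = most frequent,
#' matching the published "34 with the first 2 types" phrasing).
#'
#' @param x A [region_alignment()], a character matrix (rows = accessions),
#'   or a data frame of per-site alleles with accession rownames.
#' @return A tibble with one row per group: `group`, `size`,
#'   `representative` (smallest member label), `members` (list-column).
#'   The number of groups is `nrow()` of the result.
#' @export
collapse_haplotypes <- function(x) {
  if (inherits(x, "region_alignment")) x <- x$mat
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) abort("expected an alignment, matrix or data frame")
  if (is.null(rownames(x))) rownames(x) <- paste0("acc", seq_len(nrow(x)))
  pattern <- apply(x, 1L, paste0, collapse = "\r")
  split_members <- split(rownames(x), pattern)
  groups <- tibble(
    size = unname(lengths(split_members)),
    representative = unname(purrr::map_chr(split_members, ~ sort(.x)[1])),
    members = unname(purrr::map(split_members, sort))
  )
  groups <- dplyr::arrange(groups, dplyr::desc(.data$size),
                           .data$representative)
  groups$group <- seq_len(nrow(groups))
  groups[, c("group", "size", "representative", "members")]
}

#' Cross-tabulate haplotype calls by origin
#'
#' Builds the country-by-haplotype contingency table of the survey: one row
#' per origin, one column per haplotype type, with row totals. Accessions
#' without metadata are counted under `"unknown"` (with a warning).
#'
#' @param calls Output of [classify_accessions()].
#' @param metadata Tibble `accession`, `origin`, `subpop`, `traditional`.
#' @param traditional_only Restrict to traditional accessions (default
#'   `FALSE`).
#' @return A tibble: `origin`, one numeric column per type, `total` (the
#'   number of accessions from that origin carrying any listed type).
#' @export
summarize_by_origin <- function(calls, metadata, traditional_only = FALSE) {
  long <- calls %>%
    dplyr::select("accession", "matches") %>%
    tidyr::unnest("matches")
  merged <- dplyr::left_join(long, metadata, by = "accession")
  if (any(is.na(merged$origin))) {
    warn("accessions without metadata counted under 'unknown'")
    merged$origin[is.na(merged$origin)] <- "unknown"
  }
  if (traditional_only) {
    merged <- merged[!is.na(merged$traditional) & merged$traditional, ,
                     drop = FALSE]
  }
  type_levels <- sort(unique(merged$type_label))
  wide <- merged %>%
    dplyr::count(.data$origin, .data$type_label) %>%
    tidyr::pivot_wider(names_from = "type_label", values_from = "n",
                       values_fill = 0L)
  for (tl in setdiff(type_levels, names(wide))) wide[[tl]] <- 0L
  wide <- wide[, c("origin", type_levels), drop = FALSE]
  wide$total <- rowSums(wide[, type_levels, drop = FALSE])
  dplyr::arrange(wide, .data$origin)
}

#' Write an origin summary as TSV, rendering zero cells as "--"
#'
#' @param summary Output of [summarize_by_origin()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_origin_summary <- function(summary, path) {
  out <- summary
  for (cl in setdiff(names(out), "origin")) {
    out[[cl]] <- ifelse(out[[cl]] == 0, "--", as.character(out[[cl]]))
  }
  readr::write_tsv(out, path)
  invisible(path)
}
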