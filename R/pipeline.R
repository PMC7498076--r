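#' Pipeline configuration
#'
#' Collects the inputs and thresholds of the end-to-end survey. Either file
#' paths (reference FASTA, gene model GFF3, rule table TSV, per-accession
#' VCFs, metadata TSV) or a [synth_config()] for a fully synthetic run.
#'
#' @param synth A [synth_config()] for synthetic runs (default), or `NULL`
#'   when file inputs are given.
#' @param reference_path,gene_model_path,rule_table_path,metadata_path
#'   Optional file inputs overriding the synthetic locus.
#' @param vcf_paths Named character vector of per-accession VCFs (names =
#'   accession labels), for file-based runs.
#' @param screen A [screen_config()].
#' @param popgen_window Window for the diversity statistics (default the
#'   synthetic region).
#' @param network_limit Parsimony connection limit (default 2).
#' @param bootstrap_reps Bootstrap replicates for the NJ tree (default 100;
#'   the published analysis used 1,000).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            reference_path = NULL, gene_model_path = NULL,
                            rule_table_path = NULL, metadata_path = NULL,
                            vcf_paths = NULL,
                            screen = screen_config(),
                            popgen_window = NULL,
                            network_limit = 2L,
                            bootstrap_reps = 100L,
                            seed = 1L,
                            out_dir = tempfile("hd1run")) {
  for (p in c(reference_path, gene_model_path, rule_table_path,
              metadata_path, vcf_paths)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("input path does not exist: %s", p))
    }
  }
  structure(
    list(synth = synth, reference_path = reference_path,
         gene_model_path = gene_model_path,
         rule_table_path = rule_table_path, metadata_path = metadata_path,
         vcf_paths = vcf_paths, screen = screen,
         popgen_window = popgen_window, network_limit = network_limit,
         bootstrap_reps = bootstrap_reps, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the end-to-end haplotype survey
#'
#' Composes the full pipeline: high-quality filtering, rule classification,
#' the large-insertion read screen for carriers of the retrotransposon
#' rule, haplotype collapsing, origin summaries, windowed diversity and
#' neutrality statistics, the bootstrapped NJ tree and the parsimony
#' network. All outputs are written under `config$out_dir` together with a
#' run manifest (seed, configuration hash, package version), and returned
#' invisibly as a list.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with `calls`, `summary`, `stats`, `tree`,
#'   `network`, `collapse`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  rules <- stage("rules", {
    if (!is.null(config$rule_table_path)) read_rule_table(config$rule_table_path)
    else hd1_rules()
  })

  if (!is.null(config$vcf_paths)) {
    reference <- stage("reference", read_fasta_reference(config$reference_path))
    gene <- stage("gene_model", read_gene_model(config$gene_model_path))
    metadata <- stage("metadata",
                      readr::read_tsv(config$metadata_path,
                                      show_col_types = FALSE))
    variants <- stage("read_vcf", purrr::imap_dfr(
      config$vcf_paths,
      function(p, acc) read_vcf(p, accession = acc)
    ))
    truth <- NULL
  } else {
    cohort <- stage("synthesize", generate_cohort(config$synth))
    reference <- cohort$reference; gene <- cohort$gene
    metadata <- cohort$metadata; truth <- cohort$truth
    variants <- cohort$variants
  }
  accessions <- metadata$accession

  variants <- stage("normalize", normalize_variants(variants, reference))
  hq <- stage("filter", filter_high_quality(variants))

  calls <- stage("classify",
                 classify_accessions(hq, rules, accessions = accessions))

  # read screen for the large-insertion rule: union route on synthetic runs
  sv <- NULL
  ins_rules <- rules[rules$change_kind == "ins", ]
  ins_rules <- ins_rules[as.integer(ins_rules$change_payload) >= 1000L, ]
  if (is.null(config$vcf_paths) && nrow(ins_rules) && !is.null(truth)) {
    sv <- stage("screen", screen_cohort_carriers(
      truth, ins_rules, reference, config
    ))
    calls <- stage("classify",
                   classify_accessions(hq, rules, sv_calls = sv,
                                       accessions = accessions))
  }

  origin <- stage("summarize", summarize_by_origin(calls, metadata))

  region <- if (!is.null(config$popgen_window)) config$popgen_window else
    gene$region
  aln <- stage("alignment",
               vcf_to_alignment(hq, reference, region,
                                accessions = accessions))
  groups <- tibble(label = accessions,
                   group = ifelse(calls$types == "", "wildtype", calls$types))
  stats <- stage("popgen", suppressWarnings(region_stats(aln, groups)))

  # tree + network over the distinct haplotypes of the gene region
  gene_aln <- stage("gene_alignment", subset_alignment(
    aln, window = c(max(region[1], gene_span(gene)[1] - 1000L),
                    min(region[2], gene_span(gene)[2] + 1000L))
  ))
  groups_tbl <- stage("collapse", collapse_haplotypes(gene_aln))
  haps <- tibble(
    label = sprintf("hap%03d", groups_tbl$group),
    seq = apply(gene_aln$mat[groups_tbl$representative, , drop = FALSE],
                1L, paste0, collapse = ""),
    freq = groups_tbl$size,
    group = purrr::map_chr(groups_tbl$members, function(m) {
      g <- groups$group[match(m, groups$label)]
      names(sort(table(g), decreasing = TRUE))[1]
    })
  )
  net <- stage("network", parsimony_network(haps, limit = config$network_limit))
  tree <- if (nrow(groups_tbl) >= 4L) {
    hap_aln <- region_alignment(
      gene_aln$mat[groups_tbl$representative, , drop = FALSE],
      labels = haps$label, positions = gene_aln$positions
    )
    stage("tree", bootstrap_support(hap_aln, reps = config$bootstrap_reps,
                                    seed = config$seed))
  } else NULL

  manifest <- tibble(
    package = "hd1survey",
    version = as.character(utils::packageVersion("hd1survey")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_accessions = length(accessions),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )

  # outputs
  od <- config$out_dir
  readr::write_tsv(calls %>% dplyr::select(-"matches"),
                   file.path(od, "calls.tsv"))
  write_origin_summary(origin, file.path(od, "origin_summary.tsv"))
  write_diversity_tsv(stats, file.path(od, "diversity.tsv"))
  if (!is.null(tree)) write_newick(tree, file.path(od, "tree.nwk"))
  write_network(net, file.path(od, "network_nodes.tsv"),
                file.path(od, "network_edges.tsv"))
  readr::write_tsv(manifest, file.path(od, "manifest.tsv"))

  invisible(list(calls = calls, summary = origin, stats = stats,
                 tree = tree, network = net, collapse = groups_tbl,
                 manifest = manifest, sv_calls = sv))
}

# run the read screen over the accessions whose truth says they carry (or
# not) the large insertion; synthetic route used by run_pipeline
screen_cohort_carriers <- function(truth, ins_rules, reference, config) {
  rows <- list()
  for (r in seq_len(nrow(ins_rules))) {
    rule <- ins_rules[r, ]
    bp <- rule$pos
    carriers <- truth$accession[truth$type_label == rule$type_label]
    for (acc in carriers) {
      i <- match(acc, truth$accession)
      pl <- plant_haplotype(reference, rule, accession = acc,
                            seed = config$synth$seed + i)
      reads <- simulate_read_pairs(
        pl$genome, reference, pl$variants,
        depth = config$synth$depth, insert_mu = config$synth$insert_mu,
        insert_sigma = config$synth$insert_sigma,
        read_len = config$synth$read_len,
        seed = config$synth$seed + i,
        window = c(bp - 2000L, bp + 2000L)
      )
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(accession = acc, type_label = rule$type_label),
        screen_large_insertion(reads, bp, config$screen)
      )
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else NULL
}
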