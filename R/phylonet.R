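#' Pairwise p-distance matrix
#'
#' `d(i, j)` is the proportion of differing sites among the sites compared.
#' With `deletion = "complete"` every column containing a gap or `N` in any
#' row is discarded globally before comparison; with `"pairwise"` only the
#' sites missing within each pair are discarded for that pair. Computation
#' is delegated to `ape::dist.dna(model = "raw")`.
#'
#' @param a A [region_alignment()].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric numeric matrix with zero diagonal, labeled by
#'   accession.
#' @export
p_distance_matrix <- function(a, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (nrow(a$mat) < 2L) abort("need at least 2 sequences")
  d <- ape::dist.dna(aln_to_DNAbin(a), model = "raw",
                     pairwise.deletion = deletion == "pairwise")
  m <- as.matrix(d)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("no comparable sites between '%s' and '%s'",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj()`; the three-taxon case uses
#' the closed form). Negative branch lengths, an artifact of the NJ length
#' formulas, are clamped to zero with the deficit transferred to the
#' sibling branches of the same node (standard practice; the original
#' PHYLIP behavior is not reproduced bit-for-bit).
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) abort("need at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-8) abort("distance matrix is not symmetric")
  if (nrow(m) == 3L) {
    lab <- rownames(m) %||% paste0("t", 1:3)
    b1 <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
    b2 <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
    b3 <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
    txt <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                   lab[1], b1, lab[2], b2, lab[3], b3)
    return(ape::read.tree(text = txt))
  }
  tree <- ape::nj(stats::as.dist(m))
  clamp_negative_branches(tree)
}

clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (length(neg) == 0L) break
    e <- neg[1]
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      tree$edge.length[sibs] <- tree$edge.length[sibs] + deficit / length(sibs)
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap support for the splits of the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance/NJ tree for each replicate, and reports, for every internal
#' split of the full-data tree, the fraction of replicates containing it
#' (`ape::prop.clades` counting). Supports are mapped onto the full-data
#' tree, not onto a consensus.
#'
#' @param a A [region_alignment()].
#' @param reps Number of bootstrap replicates (the published analysis used
#'   1,000; tests use fewer).
#' @param seed Integer seed (fixes the resampling).
#' @param deletion Passed to [p_distance_matrix()].
#' @return A list of class `nj_boot`: `tree` (full-data tree with supports
#'   as `node.label`), `support` (tibble `node`, `support`), `reps`.
#' @export
bootstrap_support <- function(a, reps = 100L, seed = 1L,
                              deletion = "pairwise") {
  if (reps < 1L) abort("reps must be >= 1")
  full <- neighbor_joining(p_distance_matrix(a, deletion))
  set.seed(seed)
  L <- ncol(a$mat)
  boots <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    ar <- region_alignment(a$mat[, cols, drop = FALSE], labels = a$labels,
                           positions = seq_len(L))
    boots[[r]] <- neighbor_joining(p_distance_matrix(ar, deletion))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / reps
  tree <- full
  tree$node.label <- format(support, trim = TRUE)
  structure(
    list(tree = tree,
         support = tibble(node = seq_along(support) + length(full$tip.label),
                          support = support),
         reps = reps),
    class = "nj_boot"
  )
}

#' @export
print.nj_boot <- function(x, ...) {
  cat(sprintf("<nj_boot> %d tips, %d replicates, mean split support %.2f\n",
              length(x$tree$tip.label), x$reps, mean(x$support$support)))
  invisible(x)
}

#' Tidy the split supports of a bootstrapped tree
#' @param x An `nj_boot` object.
#' @param ... Unused.
#' @return Tibble `node`, `support`.
#' @method tidy nj_boot
#' @export
tidy.nj_boot <- function(x, ...) x$support

#' One-row summary of a bootstrapped tree
#' @param x An `nj_boot` object.
#' @param ... Unused.
#' @return Tibble `n_tips`, `reps`, `mean_support`, `min_support`.
#' @method glance nj_boot
#' @export
glance.nj_boot <- function(x, ...) {
  tibble(
    n_tips = length(x$tree$tip.label), reps = x$reps,
    mean_support = mean(x$support$support),
    min_support = min(x$support$support)
  )
}

#' Write a tree as Newick (supports as internal labels)
#'
#' @param tree An `ape::phylo` tree or an `nj_boot` result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "nj_boot")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Distance matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  m <- as.matrix(d)
  lines <- c(
    sprintf("%5d", nrow(m)),
    vapply(seq_len(nrow(m)), function(i) {
      paste0(formatC(rownames(m)[i], width = -10),
             paste(sprintf("%.6f", m[i, ]), collapse = " "))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}
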