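# independent oracles used by the tests; deliberately brute-force

# all equivalent VCF-style representations (pos, ref, alt) of a deletion of
# `len` bases producing the same haplotype, by exhaustive shift-and-compare
enumerate_del_representations <- function(reference, pos, len,
                                          search = 30L) {
  target <- local({
    off <- pos - reference$start + 1L
    paste0(substr(reference$seq, 1L, off - 1L),
           substr(reference$seq, off + len, nchar(reference$seq)))
  })
  reps <- list()
  for (p in seq(max(reference$start, pos - search),
                min(ref_end(reference) - len, pos + search))) {
    off <- p - reference$start + 1L
    candidate <- paste0(substr(reference$seq, 1L, off - 1L),
                        substr(reference$seq, off + len, nchar(reference$seq)))
    if (candidate == target) {
      anchor <- substr(reference$seq, off - 1L, off - 1L)
      deleted <- substr(reference$seq, off, off + len - 1L)
      reps[[length(reps) + 1L]] <- list(
        pos = p - 1L, ref = paste0(anchor, deleted), alt = anchor
      )
    }
  }
  reps
}

# direct O(n^2 L) pairwise-difference loop
brute_pairwise_stats <- function(a) {
  m <- a$mat
  n <- nrow(m); L <- ncol(m)
  total <- 0; npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + sum(m[i, ] != m[j, ])
      npairs <- npairs + 1
    }
  }
  S <- 0L; eta <- 0L
  for (col in seq_len(L)) {
    u <- unique(m[, col])
    if (length(u) > 1L) { S <- S + 1L; eta <- eta + length(u) - 1L }
  }
  list(k = total / npairs, S = S, eta = eta, pi = total / npairs / L)
}

# least-squares fit of a 4-taxon additive distance matrix on each of the 3
# unrooted topologies; returns the best topology as a split string
best_quartet_split <- function(m) {
  labs <- rownames(m)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  rss <- vapply(splits, function(pair) {
    # topology: {labs[pair]} | rest; 5 branch lengths via least squares
    a <- pair[1]; b <- pair[2]; cd <- setdiff(1:4, pair)
    X <- rbind(
      c(1, 1, 0, 0, 0),  # d(a,b) = ea + eb
      c(1, 0, 1, 0, 1),  # d(a,c) = ea + ec + em
      c(1, 0, 0, 1, 1),  # d(a,d)
      c(0, 1, 1, 0, 1),  # d(b,c)
      c(0, 1, 0, 1, 1),  # d(b,d)
      c(0, 0, 1, 1, 0)   # d(c,d)
    )
    y <- c(m[a, b], m[a, cd[1]], m[a, cd[2]],
           m[b, cd[1]], m[b, cd[2]], m[cd[1], cd[2]])
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  pair <- splits[[which.min(rss)]]
  paste(sort(labs[pair]), collapse = "|")
}

# split (bipartition) of tips implied by each internal edge of a phylo tree
tree_splits <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  vapply(parts, function(p) paste(sort(labs[p]), collapse = "|"), "")
}
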