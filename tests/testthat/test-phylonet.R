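test_that("p-distances match hand counts under both deletion modes", {
  a <- region_alignment(c(x = "ACGT", y = "ACGA"))
  expect_equal(p_distance_matrix(a)["x", "y"], 0.25)
  same <- region_alignment(c(x = "ACGT", y = "ACGT"))
  expect_equal(p_distance_matrix(same)["x", "y"], 0)
  # {AC-T, ACGT, ACGA}: complete deletion drops column 3 globally
  tri <- region_alignment(c(a = "AC-T", b = "ACGT", c = "ACGA"))
  pw <- p_distance_matrix(tri, "pairwise")
  cd <- p_distance_matrix(tri, "complete")
  expect_equal(pw["a", "b"], 0)        # 3 comparable, 0 mismatch
  expect_equal(pw["a", "c"], 1 / 3)
  expect_equal(pw["b", "c"], 1 / 4)
  expect_equal(cd["b", "c"], 1 / 3)    # column 3 removed for everyone
  expect_equal(cd["a", "b"], 0)
  # a pair with no comparable sites errors with the pair named
  bad <- region_alignment(c(p = "A-", q = "-A", r = "AA"))
  expect_error(p_distance_matrix(bad, "pairwise"), "no comparable sites")
})

test_that("neighbor joining recovers three- and four-taxon additive trees", {
  m3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- neighbor_joining(m3)
  expect_equal(sort(tr3$tip.label), c("a", "b", "c"))
  # closed form: b_a = (d_ab + d_ac - d_bc)/2 = 1, b_b = 2, b_c = 3
  lens <- setNames(tr3$edge.length,
                   tr3$tip.label[tr3$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 2, c = 3))

  # 4-taxon additive matrix from tree ((a:1,b:2):1,(c:3,d:4))
  m4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m4["a", "b"] <- m4["b", "a"] <- 3
  m4["a", "c"] <- m4["c", "a"] <- 5
  m4["a", "d"] <- m4["d", "a"] <- 6
  m4["b", "c"] <- m4["c", "b"] <- 6
  m4["b", "d"] <- m4["d", "b"] <- 7
  m4["c", "d"] <- m4["d", "c"] <- 7
  tr4 <- neighbor_joining(m4)
  # path lengths reproduce the additive distances exactly
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(m4), colnames(m4)], m4,
               tolerance = 1e-9)
  # and the topology equals the least-squares enumeration oracle's choice
  expect_true(paste(sort(c("a", "b")), collapse = "|") == best_quartet_split(m4))
  split_ab <- tree_splits(tr4)
  expect_true("a|b" %in% split_ab || "c|d" %in% split_ab)

  # permuting labels yields an isomorphic tree
  perm <- c("c", "a", "d", "b")
  trp <- neighbor_joining(m4[perm, perm])
  expect_true(ape::all.equal.phylo(tr4, trp, use.edge.length = TRUE))

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3")
  asym <- m4; asym[1, 2] <- 9
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("negative NJ branch lengths are clamped with compensation", {
  # a non-additive matrix known to produce a negative NJ branch
  set.seed(41)
  m <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m[upper.tri(m)] <- runif(10, 0.1, 0.2)
  m <- m + t(m)
  m["a", "b"] <- m["b", "a"] <- 0.5   # distort
  tr <- neighbor_joining(m)
  expect_true(all(tr$edge.length >= 0))
  raw <- ape::nj(stats::as.dist(m))
  expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-9)
})

test_that("bootstrap support is deterministic and finds solid splits", {
  # two clusters separated by >= 20 fixed differences
  set.seed(43)
  base <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  other <- base
  other[1:20] <- vapply(base[1:20],
                        function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  mat <- rbind(
    c1 = base, c2 = base, c3 = base,
    d1 = other, d2 = other, d3 = other
  )
  # private mutations so tips are distinct
  for (i in 1:6) mat[i, 20 + 5 * i] <- setdiff(c("A", "C", "G", "T"),
                                               mat[i, 20 + 5 * i])[1]
  a <- region_alignment(mat)
  bs <- bootstrap_support(a, reps = 200, seed = 2)
  # the split separating the two clusters has support >= 0.99
  expect_gte(max(bs$support$support), 0.99)
  # determinism
  bs2 <- bootstrap_support(a, reps = 200, seed = 2)
  expect_identical(bs$support, bs2$support)
  # reps = 1: supports are 0 or 1
  b1 <- bootstrap_support(a, reps = 1, seed = 3)
  expect_true(all(b1$support$support %in% c(0, 1)))
  # tidy/glance surface
  expect_equal(nrow(tidy(bs)), nrow(bs$support))
  expect_equal(glance(bs)$reps, 200)
})

test_that("newick output round-trips through the reader", {
  m3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(m3)
  p <- tempfile(fileext = ".nwk")
  write_newick(tr, p)
  back <- ape::read.tree(p)
  expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
})

test_that("the parsimony network follows single-step connection rules", {
  # two haplotypes one step apart: a single edge
  net1 <- parsimony_network(tibble::tibble(
    label = c("h1", "h2"), seq = c("AAAA", "AAAT")))
  expect_equal(nrow(net1$edges), 1L)
  expect_equal(n_components(net1), 1)

  # d(A,B)=1, d(B,C)=1, d(A,C)=2: path A-B-C, no inferred intermediate
  net2 <- parsimony_network(tibble::tibble(
    label = c("A", "B", "C"), seq = c("AAAA", "AAAT", "AATT"),
    freq = c(5, 3, 1)))
  expect_equal(sum(net2$nodes$inferred), 0L)
  expect_equal(nrow(net2$edges), 2L)
  expect_equal(n_components(net2), 1)

  # two haplotypes two steps apart: one inferred intermediate, freq 0
  net3 <- parsimony_network(tibble::tibble(
    label = c("h1", "h2"), seq = c("AAAA", "AATT")))
  expect_equal(sum(net3$nodes$inferred), 1L)
  expect_equal(net3$nodes$freq[net3$nodes$inferred], 0)
  expect_equal(nrow(net3$edges), 2L)

  # three steps apart at limit 2: two components
  net4 <- parsimony_network(tibble::tibble(
    label = c("h1", "h2"), seq = c("AAAA", "TTTA")))
  expect_equal(n_components(net4), 2)

  # missing data excluded from the distance: N-masked site does not count
  net5 <- parsimony_network(tibble::tibble(
    label = c("h1", "h2"), seq = c("ANAA", "ATAT")))
  expect_equal(nrow(net5$edges), 1L)  # distance 1 after exclusion

  expect_error(parsimony_network(tibble::tibble(
    label = c("a", "b"), seq = c("AA", "AAA"))), "length")
})

test_that("network edges always join nodes at implied distance one", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    seqs <- vapply(seq_len(n), function(j)
      paste(sample(c("A", "T"), 6, replace = TRUE), collapse = ""), "")
    haps <- tibble::tibble(label = paste0("h", seq_len(n)), seq = seqs)
    haps <- haps[!duplicated(haps$seq), ]
    net <- parsimony_network(haps, limit = 2L)
    # components are internally connected with >= size-1 edges
    for (comp in unique(net$nodes$component)) {
      ids <- net$nodes$id[net$nodes$component == comp]
      sub <- igraph::induced_subgraph(net$graph, ids)
      expect_true(igraph::is_connected(sub))
    }
  }
})

test_that("two mutation clusters far apart split the network and the tree", {
  set.seed(45)
  base <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                collapse = "")
  mutate_at <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    for (a in at) v[a] <- setdiff(c("A", "C", "G", "T"), v[a])[1]
    paste(v, collapse = "")
  }
  haps <- tibble::tibble(
    label = c("a1", "a2", "b1", "b2"),
    seq = c(base, mutate_at(base, 1),
            mutate_at(base, 10:15), mutate_at(base, c(10:15, 20))),
    freq = c(10, 5, 8, 2)
  )
  net <- parsimony_network(haps, limit = 2L)
  expect_gte(n_components(net), 2)
  nodes_p <- tempfile(fileext = ".tsv"); edges_p <- tempfile(fileext = ".tsv")
  write_network(net, nodes_p, edges_p)
  expect_true(file.exists(nodes_p) && file.exists(edges_p))
  # the alignment of the same haplotypes gives a maximally supported split
  a <- region_alignment(setNames(haps$seq, haps$label))
  bs <- bootstrap_support(a, reps = 100, seed = 5)
  expect_gte(max(bs$support$support), 0.99)
  # autoplot returns a ggplot without error
  expect_s3_class(autoplot(net), "ggplot")
})
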