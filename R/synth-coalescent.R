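#' Simulate a neutral coalescent alignment under infinite sites
#'
#' Standard single-locus neutral coalescent (Hudson's algorithm): with `k`
#' active lineages the waiting time to the next coalescence is exponential
#' with rate `k(k-1)/2` (time in units of 2N generations) and a uniformly
#' chosen pair merges. Mutations are Poisson with mean `theta/2` times the
#' total branch length, placed on branches proportionally to length, each at
#' a distinct uniformly drawn site (infinite sites: no recurrent mutation,
#' so the number of segregating sites equals the number of mutations).
#' Under this model `E[S] = theta * a1` with `a1 = sum(1/i, i < n)`.
#'
#' @param n_samples Number of sequences (>= 2).
#' @param theta Population mutation parameter per region (`4*N*mu*L`).
#' @param region_len Number of sites available for mutations.
#' @param seed Integer seed; fixed seed gives an identical alignment.
#' @return A [region_alignment()] with rows `s1..sn`.
#' @export
simulate_neutral_alignment <- function(n_samples, theta, region_len = 1000L,
                                       seed = 1L) {
  if (n_samples < 2L) abort("n_samples must be >= 2")
  if (theta <= 0) abort("theta must be > 0")
  set.seed(seed)
  gen <- coalescent_branches(n_samples)
  total_len <- sum(gen$length)
  n_mut <- rpois(1L, theta / 2 * total_len)
  n_mut <- min(n_mut, region_len)  # infinite sites at finite width: cap
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, region_len, replace = TRUE)
  mat <- matrix(rep(anc, each = n_samples), nrow = n_samples)
  rownames(mat) <- paste0("s", seq_len(n_samples))
  if (n_mut > 0L) {
    sites <- sample.int(region_len, n_mut)  # without replacement: no collision
    branch <- sample.int(length(gen$length), n_mut, replace = TRUE,
                         prob = gen$length)
    for (m in seq_len(n_mut)) {
      carriers <- gen$leaves[[branch[m]]]
      derived <- sample(setdiff(bases, anc[sites[m]]), 1L)
      mat[carriers, sites[m]] <- derived
    }
  }
  region_alignment(mat, labels = rownames(mat))
}

# branches of a coalescent genealogy: leaf sets and lengths
coalescent_branches <- function(n) {
  active <- as.list(seq_len(n))        # leaf sets of active lineages
  birth <- rep(0, n)                   # time each active lineage started
  t <- 0
  leaves <- list(); lens <- numeric(0)
  k <- n
  while (k > 1L) {
    t <- t + rexp(1L, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    for (p in pair) {
      leaves[[length(leaves) + 1L]] <- active[[p]]
      lens <- c(lens, t - birth[p])
    }
    merged <- sort(c(active[[pair[1]]], active[[pair[2]]]))
    active[pair] <- NULL
    birth <- birth[-pair]
    active[[length(active) + 1L]] <- merged
    birth <- c(birth, t)
    k <- k - 1L
  }
  list(leaves = leaves, length = lens)
}
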