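#' Remove alignment columns with gaps or missing data
#'
#' Diversity statistics are computed after removing every column containing
#' a gap (`-`) or missing base (`N`) in *any* row, mirroring the "complete
#' deletion" treatment of the published analysis.
#'
#' @param a A [region_alignment()].
#' @return A [region_alignment()] with only clean columns.
#' @export
clean_alignment <- function(a) {
  if (nrow(a$mat) == 0L) abort("empty alignment")
  ok <- apply(a$mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(ok)) abort("no analyzable sites: all columns contain gaps or N")
  region_alignment(a$mat[, ok, drop = FALSE], labels = a$labels,
                   positions = a$positions[ok])
}

#' Diversity statistics of an alignment
#'
#' Computes, over a cleaned alignment of `n` sequences and `L` sites:
#' the number of segregating sites `S` (columns with at least two alleles);
#' the total number of mutations `eta` (sum over columns of alleles minus
#' one, so a tri-allelic column adds one to `S` but two to `eta`); the mean
#' number of pairwise differences `k` (per sequence, over all `C(n,2)`
#' pairs); the nucleotide diversity `pi = k / L`; `theta_seq = eta / a1`
#' (theta per sequence from eta, with `a1 = sum(1/i, i < n)`); and
#' Watterson's per-site estimator `theta_w_site = theta_seq / L`.
#'
#' @param a A cleaned [region_alignment()] (see [clean_alignment()]).
#' @return A one-row tibble: `n`, `L`, `S`, `eta`, `k`, `pi`, `theta_seq`,
#'   `theta_w_site`.
#' @export
diversity_stats <- function(a) {
  m <- a$mat
  n <- nrow(m); L <- ncol(m)
  if (n < 2L) abort("need at least 2 sequences")
  npairs <- n * (n - 1) / 2
  S <- 0L; eta <- 0L; diff_sum <- 0
  for (j in seq_len(L)) {
    tab <- tabulate(match(m[, j], c("A", "C", "G", "T")), 4L)
    n_alleles <- sum(tab > 0L)
    if (n_alleles > 1L) {
      S <- S + 1L
      eta <- eta + (n_alleles - 1L)
      diff_sum <- diff_sum + (npairs - sum(tab * (tab - 1) / 2))
    }
  }
  a1 <- sum(1 / seq_len(n - 1))
  k <- diff_sum / npairs
  tibble(
    n = n, L = L, S = S, eta = eta, k = k, pi = k / L,
    theta_seq = eta / a1, theta_w_site = eta / a1 / L
  )
}

#' Tajima's standardization constants
#'
#' The `a1..e2` constants of the D statistic as functions of the sample
#' size `n` (Tajima 1989).
#'
#' @param n Sample size (>= 2).
#' @return A named list `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 2L) abort("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D neutrality statistic
#'
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))`: the standardized discrepancy
#' between the pairwise-difference estimator and the segregating-sites
#' estimator of theta. Negative values indicate an excess of rare variants
#' (selection or expansion). Following the common DnaSP accounting, the
#' numerator and variance use `S`; the reported theta estimators elsewhere
#' use `eta` (the two coincide on infinite-sites data, where `S == eta`).
#' With `S = 0` the statistic is undefined and reported as `NA`.
#'
#' @param stats One-row tibble from [diversity_stats()] (or any list with
#'   `S`, `k`, `n`).
#' @param n Sample size; defaults to `stats$n`.
#' @return A one-row tibble `D`, `p_value`, `sig`.
#' @export
tajimas_D <- function(stats, n = stats$n) {
  S <- stats$S; k <- stats$k
  if (S == 0L) {
    return(tibble(D = NA_real_, p_value = NA_real_, sig = NA_character_))
  }
  cst <- tajima_constants(n)
  D <- (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  if (n < 4L) {
    return(tibble(D = D, p_value = NA_real_, sig = NA_character_))
  }
  sig <- significance_of_D(D, n)
  tibble(D = D, p_value = sig$p_value, sig = sig$sig)
}

#' Significance class of a Tajima's D value
#'
#' Two-tailed classification using the beta-distribution approximation of
#' the null: D is rescaled onto its analytic support `[Dmin, Dmax]` for the
#' given `n`, a beta density with mean 0 and variance 1 on that support
#' supplies the tail mass, and the class is assigned at the 0.05 / 0.01 /
#' 0.001 levels (the starred convention of DnaSP output). Values outside
#' the support are clamped with a warning.
#'
#' @param D Tajima's D value.
#' @param n Sample size (>= 4 for a meaningful classification).
#' @return A one-row tibble `p_value`, `sig` with `sig` one of `"ns"`,
#'   `"p<0.05"`, `"p<0.01"`, `"p<0.001"`.
#' @export
significance_of_D <- function(D, n) {
  if (n < 4L) abort("significance classification needs n >= 4")
  cst <- tajima_constants(n)
  Dmin <- (2 / n - 1 / cst$a1) / sqrt(cst$e2)
  Dmax <- if (n %% 2 == 0) {
    (n / (2 * (n - 1)) - 1 / cst$a1) / sqrt(cst$e2)
  } else {
    ((n + 1) / (2 * n) - 1 / cst$a1) / sqrt(cst$e2)
  }
  if (D < Dmin || D > Dmax) {
    warn(sprintf("D = %.4f outside analytic bounds [%.4f, %.4f]; clamped",
                 D, Dmin, Dmax))
    D <- min(max(D, Dmin), Dmax)
  }
  alpha <- -(1 + Dmin * Dmax) * Dmax / (Dmax - Dmin)
  beta <- (1 + Dmin * Dmax) * Dmin / (Dmax - Dmin)
  x <- (D - Dmin) / (Dmax - Dmin)
  cdf <- pbeta(x, beta, alpha)
  p <- 2 * min(cdf, 1 - cdf)
  sig <- if (p < 0.001) "p<0.001"
    else if (p < 0.01) "p<0.01"
    else if (p < 0.05) "p<0.05"
    else "ns"
  tibble(p_value = p, sig = sig)
}

#' Windowed diversity statistics per accession group
#'
#' For each declared group: subset the alignment to the group's rows and
#' the requested window, remove gapped/missing columns, and compute the
#' diversity statistics and Tajima's D with its significance class. Groups
#' of fewer than two accessions are skipped with a warning.
#'
#' @param a A [region_alignment()] whose `positions` are reference
#'   coordinates.
#' @param groups Tibble `label`, `group` assigning accessions to groups
#'   (default: all accessions, one group).
#' @param window Length-2 reference window (default: full alignment).
#' @return A tibble with one row per group: the group name, `n`, `L`, `S`,
#'   `eta`, `k`, `pi`, `theta_w` (per site), `D`, `sig`.
#' @export
region_stats <- function(a, groups = NULL, window = NULL) {
  if (is.null(groups)) {
    groups <- tibble(label = a$labels, group = "all")
  }
  if (!is.null(window)) {
    if (window[1] < min(a$positions, na.rm = TRUE) ||
        window[2] > max(a$positions, na.rm = TRUE)) {
      abort("window outside alignment coordinates")
    }
  }
  out <- list()
  for (g in unique(groups$group)) {
    labs <- groups$label[groups$group == g]
    if (length(labs) < 2L) {
      warn(sprintf("group '%s' has fewer than 2 accessions; skipped", g))
      next
    }
    sub <- subset_alignment(a, labels = labs, window = window)
    cleaned <- clean_alignment(sub)
    st <- diversity_stats(cleaned)
    d <- tajimas_D(st)
    out[[length(out) + 1L]] <- dplyr::bind_cols(
      tibble(group = g), st,
      tibble(theta_w = st$theta_w_site, D = d$D, sig = d$sig)
    )
  }
  dplyr::bind_rows(out)
}

#' Write a diversity table as TSV
#'
#' @param stats Output of [region_stats()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diversity_tsv <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}
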