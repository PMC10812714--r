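#' @name differentiation
#' @title Pairwise population differentiation
#'
#' @description
#' Per-site Weir-Cockerham (1984) variance components and theta for a pair
#' of populations, genome-wide ratio-of-sums F_ST, and Reynolds' coancestry
#' distance D = -ln(1 - theta_R) from the sample-size-corrected
#' allele-frequency estimator. Negative per-site estimates are retained (not
#' clamped) so that sums and window means stay unbiased.
NULL

# Weir-Cockerham variance components for two populations at each locus.
# Inputs are per-locus vectors: sample sizes (diploid calls), alt-allele
# frequencies, and heterozygote frequencies in each population.
wc_components_vec <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  usable <- n1 >= 2L & n2 >= 2L
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!usable] <- NA_real_
  b[!usable] <- NA_real_
  cc[!usable] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom > 0, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, theta = theta)
}

# Per-population per-locus summaries needed by the estimators.
pop_site_stats <- function(genotypes, idx) {
  sub <- genotypes[, idx, drop = FALSE]
  n <- rowSums(!is.na(sub))
  p <- rowSums(sub, na.rm = TRUE) / (2 * n)
  h <- rowSums(sub == 1L, na.rm = TRUE) / n
  list(n = n, p = p, h = h)
}

#' Weir-Cockerham components at a single locus from genotype counts
#'
#' @param counts_a,counts_b Length-3 vectors `c(n_AA, n_Aa, n_aa)` of
#'   genotype counts (dosage 0, 1, 2) for the two populations.
#' @return A list with components `a` (among-population), `b`
#'   (among-individual-within-population), `c` (within-individual) and
#'   `theta = a/(a+b+c)` (`NA` when the locus is monomorphic across both
#'   populations or a population has fewer than two calls).
#' @examples
#' wc_fst_site(c(3, 1, 1), c(0, 2, 3))
#' @export
wc_fst_site <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 3L, length(counts_b) == 3L,
            all(counts_a >= 0), all(counts_b >= 0))
  n1 <- sum(counts_a); n2 <- sum(counts_b)
  if (n1 < 2L || n2 < 2L)
    stop("each population needs >= 2 non-missing diploid calls")
  p1 <- (counts_a[2] + 2 * counts_a[3]) / (2 * n1)
  p2 <- (counts_b[2] + 2 * counts_b[3]) / (2 * n2)
  comp <- wc_components_vec(n1, p1, counts_a[2] / n1,
                            n2, p2, counts_b[2] / n2)
  list(a = comp$a, b = comp$b, c = comp$c, theta = comp$theta)
}

#' Per-site Weir-Cockerham components for two populations
#'
#' @param genotypes Dosage matrix.
#' @param popmap Population map.
#' @param pop_a,pop_b Population labels; each may be a vector of labels, in
#'   which case the named populations are pooled into one group.
#' @param loci Optional integer subset of locus rows.
#' @return data.frame with per-locus columns `a`, `b`, `c`, `theta`.
#' @export
site_fst <- function(genotypes, popmap, pop_a, pop_b, loci = NULL) {
  ia <- pop_indices(genotypes, popmap, pop_a)
  ib <- pop_indices(genotypes, popmap, pop_b)
  if (!is.null(loci)) genotypes <- genotypes[loci, , drop = FALSE]
  sa <- pop_site_stats(genotypes, ia)
  sb <- pop_site_stats(genotypes, ib)
  wc_components_vec(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
}

#' Genome-wide Weir-Cockerham F_ST (ratio of sums)
#'
#' `theta = sum(a) / sum(a + b + c)` over usable loci (both populations
#' with at least two calls and a positive pooled denominator contribution;
#' monomorphic loci contribute zero to both sums). Negative estimates are
#' clamped to 0; the raw value is kept in attribute `"raw"`.
#'
#' @inheritParams site_fst
#' @return Clamped theta (numeric scalar) with attribute `raw`.
#' @export
global_fst <- function(genotypes, popmap, pop_a, pop_b, loci = NULL) {
  comp <- site_fst(genotypes, popmap, pop_a, pop_b, loci)
  use <- !is.na(comp$a)
  denom <- sum(comp$a[use] + comp$b[use] + comp$c[use])
  if (!any(use) || denom <= 0) stop("no usable polymorphic loci")
  raw <- sum(comp$a[use]) / denom
  out <- max(0, raw)
  attr(out, "raw") <- raw
  out
}

#' Reynolds' genetic distance
#'
#' Coancestry theta_R from allele frequencies with finite-sample
#' correction, accumulated as a ratio of sums over loci, then
#' `D = -ln(1 - theta_R)`. Negative theta_R is truncated to 0 before the
#' log; theta_R = 1 (complete fixed differences) yields `Inf` with a
#' warning.
#'
#' Per locus, the squared frequency difference is debiased by the binomial
#' sampling variance of each frequency (`p*q/(2n - 1)`), and the
#' denominator adds the unbiased within-population gene diversities, so
#' that the ratio estimates the drift-model coancestry.
#'
#' @inheritParams site_fst
#' @return Distance D (numeric scalar) with attribute `theta_r`.
#' @export
reynolds_distance <- function(genotypes, popmap, pop_a, pop_b, loci = NULL) {
  ia <- pop_indices(genotypes, popmap, pop_a)
  ib <- pop_indices(genotypes, popmap, pop_b)
  if (!is.null(loci)) genotypes <- genotypes[loci, , drop = FALSE]
  sa <- pop_site_stats(genotypes, ia)
  sb <- pop_site_stats(genotypes, ib)
  use <- sa$n >= 2L & sb$n >= 2L
  if (!any(use)) stop("no usable loci")
  p1 <- sa$p[use]; n1 <- sa$n[use]
  p2 <- sb$p[use]; n2 <- sb$n[use]
  # unbiased estimate of sum over alleles of (p1 - p2)^2
  a_hat <- 2 * ((p1 - p2)^2 -
                p1 * (1 - p1) / (2 * n1 - 1) -
                p2 * (1 - p2) / (2 * n2 - 1))
  h1 <- unbiased_gene_diversity(p1, n1)
  h2 <- unbiased_gene_diversity(p2, n2)
  denom <- sum(a_hat + h1 + h2)
  if (denom <= 0) stop("degenerate data: no variation in either population")
  theta_r <- sum(a_hat) / denom
  theta_r <- min(1, max(0, theta_r))
  if (theta_r >= 1) {
    warning("theta_R = 1 (complete fixed differences): distance is infinite")
    d <- Inf
  } else {
    d <- -log(1 - theta_r)
  }
  attr(d, "theta_r") <- theta_r
  d
}

#' Pairwise differentiation matrix
#'
#' Square matrix in population-map order with global Weir-Cockerham F_ST
#' below the diagonal and Reynolds' distance above; the diagonal is `NA`.
#'
#' @param genotypes Dosage matrix.
#' @param popmap Population map with at least two populations.
#' @return Numeric matrix with population labels as dimnames.
#' @export
pairwise_matrix <- function(genotypes, popmap) {
  pops <- levels(popmap$population)
  k <- length(pops)
  if (k < 2L) stop("need >= 2 populations")
  m <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      m[j, i] <- as.numeric(global_fst(genotypes, popmap, pops[i], pops[j]))
      m[i, j] <- as.numeric(
        reynolds_distance(genotypes, popmap, pops[i], pops[j]))
    }
  }
  m
}
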