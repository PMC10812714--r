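#' @name diversity
#' @title Per-population diversity statistics
#'
#' @description
#' Summaries of within-population variation computed from an allele-dosage
#' matrix: number of variant loci, proportion of polymorphic loci (P_N),
#' observed and expected heterozygosity (H_O, H_E, the latter with the
#' small-sample 2n/(2n-1) correction), mean minor allele frequency, and the
#' method-of-moments inbreeding coefficient F_IS. All statistics use the
#' full filtered locus set as the denominator so values are directly
#' comparable across populations.
NULL

# Per-locus alt-allele frequency and call count within a sample subset.
pop_freq <- function(genotypes, idx) {
  sub <- genotypes[, idx, drop = FALSE]
  n <- rowSums(!is.na(sub))
  p <- rowSums(sub, na.rm = TRUE) / (2 * n)
  list(p = p, n = n)  # p is NaN where n == 0
}

#' Number of variant loci within a population
#'
#' Counts loci carrying at least one non-reference allele among the
#' population's non-missing calls.
#'
#' @param genotypes Dosage matrix (loci x samples).
#' @param popmap Population map from [read_popmap()].
#' @param pop Population label.
#' @return Integer count.
#' @export
pop_variant_count <- function(genotypes, popmap, pop) {
  idx <- pop_indices(genotypes, popmap, pop)
  sum(rowSums(genotypes[, idx, drop = FALSE], na.rm = TRUE) > 0L)
}

#' Proportion of polymorphic loci (P_N)
#'
#' Fraction of the locus set at which both alleles are observed within the
#' population.
#'
#' @inheritParams pop_variant_count
#' @return Fraction in [0, 1].
#' @export
prop_polymorphic <- function(genotypes, popmap, pop) {
  if (nrow(genotypes) == 0L) stop("no loci")
  idx <- pop_indices(genotypes, popmap, pop)
  f <- pop_freq(genotypes, idx)
  mean(!is.nan(f$p) & f$p > 0 & f$p < 1)
}

#' Observed heterozygosity (H_O)
#'
#' Mean over loci of the fraction of heterozygous calls among non-missing
#' calls in the population; loci with no data in the population are
#' excluded.
#'
#' @inheritParams pop_variant_count
#' @return Fraction in [0, 1].
#' @export
observed_het <- function(genotypes, popmap, pop) {
  idx <- pop_indices(genotypes, popmap, pop)
  sub <- genotypes[, idx, drop = FALSE]
  n <- rowSums(!is.na(sub))
  if (!any(n > 0L)) stop("no non-missing calls for population ", pop)
  het <- rowSums(sub == 1L, na.rm = TRUE)
  mean((het / n)[n > 0L])
}

#' Expected heterozygosity (H_E)
#'
#' Mean over loci of the unbiased per-locus gene diversity
#' `2*p*q * 2n/(2n - 1)`, where `n` is the number of non-missing diploid
#' calls at the locus within the population. Loci fixed within the
#' population contribute 0.
#'
#' @inheritParams pop_variant_count
#' @return Fraction in [0, 1].
#' @export
expected_het <- function(genotypes, popmap, pop) {
  idx <- pop_indices(genotypes, popmap, pop)
  f <- pop_freq(genotypes, idx)
  use <- f$n > 0L
  if (!any(use)) stop("no non-missing calls for population ", pop)
  h <- unbiased_gene_diversity(f$p[use], f$n[use])
  mean(h)
}

# 2pq with the 2n/(2n-1) finite-sample correction; n diploid calls.
unbiased_gene_diversity <- function(p, n) {
  h <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  h[n < 1L] <- NA_real_
  h
}

#' Mean within-population minor allele frequency
#'
#' Averages `min(p, 1 - p)` within the population over loci that segregate
#' in the pooled sample (all populations together).
#'
#' @inheritParams pop_variant_count
#' @return Mean MAF in [0, 0.5].
#' @export
mean_maf <- function(genotypes, popmap, pop) {
  idx <- pop_indices(genotypes, popmap, pop)
  all_f <- pop_freq(genotypes, seq_len(ncol(genotypes)))
  seg <- !is.nan(all_f$p) & all_f$p > 0 & all_f$p < 1
  if (!any(seg)) stop("no segregating loci in the pooled sample")
  f <- pop_freq(genotypes, idx)
  use <- seg & f$n > 0L
  maf <- pmin(f$p[use], 1 - f$p[use])
  mean(maf)
}

#' Inbreeding coefficient F_IS
#'
#' Method-of-moments estimate per individual,
#' `F_i = (O_hom_i - E_hom_i) / (L_i - E_hom_i)`, where `O_hom_i` is the
#' individual's observed count of homozygous calls, `L_i` its number of
#' non-missing calls, and `E_hom_i` the expected homozygote count summed
#' over those loci as `1 - 2pq * 2n/(2n - 1)` with population allele
#' frequencies. The population F_IS is the mean of the per-individual
#' values; degenerate individuals (`L_i == E_hom_i`) are excluded with a
#' warning.
#'
#' @inheritParams pop_variant_count
#' @return A list with `f_individual` (named numeric vector) and `fis`
#'   (population mean).
#' @export
fis <- function(genotypes, popmap, pop) {
  idx <- pop_indices(genotypes, popmap, pop)
  if (length(idx) < 2L) stop("F_IS needs >= 2 samples in population ", pop)
  sub <- genotypes[, idx, drop = FALSE]
  f <- pop_freq(genotypes, idx)
  h_exp <- unbiased_gene_diversity(f$p, f$n)  # NA where no calls
  called <- !is.na(sub)
  f_ind <- vapply(seq_len(ncol(sub)), function(i) {
    loci <- which(called[, i] & !is.na(h_exp))
    L_i <- length(loci)
    if (L_i == 0L) return(NA_real_)
    o_hom <- sum(sub[loci, i] != 1L)
    e_hom <- sum(1 - h_exp[loci])
    denom <- L_i - e_hom
    if (abs(denom) < .Machine$double.eps * L_i) return(NA_real_)
    (o_hom - e_hom) / denom
  }, numeric(1))
  names(f_ind) <- colnames(sub)
  if (anyNA(f_ind))
    warning("excluded degenerate individuals: ",
            paste(names(f_ind)[is.na(f_ind)], collapse = ", "))
  list(f_individual = f_ind, fis = mean(f_ind, na.rm = TRUE))
}

#' Per-population diversity summary table
#'
#' One row per population: sample size, variant count, P_N, H_O, H_E,
#' mean MAF and F_IS.
#'
#' @param genotypes Dosage matrix.
#' @param popmap Population map.
#' @return data.frame with columns `population`, `n_samples`, `n_variants`,
#'   `pn`, `ho`, `he`, `mean_maf`, `fis`.
#' @export
diversity_summary <- function(genotypes, popmap) {
  pops <- levels(popmap$population)
  rows <- lapply(pops, function(pp) {
    idx <- pop_indices(genotypes, popmap, pp)
    data.frame(population = pp,
               n_samples = length(idx),
               n_variants = pop_variant_count(genotypes, popmap, pp),
               pn = prop_polymorphic(genotypes, popmap, pp),
               ho = observed_het(genotypes, popmap, pp),
               he = expected_het(genotypes, popmap, pp),
               mean_maf = mean_maf(genotypes, popmap, pp),
               fis = fis(genotypes, popmap, pp)$fis,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-contig variant counts
#'
#' @param variants Variant table.
#' @param contig_lengths Optional named vector of contig lengths; when
#'   absent, the maximum observed position per contig is reported.
#' @return data.frame with `chrom`, `n_snps`, `length`.
#' @export
per_chromosome_counts <- function(variants, contig_lengths = NULL) {
  if (nrow(variants) == 0L)
    return(data.frame(chrom = character(0), n_snps = integer(0),
                      length = numeric(0), stringsAsFactors = FALSE))
  tab <- table(variants$chrom)
  chroms <- names(tab)
  len <- if (is.null(contig_lengths)) {
    vapply(chroms, function(ch) max(variants$pos[variants$chrom == ch]),
           numeric(1))
  } else {
    as.numeric(contig_lengths[chroms])
  }
  data.frame(chrom = chroms, n_snps = as.integer(tab),
             length = unname(len), stringsAsFactors = FALSE, row.names = NULL)
}
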