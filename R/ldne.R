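#' @name ld_ne
#' @title LD decay and effective population size
#'
#' @description
#' Pairwise squared dosage correlation (composite r-squared, appropriate
#' for unphased genotypes) within a population, binned by inter-locus
#' distance, and an effective-population-size trajectory from the drift
#' expectation `E(r^2) = 1/(1 + 4*Ne*c)`, mapping each distance bin to
#' `t = 1/(2c)` generations ago.
NULL

#' Pairwise r-squared between nearby loci
#'
#' Squared Pearson correlation of allele dosages over samples non-missing
#' at both loci, for same-contig pairs up to `max_distance` apart. Pairs
#' with an undefined correlation (a monomorphic member) are skipped.
#'
#' @param genotypes Dosage matrix.
#' @param variants Variant table aligned with `genotypes`.
#' @param popmap,pop Optional population restriction; default uses all
#'   samples.
#' @param max_distance Maximum inter-locus distance in bp.
#' @param max_pairs_per_locus Cap on partners per focal locus; when the
#'   candidate set is larger a simple random subsample is taken (seed the
#'   RNG for reproducibility).
#' @param min_sep_snps Optional minimum pair separation, in loci.
#' @return data.frame with `i`, `j` (locus row indices), `distance` (bp)
#'   and `r2`.
#' @export
pair_r2 <- function(genotypes, variants, popmap = NULL, pop = NULL,
                    max_distance = 1e6, max_pairs_per_locus = Inf,
                    min_sep_snps = 1) {
  if (!is.null(pop)) {
    idx <- pop_indices(genotypes, popmap, pop)
    genotypes <- genotypes[, idx, drop = FALSE]
  }
  if (ncol(genotypes) < 4L)
    stop("need >= 4 samples for meaningful r-squared")
  min_sep_snps <- max(1L, as.integer(min_sep_snps))
  res_i <- list(); res_j <- list(); n_out <- 0L
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    vi <- vi[order(variants$pos[vi])]
    pos <- variants$pos[vi]
    L <- length(vi)
    for (a in seq_len(L)) {
      b0 <- a + min_sep_snps
      if (b0 > L) next
      bmax <- findInterval(pos[a] + max_distance, pos)
      if (bmax < b0) next
      bs <- b0:bmax
      if (length(bs) > max_pairs_per_locus)
        bs <- sort(sample(bs, max_pairs_per_locus))
      n_out <- n_out + 1L
      res_i[[n_out]] <- rep.int(vi[a], length(bs))
      res_j[[n_out]] <- vi[bs]
    }
  }
  if (n_out == 0L)
    return(data.frame(i = integer(0), j = integer(0),
                      distance = numeric(0), r2 = numeric(0)))
  i <- unlist(res_i); j <- unlist(res_j)
  r2 <- vapply(seq_along(i), function(k) {
    r <- suppressWarnings(stats::cor(genotypes[i[k], ], genotypes[j[k], ],
                                     use = "pairwise.complete.obs"))
    if (is.na(r)) NA_real_ else r * r
  }, numeric(1))
  ok <- !is.na(r2)
  data.frame(i = i[ok], j = j[ok],
             distance = abs(variants$pos[j[ok]] - variants$pos[i[ok]]),
             r2 = r2[ok])
}

#' Bin pairwise r-squared by distance
#'
#' @param pairs data.frame from [pair_r2()].
#' @param bin_width Bin width in bp.
#' @param max_distance Upper end of the binned range.
#' @return data.frame with `bin_start`, `bin_end`, `mid`, `n_pairs`,
#'   `mean_r2` (`NA` for empty bins). Bins tile `[0, max_distance)`
#'   contiguously.
#' @export
bin_decay <- function(pairs, bin_width = 20000, max_distance = 1e6) {
  if (nrow(pairs) == 0L) stop("no pairs to bin")
  starts <- seq.int(0, max_distance - bin_width, by = bin_width)
  bin <- findInterval(pairs$distance, c(starts, max_distance),
                      rightmost.closed = FALSE)
  inside <- bin >= 1L & pairs$distance < max_distance
  n_pairs <- tabulate(bin[inside], nbins = length(starts))
  sums <- rep(0, length(starts))
  agg <- tapply(pairs$r2[inside], bin[inside], sum)
  sums[as.integer(names(agg))] <- agg
  mean_r2 <- ifelse(n_pairs > 0, sums / n_pairs, NA_real_)
  data.frame(bin_start = starts, bin_end = starts + bin_width,
             mid = starts + bin_width / 2,
             n_pairs = n_pairs, mean_r2 = mean_r2)
}

#' Effective population size from binned LD
#'
#' Inverts `E(r^2) = 1/(1 + 4*Ne*c)` per distance bin: the bin midpoint is
#' converted to a recombination fraction `c` (Morgans) via `cM_per_Mb`,
#' the mean r-squared is optionally adjusted for finite sample size
#' (`r2 - 1/(2n)`), and `Ne = (1/r2_adj - alpha) / (4c)` with
#' `t = 1/(2c)` generations ago. Bins whose adjusted r-squared or Ne is
#' non-positive are flagged undefined.
#'
#' @param bins data.frame from [bin_decay()].
#' @param n_samples Number of diploid samples used to compute r-squared.
#' @param alpha Mutation adjustment in the inversion (1 by default; 2.2 is
#'   the common alternative).
#' @param sample_size_correction Subtract `1/(2*n_samples)` from mean
#'   r-squared before inverting.
#' @param cM_per_Mb Genetic-map scaling (1 cM/Mb by default).
#' @return data.frame with `mid`, `c_morgans`, `t` (generations ago),
#'   `ne`, and logical `defined`; undefined points carry `NA` Ne.
#' @export
estimate_ne <- function(bins, n_samples, alpha = 1,
                        sample_size_correction = TRUE, cM_per_Mb = 1) {
  use <- bins$n_pairs > 0 & !is.na(bins$mean_r2)
  b <- bins[use, , drop = FALSE]
  c_m <- b$mid * cM_per_Mb / 100 / 1e6  # bp -> cM -> Morgans
  r2 <- b$mean_r2
  if (isTRUE(sample_size_correction)) r2 <- r2 - 1 / (2 * n_samples)
  ne <- rep(NA_real_, nrow(b))
  ok <- r2 > 0
  ne[ok] <- (1 / r2[ok] - alpha) / (4 * c_m[ok])
  ok <- ok & !is.na(ne) & ne > 0
  ne[!ok] <- NA_real_
  data.frame(mid = b$mid, c_morgans = c_m, t = 1 / (2 * c_m),
             ne = ne, defined = ok)
}
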