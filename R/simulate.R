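#' Simulation configuration
#'
#' Parameters of the Balding-Nichols genotype simulator. The defaults
#' emulate a two-group contrast shaped like a small multi-population
#' resequencing study: a 12-diploid test population against a 33-diploid
#' pooled control group, both drifted (F = 0.05) from a common ancestor,
#' 50,000 biallelic SNPs at uniform random positions on a 10 Mb contig,
#' 2 percent missing calls, and five planted 200-kb sweeps at strength
#' 0.95 in the test population.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param contigs Named numeric vector of contig lengths in bp.
#' @param n_snps Total SNP count, allocated to contigs by length.
#' @param populations data.frame with `label`, `n` (diploid individuals,
#'   >= 2), `drift_f` (Balding-Nichols F in `[0, 1)`), `inbreeding_f`
#'   (within-population IBD probability in `[0, 1)`).
#' @param test_population Label of the population receiving sweeps.
#' @param sweeps data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `strength` in (0, 1]; the test population's allele
#'   frequency inside each interval is overridden to
#'   `1 - (1 - strength) * u`, `u ~ U(0,1)`, i.e. near fixation.
#' @param missing_rate I.i.d. missing-call probability.
#' @param maf_floor Ancestral frequencies are drawn uniformly on
#'   `[maf_floor, 1 - maf_floor]`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       contigs = c(chr1 = 1e7),
                       n_snps = 50000,
                       populations = data.frame(
                         label = c("BG", "CTRL"),
                         n = c(12L, 33L),
                         drift_f = c(0.05, 0.05),
                         inbreeding_f = c(0, 0),
                         stringsAsFactors = FALSE),
                       test_population = "BG",
                       sweeps = data.frame(
                         chrom = "chr1",
                         start = c(1.0e6, 2.8e6, 4.6e6, 6.4e6, 8.2e6),
                         end = c(1.2e6, 3.0e6, 4.8e6, 6.6e6, 8.4e6),
                         strength = 0.95,
                         stringsAsFactors = FALSE),
                       missing_rate = 0.02,
                       maf_floor = 0.05) {
  if (is.list(contigs)) contigs <- unlist(contigs)
  if (!is.null(sweeps)) sweeps <- as.data.frame(sweeps)
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be a named vector of lengths")
  contigs <- stats::setNames(as.numeric(contigs), names(contigs))
  if (any(populations$n < 2L)) stop("population sizes must be >= 2")
  if (any(populations$drift_f < 0 | populations$drift_f >= 1))
    stop("drift_f must be in [0, 1)")
  if (any(populations$inbreeding_f < 0 | populations$inbreeding_f >= 1))
    stop("inbreeding_f must be in [0, 1)")
  if (!test_population %in% populations$label)
    stop("test_population absent from populations")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (maf_floor < 0 || maf_floor >= 0.5)
    stop("maf_floor must be in [0, 0.5)")
  if (!is.null(sweeps) && nrow(sweeps)) {
    if (any(!sweeps$chrom %in% names(contigs)))
      stop("sweep contig not in contigs")
    if (any(sweeps$start < 0 | sweeps$end <= sweeps$start |
            sweeps$end > contigs[sweeps$chrom]))
      stop("sweep intervals must lie within contig bounds")
    if (any(sweeps$strength <= 0 | sweeps$strength > 1))
      stop("sweep strength must be in (0, 1]")
  }
  structure(list(seed = as.integer(seed), contigs = contigs,
                 n_snps = as.integer(n_snps), populations = populations,
                 test_population = test_population, sweeps = sweeps,
                 missing_rate = missing_rate, maf_floor = maf_floor),
            class = "sim_config")
}

#' Simulate a two-or-more-population SNP dataset with planted sweeps
#'
#' Balding-Nichols model: per locus, an ancestral frequency `p` is drawn
#' uniformly on `[maf_floor, 1 - maf_floor]`; each population's frequency
#' is `Beta(p(1-F)/F, (1-p)(1-F)/F)` (equal to `p` when F = 0), so F is
#' the planted, recoverable F_ST between populations. Within the test
#' population, loci inside sweep intervals have their frequency overridden
#' to near fixation, producing the elevated differentiation and depleted
#' diversity a sweep scan looks for. Genotypes are two Bernoulli allele
#' draws per individual, duplicated with probability `inbreeding_f`
#' (identity by descent); missingness is i.i.d. All draws flow from one
#' Mersenne-Twister stream seeded by `config$seed`, in documented order
#' (positions, alleles, ancestral then population frequencies, sweep
#' overrides, genotypes by population, missingness), so outputs are
#' byte-identical for a fixed config.
#'
#' @param config A [sim_config()] object.
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.vcf`, `<prefix>.popmap.tsv` and `<prefix>.sweeps.bed`.
#' @return List with `variants`, `genotypes`, `popmap`, `truth` (a list:
#'   `sweeps`, `populations`, `p_ancestral`, `p_pop` matrix), `config`,
#'   and `paths` when files were written.
#' @export
simulate_dataset <- function(config = sim_config(), out_prefix = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed, kind = "Mersenne-Twister")

  # SNP positions, allocated to contigs proportionally to length
  lens <- config$contigs
  n_k <- floor(config$n_snps * lens / sum(lens))
  rem <- config$n_snps - sum(n_k)
  if (rem > 0) {
    extra <- order(config$n_snps * lens / sum(lens) - n_k,
                   decreasing = TRUE)[seq_len(rem)]
    n_k[extra] <- n_k[extra] + 1L
  }
  variants <- do.call(rbind, lapply(seq_along(lens), function(k) {
    data.frame(chrom = names(lens)[k],
               pos = sort(sample.int(lens[[k]], n_k[k])),
               stringsAsFactors = FALSE)
  }))
  L <- nrow(variants)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  variants$id <- NA_character_
  variants$ref <- ref
  variants$alt <- unname(alt)
  variants <- variants[, c("chrom", "pos", "id", "ref", "alt")]
  rownames(variants) <- NULL

  p_anc <- stats::runif(L, config$maf_floor, 1 - config$maf_floor)

  pops <- config$populations
  p_pop <- matrix(NA_real_, L, nrow(pops),
                  dimnames = list(NULL, pops$label))
  for (k in seq_len(nrow(pops))) {
    f <- pops$drift_f[k]
    p_pop[, k] <- if (f == 0) p_anc else
      stats::rbeta(L, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }

  # sweep override in the test population
  sweeps <- config$sweeps
  if (!is.null(sweeps) && nrow(sweeps)) {
    tcol <- config$test_population
    for (s in seq_len(nrow(sweeps))) {
      in_sweep <- variants$chrom == sweeps$chrom[s] &
        (variants$pos - 1) >= sweeps$start[s] &
        (variants$pos - 1) < sweeps$end[s]
      u <- stats::runif(sum(in_sweep))
      p_pop[in_sweep, tcol] <- 1 - (1 - sweeps$strength[s]) * u
    }
  }

  # genotypes: per population, two allele draws with IBD duplication
  total_n <- sum(pops$n)
  genotypes <- matrix(NA_integer_, L, total_n)
  sample_ids <- character(total_n)
  col <- 0L
  for (k in seq_len(nrow(pops))) {
    m <- pops$n[k]
    pk <- p_pop[, k]
    ibd <- matrix(stats::runif(L * m) < pops$inbreeding_f[k], L, m)
    d1 <- matrix(stats::runif(L * m) < pk, L, m)
    d2 <- matrix(stats::runif(L * m) < pk, L, m)
    dos <- ifelse(ibd, 2L * d1, d1 + d2)
    genotypes[, col + seq_len(m)] <- dos
    sample_ids[col + seq_len(m)] <-
      sprintf("%s_%02d", pops$label[k], seq_len(m))
    col <- col + m
  }
  if (config$missing_rate > 0)
    genotypes[matrix(stats::runif(L * total_n) < config$missing_rate,
                     L, total_n)] <- NA_integer_
  colnames(genotypes) <- sample_ids

  popmap <- data.frame(
    sample = sample_ids,
    population = factor(rep(pops$label, pops$n), levels = pops$label),
    stringsAsFactors = FALSE)

  truth <- list(sweeps = sweeps, populations = pops,
                p_ancestral = p_anc, p_pop = p_pop)
  out <- list(variants = variants, genotypes = genotypes, popmap = popmap,
              truth = truth, config = config)

  if (!is.null(out_prefix)) {
    paths <- list(vcf = paste0(out_prefix, ".vcf"),
                  popmap = paste0(out_prefix, ".popmap.tsv"),
                  sweeps = paste0(out_prefix, ".sweeps.bed"))
    write_vcf(variants, genotypes, paths$vcf,
              contig_lengths = config$contigs,
              source_line = sprintf(
                "popgenscan simulate seed=%d rng=Mersenne-Twister",
                config$seed))
    write_popmap(popmap, paths$popmap)
    bed <- if (!is.null(sweeps) && nrow(sweeps)) {
      paste(sweeps$chrom, format(sweeps$start, scientific = FALSE,
                                 trim = TRUE),
            format(sweeps$end, scientific = FALSE, trim = TRUE),
            paste0("sweep_strength=", sweeps$strength), sep = "\t")
    } else character(0)
    writeLines(bed, paths$sweeps)
    out$paths <- paths
  }
  out
}

#' Flag windows overlapping planted sweeps
#'
#' Half-open interval overlap: a window touching a sweep boundary only
#' (window end equal to sweep start) does not overlap.
#'
#' @param sweeps data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. `truth$sweeps` from [simulate_dataset()].
#' @param windows data.frame with `chrom`, `start`, `end`.
#' @return Logical vector, one flag per window row.
#' @export
truth_windows <- function(sweeps, windows) {
  if (is.null(sweeps) || nrow(sweeps) == 0L)
    return(rep(FALSE, nrow(windows)))
  vapply(seq_len(nrow(windows)), function(k) {
    any(sweeps$chrom == windows$chrom[k] &
        sweeps$start < windows$end[k] &
        sweeps$end > windows$start[k])
  }, logical(1))
}
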