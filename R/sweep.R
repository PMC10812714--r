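#' @name sweep_scan_module
#' @title Sliding-window selective-sweep scan
#'
#' @description
#' The scan contrasts a test population against a pooled control group in
#' overlapping genomic windows (100 kb sliding by 50 kb by default):
#' per-window mean per-site Weir-Cockerham theta is Z-transformed across
#' the genome, nucleotide diversity (theta-pi) is computed per base pair in
#' each group and combined as `log2(pi_control / pi_test)`, and windows in
#' the top tail of both statistics simultaneously are flagged as joint
#' sweep candidates. Tajima's D per group provides confirmation: sweeps
#' show strongly negative D in the test population.
NULL

#' Build sliding windows over contigs
#'
#' Windows start at 0, `step`, `2*step`, ... and only windows fully
#' contained in the contig are emitted. Coordinates are 0-based half-open.
#'
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param size Window size in bp.
#' @param step Step between successive window starts in bp; must not
#'   exceed `size`.
#' @return data.frame with `chrom`, `start`, `end`.
#' @examples
#' nrow(make_windows(c(chr1 = 1e6)))  # 19
#' @export
make_windows <- function(contig_lengths, size = 100000, step = 50000) {
  if (size <= 0) stop("size must be > 0")
  if (step <= 0) stop("step must be > 0")
  if (step > size) stop("step > size would leave gaps between windows")
  out <- lapply(names(contig_lengths), function(ch) {
    L <- contig_lengths[[ch]]
    if (L < size) return(NULL)
    starts <- seq.int(0, L - size, by = step)
    data.frame(chrom = ch, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  out
}

# For each window, the row indices of variants falling inside it
# (1-based VCF positions mapped to 0-based coordinates).
window_site_map <- function(windows, variants) {
  p0 <- variants$pos - 1
  res <- vector("list", nrow(windows))
  for (ch in unique(windows$chrom)) {
    vi <- which(variants$chrom == ch)
    vi <- vi[order(p0[vi])]
    pos_sorted <- p0[vi]
    wi <- which(windows$chrom == ch)
    lo <- findInterval(windows$start[wi] - 0.5, pos_sorted) + 1L
    hi <- findInterval(windows$end[wi] - 0.5, pos_sorted)
    for (k in seq_along(wi)) {
      res[[wi[k]]] <- if (lo[k] <= hi[k]) vi[lo[k]:hi[k]] else integer(0)
    }
  }
  res
}

#' Windowed mean of per-site F_ST
#'
#' Arithmetic mean of defined per-site theta values within each window;
#' windows with fewer than `min_snps` usable sites are dropped.
#'
#' @param theta Per-locus theta values (may contain `NA`).
#' @param variants Variant table aligned with `theta`.
#' @param windows Windows from [make_windows()].
#' @param min_snps Minimum usable SNPs per retained window.
#' @return data.frame of retained windows with `n_snps` and `fst_mean`.
#' @export
window_fst <- function(theta, variants, windows, min_snps = 50) {
  sm <- window_site_map(windows, variants)
  n_snps <- vapply(sm, function(ix) sum(!is.na(theta[ix])), integer(1))
  fst_mean <- vapply(sm, function(ix) {
    v <- theta[ix]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  keep <- n_snps >= min_snps
  cbind(windows[keep, , drop = FALSE],
        data.frame(n_snps = n_snps[keep], fst_mean = fst_mean[keep]))
}

#' Z-transform a vector of window statistics
#'
#' @param x Numeric vector (>= 2 values, nonzero spread).
#' @return `(x - mean(x)) / sd(x)` using the sample (n-1) standard
#'   deviation.
#' @export
zscore <- function(x) {
  if (length(x) < 2L) stop("need >= 2 values to Z-transform")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero spread: Z-scores undefined")
  (x - mean(x)) / s
}

# Per-site unbiased nucleotide diversity from alt-allele frequency and the
# number of non-missing allele copies m: (m/(m-1)) * 2*p*q. Equals the mean
# pairwise difference over all pairs of allele copies at the site.
pi_site <- function(p, m) {
  out <- (m / (m - 1)) * 2 * p * (1 - p)
  out[m < 2] <- NA_real_
  out
}

#' Windowed per-bp nucleotide diversity
#'
#' Sums the unbiased per-site pi over variant sites in each window and
#' divides by window length; invariant sites contribute zero. Windows with
#' sites but no genotyped calls are `NA`.
#'
#' @param genotypes Dosage matrix.
#' @param popmap Population map.
#' @param pop Population label(s); multiple labels are pooled.
#' @param windows Windows from [make_windows()].
#' @param variants Variant table aligned with `genotypes`.
#' @return Numeric vector of per-bp pi, one value per window row.
#' @export
window_pi <- function(genotypes, popmap, pop, windows, variants) {
  idx <- pop_indices(genotypes, popmap, pop)
  st <- pop_site_stats(genotypes, idx)
  ps <- pi_site(st$p, 2 * st$n)
  sm <- window_site_map(windows, variants)
  vapply(seq_len(nrow(windows)), function(k) {
    ix <- sm[[k]]
    if (length(ix) == 0L) return(0)
    v <- ps[ix]
    if (all(is.na(v))) return(NA_real_)
    sum(v, na.rm = TRUE) / (windows$end[k] - windows$start[k])
  }, numeric(1))
}

#' Log2 nucleotide-diversity ratio
#'
#' `log2(pi_control / pi_test)`: large positive values mark diversity
#' depletion in the test population. `Inf` when the test diversity is zero
#' but the control's is not; `NA` when both are zero.
#'
#' @param pi_control,pi_test Per-window per-bp diversity values.
#' @return Numeric vector.
#' @export
log2_pi_ratio <- function(pi_control, pi_test) {
  out <- log2(pi_control / pi_test)
  out[pi_control == 0 & pi_test == 0] <- NA_real_
  out
}

#' Tajima's D from per-site frequencies
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with `S` the number of
#' segregating sites, `pi` the sum of unbiased per-site diversities (total,
#' not per bp), and the standard constants evaluated at `n` = the rounded
#' mean number of non-missing allele copies across the window's genotyped
#' sites.
#'
#' @param freq Per-site alt-allele frequencies within the population for
#'   all variant sites in the window.
#' @param n_copies Per-site counts of non-missing allele copies.
#' @return D, or `NA` when no site segregates or fewer than 3 allele
#'   copies are available.
#' @export
tajimas_d <- function(freq, n_copies) {
  has_data <- n_copies > 0 & !is.na(freq)
  if (!any(has_data)) return(NA_real_)
  seg <- has_data & n_copies >= 2 & freq > 0 & freq < 1
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  n <- round(mean(n_copies[has_data]))
  if (n < 3) return(NA_real_)
  pi_tot <- sum(pi_site(freq[seg], n_copies[seg]))
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi_tot - S / k$a1) / denom
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Flag top-quantile outlier windows
#'
#' Rank-based outlier calling: the top `floor((1 - quantile) * W)` windows
#' by Z(F_ST) and, independently, by log2 pi-ratio are flagged; ties are
#' broken by genomic order (earlier windows kept). The joint flag is the
#' conjunction. Realized cutoffs (the minimum flagged value of each
#' statistic) are reported for comparability across runs.
#'
#' @param rows data.frame with columns `zfst` and `log2_ratio` in genomic
#'   order (>= 20 rows).
#' @param quantile Outlier quantile (default 0.95, i.e. top 5 percent).
#' @return List with `rows` (input plus `fst_outlier`, `pi_outlier`,
#'   `joint_outlier` logical columns) and `thresholds` (list: `quantile`,
#'   `n_flagged`, `zfst_cutoff`, `log2_ratio_cutoff`).
#' @export
call_outliers <- function(rows, quantile = 0.95) {
  W <- nrow(rows)
  if (W < 20L) stop("need >= 20 retained windows to call ",
                    100 * (1 - quantile), "% outliers")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  k <- floor((1 - quantile) * W)
  top_k <- function(v) {
    flag <- rep(FALSE, W)
    flag[order(-v, seq_len(W))[seq_len(k)]] <- TRUE
    flag
  }
  rows$fst_outlier <- top_k(rows$zfst)
  rows$pi_outlier <- top_k(rows$log2_ratio)
  rows$joint_outlier <- rows$fst_outlier & rows$pi_outlier
  list(rows = rows,
       thresholds = list(
         quantile = quantile, n_flagged = k,
         zfst_cutoff = min(rows$zfst[rows$fst_outlier]),
         log2_ratio_cutoff = min(rows$log2_ratio[rows$pi_outlier])))
}

#' Run the full selective-sweep scan
#'
#' Computes per-site Weir-Cockerham theta between the test population and
#' the pooled control group, window means (dropping windows with fewer
#' than `min_snps` usable sites), genome-wide Z(F_ST), per-bp pi in each
#' group with the log2 ratio, Tajima's D per group, and rank-based joint
#' outlier flags.
#'
#' @param variants,genotypes As from [read_vcf()] (filtered).
#' @param popmap Population map.
#' @param test_pop Label of the test population; all other populations are
#'   pooled as the control group.
#' @param window_size,step Window geometry in bp.
#' @param min_snps Minimum usable SNPs per retained window.
#' @param quantile Outlier quantile passed to [call_outliers()].
#' @param contig_lengths Optional named contig lengths; defaults to the
#'   maximum observed position per contig.
#' @return Object of class `sweep_scan`: list with `windows` (one row per
#'   retained window: coordinates, `n_snps`, `fst_mean`, `zfst`,
#'   `pi_test`, `pi_control`, `log2_ratio`, `tajd_test`, `tajd_control`,
#'   outlier flags), `thresholds`, and `params`.
#' @export
sweep_scan <- function(variants, genotypes, popmap, test_pop,
                       window_size = 100000, step = 50000, min_snps = 50,
                       quantile = 0.95, contig_lengths = NULL) {
  pops <- levels(popmap$population)
  if (!test_pop %in% pops)
    stop("test population '", test_pop, "' absent from population map")
  control_pops <- setdiff(pops, test_pop)
  if (length(control_pops) == 0L) stop("no control populations")
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(variants$pos, variants$chrom, max)
    contig_lengths <- stats::setNames(as.numeric(contig_lengths),
                                      names(contig_lengths))
  }
  windows <- make_windows(contig_lengths, size = window_size, step = step)
  if (nrow(windows) == 0L) stop("no windows: contigs shorter than ",
                                window_size, " bp")
  it <- pop_indices(genotypes, popmap, test_pop)
  ic <- pop_indices(genotypes, popmap, control_pops)
  st_t <- pop_site_stats(genotypes, it)
  st_c <- pop_site_stats(genotypes, ic)
  comp <- wc_components_vec(st_t$n, st_t$p, st_t$h, st_c$n, st_c$p, st_c$h)
  pis_t <- pi_site(st_t$p, 2 * st_t$n)
  pis_c <- pi_site(st_c$p, 2 * st_c$n)

  sm <- window_site_map(windows, variants)
  wlen <- windows$end - windows$start
  stat1 <- function(ix, v, f) if (length(ix) && !all(is.na(v[ix])))
    f(v[ix]) else NA_real_
  rows <- windows
  rows$n_snps <- vapply(sm, function(ix) sum(!is.na(comp$theta[ix])),
                        integer(1))
  rows$fst_mean <- vapply(sm, stat1, numeric(1), v = comp$theta,
                          f = function(x) mean(x, na.rm = TRUE))
  sum0 <- function(x) sum(x, na.rm = TRUE)
  rows$pi_test <- vapply(seq_along(sm), function(k)
    if (length(sm[[k]]) == 0L) 0 else
      stat1(sm[[k]], pis_t, sum0) / wlen[k], numeric(1))
  rows$pi_control <- vapply(seq_along(sm), function(k)
    if (length(sm[[k]]) == 0L) 0 else
      stat1(sm[[k]], pis_c, sum0) / wlen[k], numeric(1))
  rows$tajd_test <- vapply(seq_along(sm), function(k)
    tajimas_d(st_t$p[sm[[k]]], 2 * st_t$n[sm[[k]]]), numeric(1))
  rows$tajd_control <- vapply(seq_along(sm), function(k)
    tajimas_d(st_c$p[sm[[k]]], 2 * st_c$n[sm[[k]]]), numeric(1))

  rows$log2_ratio <- log2_pi_ratio(rows$pi_control, rows$pi_test)
  keep <- rows$n_snps >= min_snps & !is.na(rows$fst_mean) &
    !is.na(rows$pi_test) & !is.na(rows$pi_control) & !is.na(rows$log2_ratio)
  rows <- rows[keep, , drop = FALSE]
  rownames(rows) <- NULL
  if (nrow(rows) < 2L) stop("fewer than 2 retained windows; lower min_snps ",
                            "or use longer contigs")
  rows$zfst <- zscore(rows$fst_mean)
  called <- call_outliers(rows, quantile = quantile)
  structure(list(windows = called$rows, thresholds = called$thresholds,
                 params = list(test_pop = test_pop,
                               control_pops = control_pops,
                               window_size = window_size, step = step,
                               min_snps = min_snps, quantile = quantile)),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  w <- x$windows
  cat("Selective-sweep scan:", x$params$test_pop, "vs pooled {",
      paste(x$params$control_pops, collapse = ", "), "}\n")
  cat(sprintf("  %d retained windows (%g kb sliding by %g kb, >= %d SNPs)\n",
              nrow(w), x$params$window_size / 1000, x$params$step / 1000,
              x$params$min_snps))
  cat(sprintf("  outliers: %d F_ST, %d pi-ratio, %d joint\n",
              sum(w$fst_outlier), sum(w$pi_outlier), sum(w$joint_outlier)))
  cat(sprintf("  realized cutoffs: Z(F_ST) > %.3f, log2(pi ratio) > %.3f\n",
              x$thresholds$zfst_cutoff, x$thresholds$log2_ratio_cutoff))
  invisible(x)
}

#' Genes overlapping scan windows
#'
#' Annotates windows with the gene features of a GFF3 file whose spans
#' overlap them by at least 1 bp (windows are 0-based half-open, GFF3 is
#' 1-based closed).
#'
#' @param windows data.frame with `chrom`, `start`, `end` (and optionally
#'   scan statistics, which are carried through).
#' @param gff3 Path to a GFF3 file containing `gene` features.
#' @return data.frame: one row per (window, gene) overlap with the gene
#'   name and span.
#' @export
genes_in_windows <- function(windows, gff3) {
  lines <- readLines(gff3)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf != 9L))
    stop("malformed GFF3 line ", body[which(nf != 9L)[1L]], " in ", gff3,
         ": expected 9 tab-separated fields")
  if (length(body) == 0L)
    return(empty_gene_table(windows))
  f <- strsplit(lines[body], "\t", fixed = TRUE)
  feat <- data.frame(
    chrom = vapply(f, `[[`, character(1), 1L),
    type = vapply(f, `[[`, character(1), 3L),
    start = as.integer(vapply(f, `[[`, character(1), 4L)),
    end = as.integer(vapply(f, `[[`, character(1), 5L)),
    attr = vapply(f, `[[`, character(1), 9L),
    stringsAsFactors = FALSE)
  feat <- feat[feat$type == "gene", , drop = FALSE]
  if (nrow(feat) == 0L) return(empty_gene_table(windows))
  name <- sub(".*(?:^|;)Name=([^;]+).*", "\\1", feat$attr)
  noname <- !grepl("Name=", feat$attr)
  name[noname] <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", feat$attr[noname])

  g_genes <- GenomicRanges::GRanges(
    feat$chrom, IRanges::IRanges(feat$start, feat$end))
  g_win <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end))
  ov <- GenomicRanges::findOverlaps(g_win, g_genes)
  wi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  extra <- intersect(c("zfst", "log2_ratio"), names(windows))
  out <- cbind(
    windows[wi, c("chrom", "start", "end", extra), drop = FALSE],
    data.frame(gene = name[gi], gene_start = feat$start[gi],
               gene_end = feat$end[gi], stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

empty_gene_table <- function(windows) {
  extra <- intersect(c("zfst", "log2_ratio"), names(windows))
  out <- cbind(windows[0L, c("chrom", "start", "end", extra), drop = FALSE],
               data.frame(gene = character(0), gene_start = integer(0),
                          gene_end = integer(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
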