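#' Read a multi-sample VCF into a variant table and dosage matrix
#'
#' Loads a VCF (v4.x) and converts diploid GT calls to counts of the
#' non-reference allele (0, 1, 2), with `NA` for missing calls (`./.` or
#' `.|.`; phased and unphased separators are treated identically).
#' Multi-allelic or non-SNP records are loaded as-is so that
#' [apply_filters()] can count and remove them.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param samples Optional character vector restricting (and ordering) the
#'   samples to load.
#' @return A list with elements:
#'   \describe{
#'     \item{variants}{data.frame with `chrom`, `pos` (1-based), `id`,
#'       `ref`, `alt`, one row per record.}
#'     \item{genotypes}{integer matrix, loci x samples, entries in
#'       `{0, 1, 2, NA}`; column names are sample ids.}
#'     \item{depth}{numeric vector of per-site mean depth across samples
#'       (from FORMAT/DP), or `NULL` when the VCF carries no depth.}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_snps = 100, seed = 1))
#' f <- tempfile(fileext = ".vcf")
#' write_vcf(sim$variants, sim$genotypes, f)
#' dat <- read_vcf(f)
#' dim(dat$genotypes)
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    sample_ids <- character(0)
    if (ncol(vcf@gt) > 1L) sample_ids <- colnames(vcf@gt)[-1L]
    if (!is.null(samples)) sample_ids <- samples
    return(list(
      variants = data.frame(chrom = character(0), pos = integer(0),
                            id = character(0), ref = character(0),
                            alt = character(0), stringsAsFactors = FALSE),
      genotypes = matrix(integer(0), nrow = 0L, ncol = length(sample_ids),
                         dimnames = list(NULL, sample_ids)),
      depth = NULL))
  }
  variants <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos   = as.integer(fix[, "POS"]),
    id    = as.character(fix[, "ID"]),
    ref   = as.character(fix[, "REF"]),
    alt   = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L)
    stop("malformed VCF: no GT fields found in ", path)
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s))
      stop("samples absent from VCF: ", paste(missing_s, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  dos <- gt_to_dosage(gt)
  rownames(dos) <- NULL

  depth <- NULL
  fmt <- unique(vcf@gt[, 1L])
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    if (!is.null(samples)) dp <- dp[, samples, drop = FALSE]
    depth <- rowMeans(dp, na.rm = TRUE)
    depth[is.nan(depth)] <- NA_real_
    names(depth) <- NULL
  }
  list(variants = variants, genotypes = dos, depth = depth)
}

# Map a character matrix of GT strings to integer alt-allele dosages.
# Vectorised through a lookup over the (few) distinct GT strings.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  map <- vapply(u, function(g) {
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (length(alleles) != 2L)
      stop("ploidy != 2: genotype '", g, "' is not diploid")
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }, integer(1))
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  idx <- match(as.vector(gt), u)
  out[] <- map[idx]
  out
}

#' Write a variant table and dosage matrix as VCF v4.2
#'
#' Emits unphased GT calls (`0/0`, `0/1`, `1/1`) with missing entries as
#' `./.`. The inverse of [read_vcf()] for biallelic SNP data.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `id` columns.
#' @param genotypes integer dosage matrix, loci x samples, entries in
#'   `{0, 1, 2, NA}`; column names are the sample ids.
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for
#'   `##contig` header lines.
#' @param source_line Optional string recorded in a `##source` header line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path, contig_lengths = NULL,
                      source_line = NULL) {
  if (nrow(variants) != nrow(genotypes))
    stop("variants and genotypes disagree on locus count (",
         nrow(variants), " vs ", nrow(genotypes), ")")
  bad <- !(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  sample_ids <- colnames(genotypes)
  if (is.null(sample_ids) && ncol(genotypes) > 0L)
    sample_ids <- paste0("S", seq_len(ncol(genotypes)))

  header <- c("##fileformat=VCFv4.2")
  if (!is.null(source_line)) header <- c(header, paste0("##source=", source_line))
  if (!is.null(contig_lengths))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths),
                                as.integer(contig_lengths)))
  header <- c(header,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))

  gt_codes <- c("0/0", "0/1", "1/1")
  body <- character(0)
  if (nrow(variants) > 0L) {
    gt_chr <- matrix("./.", nrow = nrow(genotypes), ncol = ncol(genotypes))
    ok <- !is.na(genotypes)
    gt_chr[ok] <- gt_codes[genotypes[ok] + 1L]
    id <- if ("id" %in% names(variants)) variants$id else NA_character_
    id[is.na(id)] <- "."
    left <- paste(variants$chrom, variants$pos, id, variants$ref,
                  variants$alt, ".", ".", ".", "GT", sep = "\t")
    body <- paste(left, apply(gt_chr, 1L, paste, collapse = "\t"), sep = "\t")
    if (ncol(genotypes) == 0L) body <- left
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' @param path Two-column whitespace- or tab-delimited text file:
#'   sample id, population label. Lines starting with `#` are ignored.
#' @return data.frame with columns `sample` (character) and `population`
#'   (factor whose levels follow first appearance in the file).
#' @export
read_popmap <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no samples in population map: ", path)
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("population map line ", which(nf != 2L)[1L],
         " does not have two columns")
  sample <- vapply(parts, `[[`, character(1), 1L)
  pop <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(sample))
    stop("duplicate sample id in population map: ",
         sample[duplicated(sample)][1L])
  data.frame(sample = sample,
             population = factor(pop, levels = unique(pop)),
             stringsAsFactors = FALSE)
}

#' Write a population map
#' @param popmap data.frame as returned by [read_popmap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  writeLines(paste(popmap$sample, as.character(popmap$population),
                   sep = "\t"), path)
  invisible(path)
}

# Column indices of a population's samples in a genotype matrix.
pop_indices <- function(genotypes, popmap, pop) {
  stopifnot(is.matrix(genotypes))
  ids <- popmap$sample[as.character(popmap$population) %in% pop]
  if (length(ids) == 0L) stop("population not found in map: ",
                              paste(pop, collapse = ", "))
  idx <- match(ids, colnames(genotypes))
  if (anyNA(idx)) {
    warning("samples in population map absent from genotypes: ",
            paste(ids[is.na(idx)], collapse = ", "))
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0L) stop("no genotyped samples for population: ",
                              paste(pop, collapse = ", "))
  idx
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test for a biallelic locus: given the
#' observed allele counts, sums the probabilities of all heterozygote
#' configurations whose probability does not exceed that of the observed
#' configuration.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative integers).
#' @return The exact p-value, in (0, 1].
#' @examples
#' hwe_exact_p(1, 0, 1)  # 1/3
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  rare <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)  # minor allele copies
  hets <- seq.int(rare %% 2L, rare, by = 2L)       # feasible het counts
  # log P(nAa = h | n, rare) under HWE, conditioning on allele counts
  log_p <- function(h) {
    n_rr <- (rare - h) / 2L
    n_cc <- n - n_rr - h
    lfactorial(n) - lfactorial(n_rr) - lfactorial(h) - lfactorial(n_cc) +
      h * log(2) - (lfactorial(2L * n) - lfactorial(rare) -
                    lfactorial(2L * n - rare))
  }
  lp <- vapply(hets, log_p, numeric(1))
  p_all <- exp(lp - max(lp))
  p_all <- p_all / sum(p_all)
  p_obs <- p_all[match(n_Aa, hets)]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-12)]))
}

#' Construct variant-filtering criteria
#'
#' Thresholds for the rule-based SNP filter applied by [apply_filters()].
#' Defaults keep biallelic autosomal SNPs with per-site mean depth strictly
#' between 3x and 30x (when depth is available), call rate >= 0.90, missing
#' rate <= 0.1, pooled minor allele frequency >= 0.05 and exact
#' Hardy-Weinberg p >= 1e-5.
#'
#' @param maf_min Minimum pooled minor allele frequency; loci below are
#'   removed. `0` disables the rule.
#' @param max_missing_rate Maximum tolerated fraction of missing calls.
#' @param hwe_p_min Minimum exact HWE p-value (pooled genotype counts);
#'   `0` disables.
#' @param min_call_rate Minimum fraction of called genotypes; `0` disables.
#' @param biallelic_only Drop multi-allelic or non-SNP records.
#' @param autosomes Optional character vector of contigs to keep; `NULL`
#'   keeps all contigs.
#' @param depth_min,depth_max Bounds on per-site mean depth, applied only
#'   when depth is available (exclusive bounds: a site is kept when
#'   `depth_min < depth < depth_max`).
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(maf_min = 0.05, max_missing_rate = 0.1,
                            hwe_p_min = 1e-5, min_call_rate = 0.90,
                            biallelic_only = TRUE, autosomes = NULL,
                            depth_min = 3, depth_max = 30) {
  if (maf_min < 0 || maf_min >= 0.5)
    stop("maf_min must satisfy 0 <= maf_min < 0.5")
  if (min_call_rate < 0 || min_call_rate > 1)
    stop("min_call_rate must be in [0, 1]")
  if (max_missing_rate < 0 || max_missing_rate > 1)
    stop("max_missing_rate must be in [0, 1]")
  if (hwe_p_min < 0 || hwe_p_min > 1) stop("hwe_p_min must be in [0, 1]")
  if (depth_min >= depth_max) stop("depth_min must be < depth_max")
  structure(list(maf_min = maf_min, max_missing_rate = max_missing_rate,
                 hwe_p_min = hwe_p_min, min_call_rate = min_call_rate,
                 biallelic_only = biallelic_only, autosomes = autosomes,
                 depth_min = depth_min, depth_max = depth_max),
            class = "filter_criteria")
}

#' Apply variant-filtering rules
#'
#' Filters loci in a fixed order -- (1) contig whitelist / biallelic SNP,
#' (2) depth bounds (only when per-site depth is supplied), (3) call rate,
#' (4) missing rate, (5) pooled minor allele frequency, (6) exact
#' Hardy-Weinberg test on pooled genotype counts -- and reports, per rule,
#' the number of loci whose *first* failed rule it is, so that
#' `input = retained + sum(removed)` always holds.
#'
#' @param variants,genotypes As returned by [read_vcf()].
#' @param criteria A [filter_criteria()] object.
#' @param depth Optional numeric vector of per-site mean depth.
#' @return A list with filtered `variants`, `genotypes`, and `report`
#'   (class `filter_report`: input/retained counts and per-rule removals).
#' @export
apply_filters <- function(variants, genotypes, criteria = filter_criteria(),
                          depth = NULL) {
  if (!inherits(criteria, "filter_criteria"))
    criteria <- do.call(filter_criteria, criteria)
  if (nrow(variants) != nrow(genotypes))
    stop("variants and genotypes disagree on locus count")
  L <- nrow(genotypes)
  ns <- ncol(genotypes)
  rules <- c("structural", "depth", "call_rate", "missing", "maf", "hwe")
  removed_by <- rep(NA_character_, L)
  mark <- function(fail, rule) {
    fail[is.na(fail)] <- FALSE
    removed_by[fail & is.na(removed_by)] <<- rule
  }

  if (L > 0L) {
    single_base <- function(x) x %in% c("A", "C", "G", "T")
    structural <- rep(FALSE, L)
    if (isTRUE(criteria$biallelic_only))
      structural <- structural |
        !single_base(toupper(variants$ref)) |
        !single_base(toupper(variants$alt)) |
        toupper(variants$ref) == toupper(variants$alt)
    if (!is.null(criteria$autosomes))
      structural <- structural | !(variants$chrom %in% criteria$autosomes)
    mark(structural, "structural")

    if (!is.null(depth))
      mark(!(depth > criteria$depth_min & depth < criteria$depth_max),
           "depth")

    n_called <- rowSums(!is.na(genotypes))
    if (ns > 0L) {
      mark(n_called / ns < criteria$min_call_rate, "call_rate")
      mark((ns - n_called) / ns > criteria$max_missing_rate, "missing")
    }

    p <- rowSums(genotypes, na.rm = TRUE) / (2 * n_called)
    maf <- pmin(p, 1 - p)
    if (criteria$maf_min > 0) mark(maf < criteria$maf_min, "maf")

    if (criteria$hwe_p_min > 0) {
      todo <- which(is.na(removed_by) & n_called > 0L)
      if (length(todo)) {
        n_het <- rowSums(genotypes[todo, , drop = FALSE] == 1L, na.rm = TRUE)
        n_aa  <- rowSums(genotypes[todo, , drop = FALSE] == 2L, na.rm = TRUE)
        n_AA  <- n_called[todo] - n_het - n_aa
        hp <- mapply(hwe_exact_p, n_AA, n_het, n_aa)
        mark_idx <- todo[hp < criteria$hwe_p_min]
        removed_by[mark_idx] <- "hwe"
      }
    }
  }

  keep <- is.na(removed_by)
  removed <- vapply(rules, function(r) sum(removed_by == r, na.rm = TRUE),
                    integer(1))
  report <- structure(list(input = L, retained = sum(keep),
                           removed = removed, criteria = criteria),
                      class = "filter_report")
  list(variants = variants[keep, , drop = FALSE],
       genotypes = genotypes[keep, , drop = FALSE],
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Variant filter report\n")
  cat("  input loci:    ", x$input, "\n")
  for (r in names(x$removed))
    cat(sprintf("  removed (%s): %d\n", r, x$removed[[r]]))
  cat("  retained:      ", x$retained, "\n")
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(rule = c("input", names(x$removed), "retained"),
             loci = c(x$input, unname(x$removed), x$retained),
             stringsAsFactors = FALSE)
}

#' Greedy LD pruning of a dosage matrix
#'
#' Mirrors the classic windowed pairwise pruning: successive windows of
#' `window_snps` loci advanced by `step_snps`; within each window, pairs of
#' still-retained loci are scanned in position order and the later locus of
#' any pair whose squared dosage correlation exceeds `r2_threshold` is
#' dropped. Deterministic.
#'
#' @param genotypes Dosage matrix (loci in genomic order).
#' @param window_snps,step_snps Window extent and advance, in loci.
#' @param r2_threshold Pairwise r-squared above which the later locus is
#'   removed.
#' @return Integer vector of retained locus indices (row numbers).
#' @export
ld_prune <- function(genotypes, window_snps = 50, step_snps = 10,
                     r2_threshold = 0.2) {
  L <- nrow(genotypes)
  if (L < 1L) stop("need at least one locus")
  if (window_snps < 2L) stop("window_snps must be >= 2")
  if (step_snps < 1L) stop("step_snps must be >= 1")
  keep <- rep(TRUE, L)
  starts <- seq.int(1L, L, by = step_snps)
  for (s in starts) {
    idx <- s:min(s + window_snps - 1L, L)
    idx <- idx[keep[idx]]
    if (length(idx) < 2L) next
    for (i in seq_len(length(idx) - 1L)) {
      a <- idx[i]
      if (!keep[a]) next
      for (j in (i + 1L):length(idx)) {
        b <- idx[j]
        if (!keep[b]) next
        r <- suppressWarnings(stats::cor(genotypes[a, ], genotypes[b, ],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r * r > r2_threshold) keep[b] <- FALSE
      }
    }
  }
  which(keep)
}

#' Transition/transversion ratio
#'
#' @param variants Variant table with single-base `ref` and `alt`.
#' @return Ratio of transitions (A<->G, C<->T) to transversions; `Inf`
#'   (with a warning) when no transversions are present.
#' @export
ts_tv_ratio <- function(variants) {
  if (nrow(variants) < 1L) stop("need at least one SNP")
  ref <- toupper(variants$ref)
  alt <- toupper(variants$alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  pair <- paste0(ref[ok], alt[ok])
  ts <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- sum(ok) - ts
  if (tv == 0L) {
    warning("no transversions: Ts/Tv ratio undefined (infinite)")
    return(Inf)
  }
  ts / tv
}

#' GC content of a FASTA file
#'
#' @param path FASTA file.
#' @return Fraction (G+C)/(A+C+G+T), case-insensitive; ambiguity codes and
#'   Ns are excluded from the denominator.
#' @export
gc_content <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  freq <- colSums(Biostrings::alphabetFrequency(seqs))
  acgt <- sum(freq[c("A", "C", "G", "T")])
  if (acgt == 0) stop("no unambiguous A/C/G/T bases in ", path)
  unname(sum(freq[c("G", "C")]) / acgt)
}
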