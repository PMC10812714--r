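test_that("GT strings map to alt-allele dosages with missing as NA", {
  path <- write_lines_vcf(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tC\tT\t.\t.\t.\tGT\t1/1\t./.",
    "chr1\t300\t.\tG\tA\t.\t.\t.\tGT\t0|1\t1|1"))
  dat <- read_vcf(path)
  expect_equal(unname(dat$genotypes),
               matrix(c(0L, 1L, 2L, NA, 1L, 2L), 3, 2, byrow = TRUE))
  expect_equal(colnames(dat$genotypes), c("S1", "S2"))
  expect_equal(dat$variants$pos, c(100L, 200L, 300L))
  expect_null(dat$depth)
})

test_that("a VCF with no variant records yields an empty table and matrix", {
  path <- write_lines_vcf(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2"))
  dat <- suppressWarnings(read_vcf(path))
  expect_equal(nrow(dat$variants), 0L)
  expect_equal(nrow(dat$genotypes), 0L)
})

test_that("non-diploid GT fields are rejected", {
  path <- write_lines_vcf(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0/1"))
  expect_error(read_vcf(path), "ploidy")
})

test_that("write_vcf emits unphased GT codes and round-trips exactly", {
  vt <- data.frame(chrom = "chr1", pos = 10L, id = NA_character_,
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- matrix(1L, 1, 1, dimnames = list(NULL, "S1"))
  f <- tempfile(fileext = ".vcf")
  write_vcf(vt, gm, f)
  body <- readLines(f)
  expect_match(body[length(body)], "0/1$")
  gm[1, 1] <- NA_integer_
  write_vcf(vt, gm, f)
  expect_match(readLines(f)[length(body)], "\\./\\.$")
  expect_error(write_vcf(vt, rbind(gm, gm), f), "disagree")

  sim <- simulate_dataset(sim_config(seed = 5, contigs = c(chr1 = 1e5),
                                     n_snps = 400, missing_rate = 0.05,
                                     sweeps = NULL))
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(sim$variants, sim$genotypes, f2)
  back <- read_vcf(f2)
  expect_identical(back$genotypes, sim$genotypes)
  expect_identical(back$variants$pos, sim$variants$pos)
  expect_identical(colnames(back$genotypes), colnames(sim$genotypes))
})

test_that("population maps preserve first-appearance order and reject problems", {
  f <- tempfile()
  writeLines(c("s1 popB", "s2 popA", "s3\tpopB", "s4 popA"), f)
  pm <- read_popmap(f)
  expect_equal(nrow(pm), 4L)
  expect_equal(levels(pm$population), c("popB", "popA"))

  writeLines(c("s1 popA", "s1 popB"), f)
  expect_error(read_popmap(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_popmap(f), "no samples")

  # a five-population design of 12 + 5 + 11 + 12 + 5 goats
  sizes <- c(AB = 12, AF = 5, BG = 11, CH = 12, MR = 5)
  writeLines(paste(sprintf("g%02d", seq_len(sum(sizes))),
                   rep(names(sizes), sizes), sep = "\t"), f)
  pm <- read_popmap(f)
  expect_equal(nrow(pm), 45L)
  expect_equal(nlevels(pm$population), 5L)
  expect_equal(as.vector(table(pm$population)[names(sizes)]),
               unname(sizes))
})

test_that("exact HWE p-values match exhaustive enumeration", {
  expect_equal(hwe_exact_p(5, 0, 0), 1.0)
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_p(0, 2, 0), 1.0)
  expect_error(hwe_exact_p(0, 0, 0), "zero")
  # every genotype configuration with up to 10 individuals
  for (n in 1:10) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      p <- hwe_exact_p(nAA, nAa, naa)
      expect_gt(p, 0)
      expect_lte(p, 1)
      expect_equal(p, oracle_hwe(nAA, nAa, naa), tolerance = 1e-12)
    }
  }
})

test_that("filter rules remove loci in order with per-rule attribution", {
  ns <- 25
  gm <- matrix(0L, 6, ns, dimnames = list(NULL, sprintf("S%02d", 1:ns)))
  gm[1, 1:12] <- 1L                 # triallelic record (structural)
  gm[2, 1] <- 1L                    # pooled MAF = 1/50 = 0.02
  gm[3, ] <- rep(c(0L, 1L), length.out = ns); gm[3, 1:5] <- NA  # 20% missing
  gm[4, 1:13] <- 0L; gm[4, 14:25] <- 2L  # no hets: HWE p = 4.3e-8
  gm[5, ] <- rep(c(0L, 1L, 2L, 1L, 0L), 5)   # clean
  gm[6, ] <- rep(c(1L, 0L, 1L), length.out = ns)  # clean
  vt <- data.frame(chrom = "chr1", pos = seq(100L, 600L, 100L),
                   id = NA, ref = "A",
                   alt = c("G,T", "C", "C", "G", "T", "C"),
                   stringsAsFactors = FALSE)
  # call-rate rule disabled so the missing-rate rule is the one exercised
  crit <- filter_criteria(min_call_rate = 0)
  res <- apply_filters(vt, gm, crit)
  expect_equal(res$report$retained, 2L)
  expect_equal(res$report$removed[c("structural", "maf", "missing", "hwe")],
               c(structural = 1L, maf = 1L, missing = 1L, hwe = 1L))
  expect_equal(res$report$input,
               res$report$retained + sum(res$report$removed))
  expect_equal(res$variants$pos, c(500L, 600L))

  # idempotence: filtering the filtered set removes nothing
  res2 <- apply_filters(res$variants, res$genotypes, crit)
  expect_equal(res2$report$retained, res$report$retained)
  expect_equal(sum(res2$report$removed), 0L)

  # disabled thresholds are the identity on biallelic autosomal input
  open <- filter_criteria(maf_min = 0, max_missing_rate = 1,
                          hwe_p_min = 0, min_call_rate = 0)
  vt_bi <- vt[-1, ]; gm_bi <- gm[-1, ]
  ident <- apply_filters(vt_bi, gm_bi, open)
  expect_equal(nrow(ident$variants), 5L)

  # empty input
  e <- apply_filters(vt[0, ], gm[0, , drop = FALSE], crit)
  expect_equal(e$report$input, 0L)
  expect_equal(sum(e$report$removed), 0L)
})

test_that("filter report conserves locus counts on random fixtures", {
  for (seed in 1:20) {
    L <- sample(10:80, 1)
    gm <- rand_gm(L, 12, miss = runif(1, 0, 0.3), seed = seed)
    vt <- rand_variants(L, seed = seed)
    res <- apply_filters(vt, gm, filter_criteria())
    expect_equal(res$report$input,
                 res$report$retained + sum(res$report$removed))
    expect_equal(nrow(res$variants), res$report$retained)
  }
})

test_that("depth bounds apply only when depth is supplied", {
  gm <- rand_gm(10, 10, miss = 0, seed = 3)
  vt <- rand_variants(10, seed = 3)
  depth <- rep(16, 10); depth[c(2, 7)] <- c(2, 35)
  res <- apply_filters(vt, gm, filter_criteria(maf_min = 0, hwe_p_min = 0),
                       depth = depth)
  expect_equal(res$report$removed[["depth"]], 2L)
  res0 <- apply_filters(vt, gm, filter_criteria(maf_min = 0, hwe_p_min = 0))
  expect_equal(res0$report$removed[["depth"]], 0L)
})

test_that("LD pruning drops the later locus of correlated pairs", {
  base <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 0L, 2L, 1L)
  gm <- rbind(base, base)  # identical adjacent loci
  expect_equal(ld_prune(gm), 1L)

  # orthogonal by construction
  x <- c(0L, 1L, 2L, 0L, 1L, 2L)
  y <- c(0L, 2L, 1L, 2L, 0L, 1L)
  expect_equal(stats::cor(x, y), 0)
  expect_equal(ld_prune(rbind(x, y)), c(1L, 2L))

  # chain: r2(1,2) > 0.2 so locus 2 goes; r2(1,3) <= 0.2 so 3 survives
  l1 <- c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L, 2L, 0L, 1L, 2L)
  l2 <- l1
  l3 <- c(0L, 1L, 0L, 2L, 1L, 2L, 2L, 1L, 0L, 2L, 0L, 1L)
  stopifnot(cor(l1, l2)^2 > 0.2, cor(l1, l3)^2 <= 0.2)
  expect_equal(ld_prune(rbind(l1, l2, l3)), c(1L, 3L))

  expect_error(ld_prune(rbind(l1, l2), window_snps = 1), "window_snps")

  # post hoc: no retained within-window pair exceeds the threshold
  gm <- rand_gm(30, 20, miss = 0.05, seed = 21)
  kept <- ld_prune(gm)
  for (i in seq_along(kept)) for (j in seq_len(i - 1)) {
    r <- suppressWarnings(cor(gm[kept[i], ], gm[kept[j], ],
                              use = "pairwise.complete.obs"))
    if (!is.na(r)) expect_lte(r^2, 0.2 + 1e-12)
  }
})

test_that("Ts/Tv counts transitions against transversions", {
  vt <- data.frame(chrom = "1", pos = 1:4, id = NA,
                   ref = c("A", "C", "G", "A"),
                   alt = c("G", "T", "A", "C"), stringsAsFactors = FALSE)
  expect_equal(ts_tv_ratio(vt), 3.0)
  expect_equal(ts_tv_ratio(vt[4, ]), 0.0)
  expect_warning(r <- ts_tv_ratio(vt[1, ]), "undefined")
  expect_identical(r, Inf)
})

test_that("GC content ignores ambiguity codes", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "GCGC"), f)
  expect_equal(gc_content(f), 1.0)
  writeLines(c(">s1", "ATAT"), f)
  expect_equal(gc_content(f), 0.0)
  writeLines(c(">s1", "ATGCNN"), f)
  expect_equal(gc_content(f), 0.5)
  writeLines(c(">s1", "NNNN"), f)
  expect_error(gc_content(f), "unambiguous")
})
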