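test_that("window construction emits only fully contained windows", {
  w <- make_windows(c(chr1 = 1e6))
  expect_equal(nrow(w), 19L)
  expect_equal(w$start, seq(0, 9e5, 5e4))
  expect_equal(w$end - w$start, rep(1e5, 19))

  expect_equal(nrow(make_windows(c(chr1 = 9e4))), 0L)

  w2 <- make_windows(c(chr1 = 1.05e6), size = 1e5, step = 1e5)
  expect_equal(nrow(w2), 10L)  # floor(L / size), non-overlapping tiling
  expect_error(make_windows(c(chr1 = 1e6), size = 1e5, step = 2e5), "gaps")
})

test_that("window F_ST means respect the SNP-count threshold", {
  vt <- rand_variants(300, span = 4e5, seed = 12)
  theta <- rep(1, 300)
  w <- make_windows(c(chr1 = 4e5))
  wf <- window_fst(theta, vt, w, min_snps = 10)
  expect_true(all(wf$fst_mean == 1))

  # a window with exactly min_snps - 1 usable sites is dropped
  theta2 <- runif(300)
  in_first <- vt$pos - 1 < 1e5
  theta2[which(in_first)[-seq_len(49)]] <- NA
  wf2 <- window_fst(theta2, vt, w, min_snps = 50)
  expect_false(any(wf2$start == 0))

  # brute-force group-by oracle
  wf3 <- window_fst(theta2, vt, w, min_snps = 1)
  for (k in seq_len(nrow(wf3))) {
    sel <- vt$pos - 1 >= wf3$start[k] & vt$pos - 1 < wf3$end[k]
    expect_equal(wf3$fst_mean[k], mean(theta2[sel], na.rm = TRUE))
    expect_equal(wf3$n_snps[k], sum(!is.na(theta2[sel])))
  }
})

test_that("Z transformation normalizes and rejects degenerate input", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(rep(2, 5)), "spread")
  expect_error(zscore(1), ">= 2")
  x <- rnorm(57, 3, 0.4)
  z <- zscore(x)
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
})

test_that("window pi equals brute-force pairwise differences per bp", {
  # one site, two diploids with dosages 1,1 in a 100-bp window
  gm <- matrix(c(1L, 1L), 1, 2, dimnames = list(NULL, c("S1", "S2")))
  vt <- data.frame(chrom = "c", pos = 50L, id = NA, ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  pm <- data.frame(sample = c("S1", "S2"),
                   population = factor(c("P", "P")))
  w <- data.frame(chrom = "c", start = 0, end = 100)
  expect_equal(window_pi(gm, pm, "P", w, vt), (4 / 3) * 0.5 / 100)
  expect_equal(window_pi(gm, pm, "P", w, vt),
               oracle_window_pi(gm, 100), tolerance = 1e-12)

  # no segregating sites
  gm0 <- matrix(0L, 3, 2, dimnames = list(NULL, c("S1", "S2")))
  vt0 <- data.frame(chrom = "c", pos = c(10L, 20L, 30L), id = NA,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  expect_equal(window_pi(gm0, pm, "P", w, vt0), 0)

  # complete-data fixtures: exact to 1e-12
  for (seed in 1:40) {
    L <- sample(3:25, 1)
    gm2 <- rand_gm(L, sample(3:8, 1), miss = 0, seed = seed)
    vt2 <- rand_variants(L, span = 900, seed = seed)
    pm2 <- data.frame(sample = colnames(gm2),
                      population = factor(rep("P", ncol(gm2))))
    w2 <- data.frame(chrom = "chr1", start = 0, end = 1000)
    expect_equal(window_pi(gm2, pm2, "P", w2, vt2),
                 oracle_window_pi(gm2, 1000), tolerance = 1e-12)
  }

  # with missingness: oracle on the non-missing copies per site
  gm3 <- rand_gm(20, 6, miss = 0.25, seed = 91)
  vt3 <- rand_variants(20, span = 900, seed = 91)
  pm3 <- data.frame(sample = colnames(gm3),
                    population = factor(rep("P", 6)))
  w3 <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_equal(window_pi(gm3, pm3, "P", w3, vt3),
               oracle_window_pi(gm3, 1000), tolerance = 1e-12)
})

test_that("log2 pi-ratio flags depletion and handles zeros", {
  expect_equal(log2_pi_ratio(0.002, 0.0005), 2)
  expect_equal(log2_pi_ratio(0.001, 0.001), 0)
  expect_equal(log2_pi_ratio(0.001, 0.002), -1)
  expect_identical(log2_pi_ratio(0.001, 0), Inf)
  expect_true(is.na(log2_pi_ratio(0, 0)))
})

test_that("Tajima's D matches an independent implementation", {
  expect_true(is.na(tajimas_d(c(0, 0, 1), c(10, 10, 10))))  # S = 0
  # constructed zero numerator: pi_site equals 1/a1 at m = 4
  p0 <- (1 + sqrt(1 - 4 * (3 / 4) / (2 * (1 + 1/2 + 1/3)))) / 2
  expect_equal(tajimas_d(p0, 4), 0, tolerance = 1e-12)

  # frozen worked example: n = 10 copies, S = 5
  d <- tajimas_d(c(0.1, 0.1, 0.5, 0.9, 0.2), rep(10, 5))
  expect_equal(d, -0.581518027597, tolerance = 1e-9)

  # randomized fixtures vs oracle, with per-site missingness
  for (seed in 1:60) {
    set.seed(seed)
    S <- sample(1:30, 1)
    m <- sample(6:20, S, replace = TRUE)
    x <- vapply(m, function(mm) sample(0:mm, 1), integer(1))
    expect_equal(tajimas_d(x / m, m), oracle_tajd(x / m, m),
                 tolerance = 1e-12)
  }
})

test_that("outlier calling is rank-based with intersection joints", {
  set.seed(7)
  rows <- data.frame(chrom = "c", start = seq(0, 99) * 5e4,
                     zfst = sample(seq(0.01, 1, length.out = 100)),
                     log2_ratio = sample(seq(0.01, 1, length.out = 100)))
  out <- call_outliers(rows, 0.95)
  expect_equal(sum(out$rows$fst_outlier), 5L)
  expect_equal(sum(out$rows$pi_outlier), 5L)
  expect_equal(out$rows$joint_outlier,
               out$rows$fst_outlier & out$rows$pi_outlier)
  expect_equal(out$thresholds$zfst_cutoff,
               min(rows$zfst[out$rows$fst_outlier]))
  # flagged windows are exactly the top five values
  expect_setequal(which(out$rows$fst_outlier),
                  order(-rows$zfst)[1:5])
  expect_error(call_outliers(rows[1:19, ], 0.95), ">= 20")
})

test_that("joint outliers are the set intersection of the two flags", {
  rows <- data.frame(chrom = "c", start = seq(0, 19) * 5e4,
                     zfst = 20:1, log2_ratio = c(2:20, 1))
  out <- call_outliers(rows, 0.9)  # top 2 of each
  fst_set <- which(out$rows$fst_outlier)
  pi_set <- which(out$rows$pi_outlier)
  expect_equal(which(out$rows$joint_outlier), intersect(fst_set, pi_set))
})

test_that("gene-window overlap uses half-open interval arithmetic", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c\tsrc\tgene\t151\t250\t.\t+\t.\tID=g1;Name=GENE1",
    "c\tsrc\tgene\t51\t150\t.\t+\t.\tID=g2;Name=GENE2",
    "c\tsrc\texon\t51\t80\t.\t+\t.\tID=e1"), gff)
  w <- data.frame(chrom = "c", start = 0, end = 100)
  got <- genes_in_windows(w, gff)
  expect_equal(got$gene, "GENE2")  # [150,250) 0-based does not touch [0,100)

  # brute-force interval scan on random fixtures
  set.seed(3)
  genes <- data.frame(start1 = sample(1:500, 12))
  genes$end1 <- genes$start1 + sample(20:120, 12, replace = TRUE)
  lines <- c("##gff-version 3",
             sprintf("c\tx\tgene\t%d\t%d\t.\t+\t.\tID=g%d", genes$start1,
                     genes$end1, seq_len(12)))
  writeLines(lines, gff)
  w2 <- data.frame(chrom = "c", start = seq(0, 540, 60),
                   end = seq(0, 540, 60) + 60)
  got2 <- genes_in_windows(w2, gff)
  brute <- 0L
  for (k in seq_len(nrow(w2))) for (g in seq_len(12)) {
    if (genes$start1[g] - 1 < w2$end[k] && genes$end1[g] > w2$start[k])
      brute <- brute + 1L
  }
  expect_equal(nrow(got2), brute)

  writeLines(c("##gff-version 3", "c\tx\tgene\t1\t10"), gff)
  expect_error(genes_in_windows(w, gff), "line 2")
})

test_that("planted sweeps depress diversity and Tajima's D in the test group", {
  sim <- simulate_dataset(sim_config(seed = 42))
  filt <- apply_filters(sim$variants, sim$genotypes)
  scan <- sweep_scan(filt$variants, filt$genotypes, sim$popmap, "BG",
                     contig_lengths = sim$config$contigs)
  w <- scan$windows
  tw <- truth_windows(sim$truth$sweeps, w)
  expect_gt(sum(tw), 0)
  # diversity depletion and elevated differentiation inside sweeps
  expect_lt(mean(w$pi_test[tw]), mean(w$pi_control[tw]))
  expect_gt(mean(w$fst_mean[tw]), mean(w$fst_mean[!tw]))
  expect_gt(mean(w$log2_ratio[tw]), mean(w$log2_ratio[!tw]))
  # directionality of Tajima's D
  expect_lt(mean(w$tajd_test[tw], na.rm = TRUE), 0)
  expect_lt(mean(w$tajd_test[tw], na.rm = TRUE),
            mean(w$tajd_control[tw], na.rm = TRUE))
  # normalization identity and overlap-counting identity
  expect_equal(mean(w$zfst), 0)
  expect_equal(stats::sd(w$zfst), 1)
  ov <- summarize_overlap(scan)
  expect_equal(unname(ov["joint"]),
               length(intersect(which(w$fst_outlier), which(w$pi_outlier))))
  # all joint outliers rank in the top tail of both statistics
  expect_true(all(w$zfst[w$joint_outlier] >= scan$thresholds$zfst_cutoff))
})

test_that("windows touching a sweep boundary only are not flagged as truth", {
  sweeps <- data.frame(chrom = "c", start = 1000, end = 2000)
  w <- data.frame(chrom = "c",
                  start = c(1500, 0, 2000, 900),
                  end = c(2500, 1000, 3000, 1001))
  expect_equal(truth_windows(sweeps, w), c(TRUE, FALSE, FALSE, TRUE))
})
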