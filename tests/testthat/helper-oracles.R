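# Independent brute-force oracles, deliberately written as scalar loops /
# exhaustive enumerations so they share no code path with the package.

# Weir & Cockerham (1984) two-population components, symbol by symbol.
oracle_wc <- function(counts_a, counts_b) {
  n <- c(sum(counts_a), sum(counts_b))
  p <- c((counts_a[2] + 2 * counts_a[3]) / (2 * n[1]),
         (counts_b[2] + 2 * counts_b[3]) / (2 * n[2]))
  h <- c(counts_a[2] / n[1], counts_b[2] / n[2])
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc > 0) a / (a + b + cc) else NA_real_)
}

# Exhaustive enumeration over all heterozygote counts compatible with the
# observed allele counts.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- integer(0); logw <- numeric(0)
  for (h in 0:n) {
    kAA <- (nA - h) / 2
    if (kAA < 0 || kAA != floor(kAA)) next
    kaa <- n - kAA - h
    if (kaa < 0) next
    hets <- c(hets, h)
    logw <- c(logw, lfactorial(n) - lfactorial(kAA) - lfactorial(h) -
                lfactorial(kaa) + h * log(2))
  }
  pr <- exp(logw - max(logw)); pr <- pr / sum(pr)
  p_obs <- pr[hets == n_Aa]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# Mean pairwise difference per site over every pair of allele copies,
# summed over sites and divided by window length.
oracle_window_pi <- function(sub, window_len) {
  total <- 0
  for (s in seq_len(nrow(sub))) {
    d <- sub[s, ]
    d <- d[!is.na(d)]
    if (length(d) == 0) next
    copies <- integer(0)
    for (x in d) copies <- c(copies, switch(x + 1L, c(0L, 0L),
                                            c(0L, 1L), c(1L, 1L)))
    m <- length(copies)
    if (m < 2) next
    ndiff <- 0L; npair <- 0L
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      ndiff <- ndiff + (copies[i] != copies[j])
      npair <- npair + 1L
    }
    total <- total + ndiff / npair
  }
  total / window_len
}

# Tajima's D recomputed from scratch (constants evaluated independently).
oracle_tajd <- function(freq, m) {
  has <- m > 0 & !is.na(freq)
  if (!any(has)) return(NA_real_)
  seg <- which(has & m >= 2 & freq > 0 & freq < 1)
  S <- length(seg)
  if (S == 0) return(NA_real_)
  n <- round(sum(m[has]) / sum(has))
  if (n < 3) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pit <- 0
  for (s in seg)
    pit <- pit + (m[s] / (m[s] - 1)) * 2 * freq[s] * (1 - freq[s])
  (pit - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Reynolds' coancestry distance, per-locus loop.
oracle_reynolds <- function(gm, ia, ib) {
  num <- 0; den <- 0
  for (l in seq_len(nrow(gm))) {
    xa <- gm[l, ia]; xa <- xa[!is.na(xa)]
    xb <- gm[l, ib]; xb <- xb[!is.na(xb)]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(xa) / (2 * n1); p2 <- sum(xb) / (2 * n2)
    a_hat <- sum((c(p1, 1 - p1) - c(p2, 1 - p2))^2) -
      2 * p1 * (1 - p1) / (2 * n1 - 1) - 2 * p2 * (1 - p2) / (2 * n2 - 1)
    h1 <- 2 * p1 * (1 - p1) * 2 * n1 / (2 * n1 - 1)
    h2 <- 2 * p2 * (1 - p2) * 2 * n2 / (2 * n2 - 1)
    num <- num + a_hat
    den <- den + a_hat + h1 + h2
  }
  th <- min(1, max(0, num / den))
  -log(1 - th)
}

# Random HWE-genotype fixture: L loci x n samples, i.i.d. missingness.
rand_gm <- function(L, n, miss = 0.1, seed = 1) {
  set.seed(seed)
  p <- stats::runif(L, 0.05, 0.95)
  gm <- vapply(seq_len(n), function(i) stats::rbinom(L, 2, p), integer(L))
  if (miss > 0)
    gm[matrix(stats::runif(L * n) < miss, L, n)] <- NA_integer_
  gm <- matrix(as.integer(gm), L, n)
  colnames(gm) <- sprintf("S%02d", seq_len(n))
  gm
}

rand_variants <- function(L, chrom = "chr1", span = 1e6, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(span, L))
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  data.frame(chrom = chrom, pos = pos, id = NA_character_, ref = ref,
             alt = unname(alt), stringsAsFactors = FALSE)
}

two_pop_map <- function(gm, n_a) {
  data.frame(sample = colnames(gm),
             population = factor(rep(c("A", "B"),
                                     c(n_a, ncol(gm) - n_a)),
                                 levels = c("A", "B")),
             stringsAsFactors = FALSE)
}

write_lines_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}
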