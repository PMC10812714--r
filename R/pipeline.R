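#' @name pipeline
#' @title End-to-end analysis pipeline
#'
#' @description
#' [run_all()] chains the stages -- optional simulation, VCF and
#' population-map import, variant filtering, per-population diversity,
#' pairwise differentiation, the sweep scan, and LD decay / Ne -- with a
#' single configuration, writing self-describing TSV/BED outputs and a
#' machine-readable run manifest. All interchange is via files; each stage
#' is independently callable through the exported module functions.
NULL

default_run_config <- function() {
  list(
    seed = 1,
    vcf = NULL, popmap = NULL, gff3 = NULL, fasta = NULL,
    test_population = NULL,
    simulate = NULL,  # optional: list of sim_config() overrides
    filter = list(),  # filter_criteria() overrides
    scan = list(window_size = 1e5, step = 5e4, min_snps = 50,
                quantile = 0.95),
    ld = list(max_distance = 1e6, bin_width = 2e4,
              max_pairs_per_locus = 10, max_loci = 5000,
              alpha = 1, sample_size_correction = TRUE, cM_per_Mb = 1))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  base <- default_run_config()
  for (nm in intersect(names(config), c("filter", "scan", "ld")))
    base[[nm]] <- utils::modifyList(base[[nm]], config[[nm]])
  for (nm in setdiff(names(config), c("filter", "scan", "ld")))
    base[[nm]] <- config[[nm]]
  base
}

write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# popgenscan %s",
                     as.character(utils::packageVersion("popgenscan"))), con)
  if (!is.null(params))
    writeLines(paste0("# ", names(params), "=",
                      vapply(params, function(x)
                        paste(format(x, scientific = FALSE, trim = TRUE),
                              collapse = ","), character(1))), con)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE,
                            digits = 10),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap counts between the two outlier sets
#'
#' @param scan A `sweep_scan` object or its `windows` data.frame with
#'   `fst_outlier` and `pi_outlier` flags.
#' @return Named integer vector: `fst_only`, `pi_only`, `joint`.
#' @export
summarize_overlap <- function(scan) {
  rows <- if (inherits(scan, "sweep_scan")) scan$windows else scan
  joint <- sum(rows$fst_outlier & rows$pi_outlier)
  c(fst_only = sum(rows$fst_outlier) - joint,
    pi_only = sum(rows$pi_outlier) - joint,
    joint = joint)
}

#' Run the full pipeline
#'
#' Executes, in order: optional simulation, input loading, variant
#' filtering, diversity summary, pairwise F_ST / Reynolds matrix, the
#' sweep scan (plus gene annotation when a GFF3 is configured), and LD
#' decay with Ne estimation for the test population. Outputs are written
#' under `out_dir` with fixed names (`filter_report.tsv`,
#' `diversity.tsv`, `fst_matrix.tsv`, `scan_windows.tsv`,
#' `joint_outliers.bed`, `ld_decay.tsv`, `ne.tsv`, optionally
#' `window_genes.tsv`, plus `manifest.json`). On a stage failure the
#' completed outputs are left in place and an error manifest is written
#' before the error propagates.
#'
#' @param config A list or path to a YAML file. Recognised fields:
#'   `vcf`, `popmap`, `test_population` (required unless `simulate` is
#'   given), optional `gff3`, `fasta`, `seed`, and parameter blocks
#'   `filter` ([filter_criteria()] arguments), `scan` (window_size, step,
#'   min_snps, quantile) and `ld` (max_distance, bin_width,
#'   max_pairs_per_locus, max_loci, alpha, sample_size_correction,
#'   cM_per_Mb). A `simulate` block (list of [sim_config()] overrides)
#'   generates the inputs first.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config, out_dir) {
  cfg <- load_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "popgenscan",
                   version = as.character(
                     utils::packageVersion("popgenscan")),
                   parameters = cfg[c("seed", "filter", "scan", "ld")],
                   stages = list())
  stage <- "configure"
  fail <- function(e) {
    manifest$status <- "error"
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (completed outputs retained in ", out_dir, ")", call. = FALSE)
  }
  tryCatch({
    if (!is.null(cfg$simulate)) {
      stage <- "simulate"
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      sc <- do.call(sim_config, sim_args)
      sim <- simulate_dataset(sc, out_prefix = file.path(out_dir, "sim"))
      cfg$vcf <- sim$paths$vcf
      cfg$popmap <- sim$paths$popmap
      if (is.null(cfg$test_population))
        cfg$test_population <- sc$test_population
      manifest$stages$simulate <- list(n_snps = nrow(sim$variants),
                                       n_samples = ncol(sim$genotypes))
    }
    stage <- "configure"
    for (f in c("vcf", "popmap"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("input '", f, "' missing or not found")
    popmap <- read_popmap(cfg$popmap)
    if (is.null(cfg$test_population) ||
        !cfg$test_population %in% levels(popmap$population))
      stop("test_population must name a population in the popmap")
    manifest$inputs <- cfg[c("vcf", "popmap", "gff3", "fasta")]

    stage <- "read"
    dat <- read_vcf(cfg$vcf)
    missing_samples <- setdiff(popmap$sample, colnames(dat$genotypes))
    if (length(missing_samples))
      warning("popmap samples absent from VCF: ",
              paste(missing_samples, collapse = ", "))
    manifest$stages$read <- list(n_loci = nrow(dat$variants),
                                 n_samples = ncol(dat$genotypes))

    stage <- "filter"
    crit <- do.call(filter_criteria, cfg$filter)
    filt <- apply_filters(dat$variants, dat$genotypes, crit,
                          depth = dat$depth)
    write_tsv(as.data.frame(filt$report),
              file.path(out_dir, "filter_report.tsv"),
              params = cfg$filter)
    manifest$stages$filter <- list(
      input = filt$report$input, retained = filt$report$retained,
      removed = as.list(filt$report$removed))
    vt <- filt$variants; gm <- filt$genotypes
    if (nrow(vt) > 0L)
      manifest$stages$filter$ts_tv <- ts_tv_ratio(vt)
    if (!is.null(cfg$fasta))
      manifest$stages$filter$gc_content <- gc_content(cfg$fasta)

    stage <- "diversity"
    div <- diversity_summary(gm, popmap)
    write_tsv(div, file.path(out_dir, "diversity.tsv"))
    manifest$stages$diversity <- list(n_loci = nrow(vt),
                                      populations = div$population)

    stage <- "differentiation"
    if (nlevels(popmap$population) >= 2L) {
      m <- pairwise_matrix(gm, popmap)
      write_tsv(data.frame(population = rownames(m), m,
                           check.names = FALSE),
                file.path(out_dir, "fst_matrix.tsv"))
      manifest$stages$differentiation <- list(n_pairs =
        nlevels(popmap$population) * (nlevels(popmap$population) - 1) / 2)
    }

    stage <- "scan"
    scan <- sweep_scan(vt, gm, popmap, cfg$test_population,
                       window_size = cfg$scan$window_size,
                       step = cfg$scan$step, min_snps = cfg$scan$min_snps,
                       quantile = cfg$scan$quantile)
    write_tsv(scan$windows, file.path(out_dir, "scan_windows.tsv"),
              params = c(cfg$scan,
                         list(zfst_cutoff = scan$thresholds$zfst_cutoff,
                              log2_ratio_cutoff =
                                scan$thresholds$log2_ratio_cutoff)))
    joint <- scan$windows[scan$windows$joint_outlier, , drop = FALSE]
    writeLines(if (nrow(joint)) paste(joint$chrom,
      format(joint$start, scientific = FALSE, trim = TRUE),
      format(joint$end, scientific = FALSE, trim = TRUE),
      sep = "\t") else character(0),
      file.path(out_dir, "joint_outliers.bed"))
    ov <- summarize_overlap(scan)
    manifest$stages$scan <- list(
      n_windows = nrow(scan$windows), overlap = as.list(ov),
      zfst_cutoff = scan$thresholds$zfst_cutoff,
      log2_ratio_cutoff = scan$thresholds$log2_ratio_cutoff)
    if (!is.null(cfg$gff3)) {
      genes <- genes_in_windows(joint, cfg$gff3)
      write_tsv(genes, file.path(out_dir, "window_genes.tsv"))
      manifest$stages$scan$n_outlier_genes <- length(unique(genes$gene))
    }

    stage <- "ld_ne"
    set.seed(cfg$seed)
    ld_idx <- seq_len(nrow(vt))
    if (length(ld_idx) > cfg$ld$max_loci)
      ld_idx <- unique(round(seq(1, nrow(vt),
                                 length.out = cfg$ld$max_loci)))
    pop_n <- sum(as.character(popmap$population) == cfg$test_population)
    pairs <- pair_r2(gm[ld_idx, , drop = FALSE],
                     vt[ld_idx, , drop = FALSE],
                     popmap, cfg$test_population,
                     max_distance = cfg$ld$max_distance,
                     max_pairs_per_locus = cfg$ld$max_pairs_per_locus)
    bins <- bin_decay(pairs, bin_width = cfg$ld$bin_width,
                      max_distance = cfg$ld$max_distance)
    write_tsv(bins, file.path(out_dir, "ld_decay.tsv"), params = cfg$ld)
    ne <- estimate_ne(bins, n_samples = pop_n, alpha = cfg$ld$alpha,
                      sample_size_correction =
                        cfg$ld$sample_size_correction,
                      cM_per_Mb = cfg$ld$cM_per_Mb)
    write_tsv(ne, file.path(out_dir, "ne.tsv"))
    manifest$stages$ld_ne <- list(n_pairs = nrow(pairs),
                                  n_bins_used = sum(ne$defined))

    manifest$status <- "ok"
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = fail)
  invisible(manifest)
}
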