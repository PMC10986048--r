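pipeline_defaults <- function() {
  list(
    pops = list(B = "B", EU = "EU", AS = "AS", O = "O"),
    fd_window = 50000, fd_min_sites = 100, fd_quantile = 0.05,
    ancestry_chunk = 50000, ancestry_tail = 0.05,
    dstat_block = 5e6,
    ibd_min_len = 1e5, ribd_bin = 1e4, ribd_z = 2, ribd_nibd_min = 0.80,
    pbs_window = 50000, pbs_step = 2000, pbs_top = 0.05,
    pbs_min_sites = 10, log_base = exp(1),
    min_sites = 10, outgroup_max_derived = 0.1,
    seed = 1L
  )
}

#' Read a pipeline configuration file
#'
#' A YAML file whose keys override the pipeline defaults (window sizes,
#' quantiles, thresholds, seeds, `log_base`) and name the input paths
#' (`vcf`, `popmap`, optional `ancestry_tsv`, `ibd_eu`/`ibd_as`,
#' `ld_blocks`, `introgression_bed`, and `out_dir`).
#'
#' @param path YAML config path.
#' @return Named list: defaults overridden by the file's entries.
#' @export
read_pipeline_config <- function(path) {
  cfg <- utils::modifyList(pipeline_defaults(), yaml::read_yaml(path))
  for (k in c("vcf", "popmap", "ancestry_tsv", "ld_blocks",
              "introgression_bed", "ibd_eu", "ibd_as")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("config file ", k, " does not exist: ", cfg[[k]])
    }
  }
  cfg
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL   # the hash identifies the analysis, not where it lands
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[order(names(cfg))]), f)
  unname(tools::md5sum(f))
}

manifest_header <- function(cfg) {
  sprintf("admixscan %s; config_hash=%s; seed=%s",
          as.character(utils::packageVersion("admixscan")),
          config_hash(cfg), cfg$seed)
}

write_window_tsv <- function(wt, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(wt), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

load_pipeline_inputs <- function(cfg) {
  if (is.null(cfg$vcf) || is.null(cfg$popmap)) {
    stop("config must name 'vcf' and 'popmap'")
  }
  if (!file.exists(cfg$popmap)) stop("popmap file not found: ", cfg$popmap)
  g <- read_vcf(cfg$vcf, cfg$popmap)
  if (is.null(g$layout)) {
    # no contig header: infer chromosome ends from the last SNP
    ends <- tapply(g$sites$pos, g$sites$chrom, max)
    g$layout <- genome_layout(names(ends), as.numeric(ends))
  }
  g
}

#' Run the introgression-calling pipeline
#'
#' Stage order: genome-wide D with jackknife Z, windowed f_d, local
#' ancestry window fractions (naive painter unless an ancestry TSV is
#' supplied), top-tail ancestry windows, then f_d-top intersect
#' high-donor-ancestry as the introgression call.  Emits `dstat.json`,
#' `fd.tsv`, `ancestry.tsv`, `introgression.bed` and `log.txt` into
#' `cfg$out_dir`; every output carries the tool version, config hash and
#' seed, and reruns with the same config are byte-identical.
#'
#' @param cfg config list (see [read_pipeline_config()]); alternatively a
#'   path to a YAML config file.
#' @param g optional pre-loaded [genotype_matrix()] (skips VCF reading).
#' @return Invisibly, a manifest list: output paths plus the D result and
#'   the called `region_set`.
#' @export
run_introgression_pipeline <- function(cfg, g = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg <- utils::modifyList(pipeline_defaults(), cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- manifest_header(cfg)
  logf <- file.path(cfg$out_dir, "log.txt")
  logl <- c(hdr, "pipeline: introgression")
  if (is.null(g)) g <- stage("read_vcf", load_pipeline_inputs(cfg))
  set.seed(cfg$seed)
  pp <- cfg$pops
  q <- quartet_spec(P1 = pp$EU, P2 = pp$B, P3 = pp$AS, O = pp$O)

  d <- stage("dstat", d_statistic(g, q, block_size = cfg$dstat_block,
                                  outgroup_max_derived = cfg$outgroup_max_derived))
  dstat_path <- file.path(cfg$out_dir, "dstat.json")
  jsonlite::write_json(list(header = hdr, D = d$D, Z = d$Z, se = d$se,
                            n_blocks = d$n_blocks, n_sites = d$n_sites),
                       dstat_path, auto_unbox = TRUE, digits = NA)

  windows <- make_windows(g$layout, cfg$fd_window, cfg$fd_window)
  fd <- stage("fd", fd_windows(g, q, windows, min_sites = cfg$fd_min_sites,
                               outgroup_max_derived = cfg$outgroup_max_derived))
  write_window_tsv(fd, file.path(cfg$out_dir, "fd.tsv"), hdr)

  anc <- stage("ancestry", {
    if (!is.null(cfg$ancestry_tsv)) read_ancestry_matrix(cfg$ancestry_tsv)
    else naive_paint(g, panelA = pp$EU, panelB = pp$AS, target = pp$B,
                     chunk = cfg$ancestry_chunk)
  })
  afr <- stage("ancestry_windows", ancestry_window_fractions(anc, windows))
  write_window_tsv(afr, file.path(cfg$out_dir, "ancestry.tsv"), hdr)
  tails <- stage("ancestry_tails", top_bottom_ancestry(afr, cfg$ancestry_tail))

  calls <- stage("call_introgression",
                 call_introgression_regions(fd, tails$high_donor,
                                            cfg$fd_quantile))
  bed_path <- file.path(cfg$out_dir, "introgression.bed")
  write_bed(calls, bed_path, header = hdr)
  write_bed(tails$high_other, file.path(cfg$out_dir, "ancestry_high_EU.bed"),
            header = hdr)

  logl <- c(logl,
            sprintf("params: fd_window=%s fd_min_sites=%s fd_quantile=%s ancestry_tail=%s dstat_block=%s outgroup_max_derived=%s",
                    cfg$fd_window, cfg$fd_min_sites, cfg$fd_quantile,
                    cfg$ancestry_tail, cfg$dstat_block, cfg$outgroup_max_derived),
            sprintf("D=%.6f Z=%s", d$D, format(d$Z)),
            sprintf("introgression: %d region(s), %s bp", nrow(calls),
                    format(covered_bp(calls), scientific = FALSE)))
  writeLines(logl, logf)
  invisible(list(dstat = d, introgression = calls, high_EU = tails$high_other,
                 files = c(dstat = dstat_path, fd = file.path(cfg$out_dir, "fd.tsv"),
                           ancestry = file.path(cfg$out_dir, "ancestry.tsv"),
                           introgression = bed_path, log = logf)))
}

#' Run the selection (PBS) pipeline
#'
#' Stage order: PBS on sliding windows, top-quantile thresholding,
#' exclusion of introgression regions, merging into sweeps, and (when an
#' LD-block BED is configured) intersection with GWAS LD blocks.  Emits
#' `pbs.tsv`, `threshold.json`, `sweeps.bed`, `core_regions.bed` and
#' `log.txt`.
#'
#' @inheritParams run_introgression_pipeline
#' @param introgressed optional `region_set` of introgression regions; by
#'   default read from `cfg$introgression_bed`, or empty with a logged
#'   notice.
#' @return Invisibly, a manifest list with the threshold, sweep and core
#'   `region_set`s, the genome fraction under selection, and file paths.
#' @export
run_selection_pipeline <- function(cfg, g = NULL, introgressed = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg <- utils::modifyList(pipeline_defaults(), cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- manifest_header(cfg)
  logl <- c(hdr, "pipeline: selection")
  if (is.null(g)) g <- stage("read_vcf", load_pipeline_inputs(cfg))
  pp <- cfg$pops
  if (is.null(introgressed)) {
    if (!is.null(cfg$introgression_bed)) {
      introgressed <- read_bed(cfg$introgression_bed)
    } else {
      introgressed <- region_set()
      logl <- c(logl, "notice: no introgression regions supplied; nothing excluded")
    }
  }
  windows <- make_windows(g$layout, cfg$pbs_window, cfg$pbs_step)
  pbs <- stage("pbs", pbs_windows(g, target = pp$B, control = pp$EU,
                                  outgroup = pp$AS, windows,
                                  min_sites = cfg$pbs_min_sites,
                                  log_base = cfg$log_base))
  write_window_tsv(pbs, file.path(cfg$out_dir, "pbs.tsv"), hdr)
  sw <- stage("call_sweeps", call_sweeps(pbs, introgressed, cfg$pbs_top))
  frac <- genome_fraction(sw$sweeps, g$layout)
  jsonlite::write_json(list(header = hdr, threshold = sw$threshold,
                            genome_fraction = frac,
                            n_regions = nrow(sw$sweeps)),
                       file.path(cfg$out_dir, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  write_bed(sw$sweeps, file.path(cfg$out_dir, "sweeps.bed"), header = hdr)
  core <- NULL
  if (!is.null(cfg$ld_blocks)) {
    core <- stage("ld_overlap",
                  overlap_with_ld_blocks(sw$sweeps, read_bed(cfg$ld_blocks)))
    write_bed(core, file.path(cfg$out_dir, "core_regions.bed"), header = hdr)
    logl <- c(logl, sprintf("core regions: %d", nrow(core)))
  } else {
    logl <- c(logl, "notice: no LD-block BED configured; core-region stage skipped")
  }
  logl <- c(logl,
            sprintf("params: pbs_window=%s pbs_step=%s pbs_top=%s pbs_min_sites=%s log_base=%s",
                    cfg$pbs_window, cfg$pbs_step, cfg$pbs_top,
                    cfg$pbs_min_sites, format(cfg$log_base)),
            sprintf("threshold=%.6f sweeps=%d genome_fraction=%.6f",
                    sw$threshold, nrow(sw$sweeps), frac))
  writeLines(logl, file.path(cfg$out_dir, "log.txt"))
  invisible(list(threshold = sw$threshold, sweeps = sw$sweeps, core = core,
                 genome_fraction = frac,
                 files = c(pbs = file.path(cfg$out_dir, "pbs.tsv"),
                           threshold = file.path(cfg$out_dir, "threshold.json"),
                           sweeps = file.path(cfg$out_dir, "sweeps.bed"),
                           log = file.path(cfg$out_dir, "log.txt"))))
}
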