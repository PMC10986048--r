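#' Construct a genotype matrix of phased or unphased biallelic SNPs
#'
#' The substrate of every statistic in the package: haplotype alleles coded
#' 0 (REF), 1 (ALT), `NA` (missing) at biallelic SNPs, with a population
#' label per sample.  Diploid samples occupy two adjacent haplotype columns
#' named `<sample>_1` / `<sample>_2`.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; positions must be strictly increasing within a chromosome.
#' @param haps integer matrix, sites x haplotypes, values in `{0, 1, NA}`;
#'   two columns per sample in sample order.
#' @param samples character vector of sample names.
#' @param popmap named character vector mapping every sample to exactly one
#'   population label.
#' @param phased logical per sample: whether its two haplotype columns carry
#'   real phase (TRUE for simulator output).
#' @param layout optional [genome_layout()] carried along for window/bin
#'   construction.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, haps, samples, popmap,
                            phased = rep(TRUE, length(samples)),
                            layout = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(haps), nrow(haps) == nrow(sites),
            ncol(haps) == 2L * length(samples))
  if (!all(samples %in% names(popmap))) {
    missing <- setdiff(samples, names(popmap))
    stop("samples missing from popmap: ", paste(missing, collapse = ", "))
  }
  sites$pos <- as.numeric(sites$pos)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  haps <- haps[ord, , drop = FALSE]
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", ch)
  }
  rownames(sites) <- NULL
  colnames(haps) <- paste(rep(samples, each = 2), 1:2, sep = "_")
  structure(list(sites = sites, haps = haps, samples = samples,
                 popmap = popmap[samples],
                 phased = stats::setNames(phased, samples),
                 layout = layout),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$popmap)
  cat("genotype_matrix:", nrow(x$sites), "biallelic SNPs,",
      length(x$samples), "samples\n  populations:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# column indices of the haplotypes belonging to a population
pop_hap_idx <- function(g, pop) {
  s <- which(g$popmap == pop)
  if (!length(s)) stop("unknown or empty population: ", pop)
  sort(c(2L * s - 1L, 2L * s))
}

pop_samples <- function(g, pop) g$samples[g$popmap == pop]

#' Read a sample-to-population map
#'
#' @param path TSV with two columns: sample, population (no header).
#' @return Named character vector, sample -> population.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "population"))
  if (anyDuplicated(df$sample)) stop("duplicate samples in popmap: ", path)
  stats::setNames(df$population, df$sample)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Multi-allelic and non-SNP records are dropped (the count is reported via
#' a message).  Per-sample phasing is recorded from the genotype separator.
#'
#' @param path VCF path (plain or bgzipped) with GT fields.
#' @param popmap path to a popmap TSV, or a named character vector as
#'   returned by [read_popmap()].
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, popmap) {
  if (is.character(popmap) && length(popmap) == 1 && file.exists(popmap)) {
    popmap <- read_popmap(popmap)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  keep[is.na(keep)] <- FALSE
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("read_vcf: dropped ", n_drop, " multi-allelic/non-SNP record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  vcf_samples <- colnames(gt)
  unmapped <- setdiff(vcf_samples, names(popmap))
  if (length(unmapped)) {
    stop("VCF sample(s) absent from popmap: ", paste(unmapped, collapse = ", "))
  }
  if (!length(vcf_samples)) stop("no samples shared between VCF and popmap")
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.numeric(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  haps <- matrix(NA_integer_, nrow(sites), 2L * length(vcf_samples))
  phased <- logical(length(vcf_samples))
  for (i in seq_along(vcf_samples)) {
    col <- gt[, i]
    has_sep <- grepl("[/|]", col)
    a1 <- ifelse(has_sep, sub("^([^/|]*)[/|].*$", "\\1", col), col)
    a2 <- ifelse(has_sep, sub("^[^/|]*[/|]([^/|]*).*$", "\\1", col),
                 NA_character_)
    a1[a1 %in% c(".", "") | is.na(a1)] <- NA
    a2[a2 %in% c(".", "") | is.na(a2)] <- NA
    haps[, 2L * i - 1L] <- suppressWarnings(as.integer(a1))
    haps[, 2L * i] <- suppressWarnings(as.integer(a2))
    nonmiss <- col[!is.na(col) & col != "." & has_sep]
    phased[i] <- length(nonmiss) > 0 && all(grepl("|", nonmiss, fixed = TRUE))
  }
  layout <- NULL
  contigs <- grep("^##contig=", v@meta, value = TRUE)
  if (length(contigs)) {
    id <- sub('.*[<,]ID=([^,>]+).*', "\\1", contigs)
    len <- suppressWarnings(as.numeric(sub('.*[<,]length=([0-9]+).*', "\\1",
                                           contigs)))
    if (!anyNA(len)) layout <- genome_layout(id, len)
  }
  genotype_matrix(sites, haps, vcf_samples, popmap, phased, layout = layout)
}

#' Write a genotype matrix as a (gzipped) VCF
#'
#' @param g a [genotype_matrix()].
#' @param path output path; `.vcf.gz` is appended sense-preserving by the
#'   writer, so pass a name ending in `.vcf.gz`.
#' @return `path`, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_vcf <- function(g, path) {
  n <- nrow(g$sites)
  meta <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(g$layout)) {
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>", g$layout$chrom,
                            as.integer(g$layout$length)))
  }
  fix <- cbind(CHROM = g$sites$chrom,
               POS = format(g$sites$pos, scientific = FALSE, trim = TRUE),
               ID = ".", REF = g$sites$ref, ALT = g$sites$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gtcols <- matrix("", n, length(g$samples),
                   dimnames = list(NULL, g$samples))
  for (i in seq_along(g$samples)) {
    sep <- if (g$phased[i]) "|" else "/"
    a1 <- g$haps[, 2L * i - 1L]; a2 <- g$haps[, 2L * i]
    gtcols[, i] <- paste(ifelse(is.na(a1), ".", a1),
                         ifelse(is.na(a2), ".", a2), sep = sep)
  }
  gt <- cbind(FORMAT = rep("GT", n), gtcols)
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Write a popmap TSV
#'
#' @param popmap named character vector, sample -> population.
#' @param path output path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(data.frame(names(popmap), unname(popmap)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
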