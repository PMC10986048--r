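ibd_segment_set <- function(sample1, sample2, chrom, start, end) {
  df <- data.frame(sample1 = as.character(sample1),
                   sample2 = as.character(sample2),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (nrow(df) && (any(df$start >= df$end) || any(df$sample1 == df$sample2))) {
    stop("IBD segments need start < end and distinct samples")
  }
  class(df) <- c("ibd_segments", "data.frame")
  df
}

#' Naive exact-identity IBD detector
#'
#' A desk-scale stand-in for an HMM-based IBD caller: maximal runs of
#' exact allele identity between cross-population haplotype pairs,
#' reported per sample pair (overlapping segments from different
#' haplotype combinations are unioned) when their genomic span reaches
#' `min_len`.  Missing alleles break a run.
#'
#' @param g a phased [genotype_matrix()].
#' @param popA,popB population labels.
#' @param min_len minimum segment span in bp (default 100 kb).
#' @return An `ibd_segments` data frame: `sample1`, `sample2`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @export
naive_ibd <- function(g, popA, popB, min_len = 1e5) {
  sa <- pop_samples(g, popA); sb <- pop_samples(g, popB)
  if (!all(g$phased[c(sa, sb)])) stop("naive_ibd requires phased haplotypes")
  out <- vector("list", 0)
  for (ch in unique(g$sites$chrom)) {
    rows <- which(g$sites$chrom == ch)
    pos <- g$sites$pos[rows]
    H <- g$haps[rows, , drop = FALSE]
    has_na <- anyNA(H)
    for (s1 in sa) for (s2 in sb) {
      i1 <- 2L * match(s1, g$samples) - 1L
      i2 <- 2L * match(s2, g$samples) - 1L
      segs <- NULL
      n <- length(pos)
      for (c1 in c(i1, i1 + 1L)) for (c2 in c(i2, i2 + 1L)) {
        a <- H[, c1]; b <- H[, c2]
        # identity runs = maximal stretches between mismatches (missing
        # alleles break a run)
        mism <- if (has_na) which(a != b | is.na(a) | is.na(b)) else
          which(a != b)
        mism <- c(0L, mism, n + 1L)
        gap <- which(diff(mism) >= 2L)
        if (!length(gap)) next
        s0 <- pos[mism[gap] + 1L] - 1
        e0 <- pos[mism[gap + 1L] - 1L]
        keep <- (e0 - s0) >= min_len
        if (any(keep)) {
          segs <- rbind(segs, data.frame(start = s0[keep], end = e0[keep]))
        }
      }
      if (!is.null(segs)) {
        m <- merge_regions(region_set(rep(ch, nrow(segs)), segs$start,
                                      segs$end), 0)
        out[[length(out) + 1L]] <-
          data.frame(sample1 = s1, sample2 = s2, chrom = m$chrom,
                     start = m$start, end = m$end, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(ibd_segment_set(character(), character(),
                                           character(), numeric(), numeric()))
  df <- do.call(rbind, out)
  ibd_segment_set(df$sample1, df$sample2, df$chrom, df$start, df$end)
}

#' Read IBD segments from TSV
#'
#' @param path TSV with header `sample1 sample2 chrom start end`.
#' @param one_based set TRUE for 1-based closed input intervals (they are
#'   converted to the package's 0-based half-open convention).
#' @return An `ibd_segments` data frame.
#' @export
read_ibd_segments <- function(path, one_based = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (one_based) df$start <- df$start - 1
  ibd_segment_set(df$sample1, df$sample2, df$chrom, df$start, df$end)
}

#' Write IBD segments as TSV
#' @param segs an `ibd_segments` data frame.
#' @param path output path.
#' @export
write_ibd_segments <- function(segs, path) {
  utils::write.table(segs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binned IBD-sharing contrast (nIBD / rIBD / ZrIBD)
#'
#' The genome is cut into fixed bins; in each bin, `cIBD` is the number of
#' cross-population sample pairs with any IBD segment overlapping the bin
#' (a pair counts once per bin), `tIBD` the total number of pairs, and
#' `nIBD = cIBD / tIBD`.  `rIBD = nIBD_EU - nIBD_AS` contrasts sharing
#' with the two competing populations, and `ZrIBD` standardizes rIBD by
#' its genome-wide mean and standard deviation over all bins.
#'
#' @param segs_EU IBD segments between the target and the EU-side
#'   population; `segs_AS` likewise for the AS side.
#' @param n_B,n_EU,n_AS sample counts of the target and the two
#'   populations (`tIBD = n_B * n_other`).
#' @param layout a [genome_layout()].
#' @param bin bin size in bp (default 10 kb).
#' @return A `window_table` of bins with columns `cIBD_EU`, `nIBD_EU`,
#'   `cIBD_AS`, `nIBD_AS`, `rIBD`, `ZrIBD`.
#' @export
ribd_bins <- function(segs_EU, segs_AS, n_B, n_EU, n_AS, layout, bin = 1e4) {
  bins <- make_windows(layout, bin, bin)
  if (nrow(bins) == 0) stop("zero bins")
  count_pairs <- function(segs) {
    cnt <- numeric(nrow(bins))
    if (nrow(segs) == 0) return(cnt)
    # bin row offsets per chromosome (bins are 0-anchored, fixed-size)
    off <- stats::setNames(match(layout$chrom, bins$chrom) - 1L, layout$chrom)
    nb <- stats::setNames(tabulate(factor(bins$chrom, layout$chrom)),
                          layout$chrom)
    key <- paste(segs$sample1, segs$sample2)
    for (pair in unique(key)) {
      ps <- segs[key == pair, , drop = FALSE]
      hit <- integer(0)
      for (r in seq_len(nrow(ps))) {
        ch <- ps$chrom[r]
        if (!ch %in% layout$chrom) next
        b0 <- ps$start[r] %/% bin
        b1 <- min((ps$end[r] - 1) %/% bin, nb[[ch]] - 1L)
        if (b1 >= b0) hit <- c(hit, off[[ch]] + b0:b1 + 1L)
      }
      hit <- unique(hit)
      cnt[hit] <- cnt[hit] + 1
    }
    cnt
  }
  c_eu <- count_pairs(segs_EU)
  c_as <- count_pairs(segs_AS)
  n_eu <- c_eu / (n_B * n_EU)
  n_as <- c_as / (n_B * n_AS)
  ribd <- n_eu - n_as
  s <- stats::sd(ribd)
  if (!is.finite(s) || s == 0) {
    stop("rIBD has zero variance genome-wide; ZrIBD undefined")
  }
  z <- (ribd - mean(ribd)) / s
  as_window_table(bins, data.frame(cIBD_EU = c_eu, nIBD_EU = n_eu,
                                   cIBD_AS = c_as, nIBD_AS = n_as,
                                   rIBD = ribd, ZrIBD = z))
}

#' Call EU-like (ancestor-shared) haplotype regions from rIBD bins
#'
#' Bins with `ZrIBD > z_sd` and `nIBD_EU > nibd_min` are intersected with
#' the high-EU-ancestry windows (bins outside them are excluded) and
#' merged with gap 0.
#'
#' @param bins a `window_table` from [ribd_bins()].
#' @param ancestry_high_EU `region_set` of bottom-tail (EU-excess)
#'   ancestry windows.
#' @param z_sd ZrIBD threshold in standard deviations (default 2).
#' @param nibd_min minimum nIBD with the EU-side population (default 0.80).
#' @return A `region_set` tagged `"yorkshire_like"`.
#' @export
call_yorkshire_like <- function(bins, ancestry_high_EU, z_sd = 2,
                                nibd_min = 0.80) {
  sel <- which(bins$ZrIBD > z_sd & bins$nIBD_EU > nibd_min)
  if (!length(sel)) return(region_set())
  cand <- region_set(bins$chrom[sel], bins$start[sel], bins$end[sel])
  merge_regions(intersect_regions(cand, ancestry_high_EU,
                                  tag = "yorkshire_like"), 0)
}
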