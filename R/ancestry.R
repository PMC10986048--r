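#' Naive chunk-wise ancestry painter
#'
#' A deliberately simple local-ancestry stand-in for desk-scale work: in
#' each genomic chunk, every target haplotype is labelled by the reference
#' panel containing its minimum-Hamming-distance haplotype (0 = `panelA`,
#' 1 = `panelB`); exact ties between the panels leave the chunk
#' unassigned.  Production local-ancestry output (a 0/1 site-by-haplotype
#' matrix) can be supplied instead via [read_ancestry_matrix()].
#'
#' @param g a phased [genotype_matrix()].
#' @param panelA,panelB reference population labels (label 0 and 1).
#' @param target population whose haplotypes are painted.
#' @param chunk chunk length in bp (default 50 kb).
#' @return An `ancestry_matrix`: list with `labels` (sites x target
#'   haplotypes, values 0/1/NA), `sites`, `haplotypes`.
#' @export
naive_paint <- function(g, panelA = "EU", panelB = "AS", target = "B",
                        chunk = 50000) {
  ta <- pop_hap_idx(g, target)
  pa <- pop_hap_idx(g, panelA)
  pb <- pop_hap_idx(g, panelB)
  if (!length(pa) || !length(pb)) stop("empty reference panel")
  labels <- matrix(NA_real_, nrow(g$sites), length(ta))
  for (ch in unique(g$sites$chrom)) {
    rows_ch <- which(g$sites$chrom == ch)
    cidx <- (g$sites$pos[rows_ch] - 1) %/% chunk
    for (ci in unique(cidx)) {
      rows <- rows_ch[cidx == ci]
      X <- g$haps[rows, ta, drop = FALSE]
      A <- g$haps[rows, pa, drop = FALSE]
      B <- g$haps[rows, pb, drop = FALSE]
      # missing alleles -> 0.5: contributes equally to every comparison
      X[is.na(X)] <- 0.5; A[is.na(A)] <- 0.5; B[is.na(B)] <- 0.5
      dA <- crossprod(X, 1 - A) + crossprod(1 - X, A)  # target x panelA
      dB <- crossprod(X, 1 - B) + crossprod(1 - X, B)
      mA <- apply(dA, 1, min); mB <- apply(dB, 1, min)
      lab <- ifelse(mA < mB, 0, ifelse(mB < mA, 1, NA))
      labels[rows, ] <- matrix(lab, length(rows), length(ta), byrow = TRUE)
    }
  }
  structure(list(labels = labels,
                 sites = g$sites[, c("chrom", "pos")],
                 haplotypes = colnames(g$haps)[ta]),
            class = "ancestry_matrix")
}

#' Read a site-by-haplotype ancestry label matrix
#'
#' @param path TSV with columns `chrom`, `pos`, then one 0/1 column per
#'   target haplotype (header row with haplotype ids; empty cells or `NA`
#'   mean unassigned).
#' @return An `ancestry_matrix`.
#' @export
read_ancestry_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(df)))
  hapcols <- setdiff(names(df), c("chrom", "pos"))
  labels <- as.matrix(df[hapcols])
  storage.mode(labels) <- "numeric"
  if (!all(labels %in% c(0, 1) | is.na(labels))) {
    stop("ancestry labels must be 0, 1 or missing")
  }
  structure(list(labels = labels,
                 sites = df[, c("chrom", "pos")], haplotypes = hapcols),
            class = "ancestry_matrix")
}

#' Write an ancestry matrix as TSV
#'
#' @param a an `ancestry_matrix`.
#' @param path output path.
#' @export
write_ancestry_matrix <- function(a, path) {
  df <- cbind(a$sites, as.data.frame(a$labels))
  names(df) <- c("chrom", "pos", a$haplotypes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-window donor-ancestry fractions
#'
#' For each non-overlapping window, the fraction of assigned
#' (site x haplotype) cells labelled 1 (donor ancestry); unassigned cells
#' are excluded from numerator and denominator.
#'
#' @param a an `ancestry_matrix`.
#' @param windows a non-overlapping `region_set` of windows.
#' @return A `window_table` with columns `n_assigned` (assigned cells) and
#'   `ancestry` (fraction labelled 1, `NA` if no cell assigned).
#' @export
ancestry_window_fractions <- function(a, windows) {
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)])) {
      stop("windows must be non-overlapping")
    }
  }
  ones <- rowSums(a$labels == 1, na.rm = TRUE)
  assigned <- rowSums(!is.na(a$labels))
  S <- window_sums(a$sites, windows, cbind(ones = ones, assigned = assigned))
  frac <- ifelse(S[, "assigned"] > 0, S[, "ones"] / S[, "assigned"], NA)
  as_window_table(windows, data.frame(n_assigned = S[, "assigned"],
                                      ancestry = frac))
}

#' Call top and bottom ancestry windows
#'
#' The top tail of the empirical window-ancestry distribution (excess of
#' donor, label-1, ancestry) and the bottom tail (excess of label-0
#' ancestry), each holding `ceiling(tail * n)` non-missing windows before
#' merging; ties are broken by genomic order (earlier window wins).
#'
#' @param wt a `window_table` from [ancestry_window_fractions()].
#' @param tail tail mass in `(0, 0.5]` (default 0.05).
#' @return List with `region_set`s `high_donor` (top tail, tag
#'   `"high_AS_ancestry"`) and `high_other` (bottom tail, tag
#'   `"high_EU_ancestry"`).
#' @export
top_bottom_ancestry <- function(wt, tail = 0.05) {
  if (tail <= 0 || tail > 0.5) stop("tail must be in (0, 0.5]")
  ok <- which(!is.na(wt$ancestry))
  if (!length(ok)) stop("no windows with assigned ancestry")
  k <- ceiling(tail * length(ok))
  top <- ok[order(-wt$ancestry[ok], seq_along(ok))][seq_len(k)]
  bot <- ok[order(wt$ancestry[ok], seq_along(ok))][seq_len(k)]
  mk <- function(idx, tag) {
    merge_regions(region_set(wt$chrom[idx], wt$start[idx], wt$end[idx], tag), 0)
  }
  list(high_donor = mk(top, "high_AS_ancestry"),
       high_other = mk(bot, "high_EU_ancestry"))
}
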