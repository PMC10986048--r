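#' Per-site allele counts for a set of populations
#'
#' Counts use only non-missing haplotype alleles.  A site is flagged
#' unusable when any requested population has fewer than `min_alleles`
#' called alleles there.
#'
#' @param g a [genotype_matrix()].
#' @param pops character vector of population labels present in `g`.
#' @param min_alleles minimum called alleles per population for a site to
#'   be usable (default 2).
#' @return A list of class `site_freqs`: matrices `alt` (ALT allele count)
#'   and `called` (called allele count), one column per population, plus a
#'   logical vector `usable`.
#' @export
site_frequencies <- function(g, pops, min_alleles = 2) {
  unknown <- setdiff(pops, unique(g$popmap))
  if (length(unknown)) stop("unknown population(s): ", paste(unknown, collapse = ", "))
  alt <- called <- matrix(0, nrow(g$sites), length(pops),
                          dimnames = list(NULL, pops))
  for (p in pops) {
    h <- g$haps[, pop_hap_idx(g, p), drop = FALSE]
    alt[, p] <- rowSums(h == 1L, na.rm = TRUE)
    called[, p] <- rowSums(!is.na(h))
  }
  usable <- rowSums(called < min_alleles) == 0
  structure(list(alt = alt, called = called, usable = usable,
                 min_alleles = min_alleles), class = "site_freqs")
}

# per-window column sums of X (sites x k, NA not allowed) over half-open
# windows, via cumulative sums and findInterval on 0-based site positions
window_sums <- function(sites, windows, X) {
  X <- as.matrix(X)
  out <- matrix(0, nrow(windows), ncol(X), dimnames = list(NULL, colnames(X)))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(sites$chrom == ch)
    if (!length(si)) next
    pos0 <- sites$pos[si] - 1
    cs <- apply(X[si, , drop = FALSE], 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
    cs <- rbind(0, cs)
    hi <- findInterval(windows$end[wi] - 1, pos0) + 1L
    lo <- findInterval(windows$start[wi] - 1, pos0) + 1L
    out[wi, ] <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  out
}

as_window_table <- function(windows, df) {
  out <- cbind(data.frame(chrom = windows$chrom, start = windows$start,
                          end = windows$end, stringsAsFactors = FALSE), df)
  class(out) <- c("window_table", "data.frame")
  out
}

#' @export
print.window_table <- function(x, ...) {
  cat("window_table:", nrow(x), "windows\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

# Weir & Cockerham (1984) per-site variance components for two populations
# of diploids.  Returns a (among-population), abc (total) and a usable flag
# (>= 2 called diploids in each population).
wc_site_components <- function(g, popA, popB) {
  comp_pop <- function(pop) {
    idx <- pop_hap_idx(g, pop)
    h1 <- g$haps[, idx[seq(1, length(idx), 2)], drop = FALSE]
    h2 <- g$haps[, idx[seq(2, length(idx), 2)], drop = FALSE]
    dose <- h1 + h2                       # NA if either haplotype missing
    het <- (h1 != h2)
    n <- rowSums(!is.na(dose))
    list(n = n,
         p = ifelse(n > 0, rowSums(dose, na.rm = TRUE) / (2 * n), NA),
         h = ifelse(n > 0, rowSums(het & !is.na(dose), na.rm = TRUE) / n, NA))
  }
  x <- comp_pop(popA); y <- comp_pop(popB)
  n1 <- x$n; n2 <- y$n
  usable <- n1 >= 2 & n2 >= 2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * x$p + n2 * y$p) / (2 * nbar)
  s2 <- (n1 * (x$p - pbar)^2 + n2 * (y$p - pbar)^2) / nbar   # r - 1 = 1
  hbar <- (n1 * x$h + n2 * y$h) / (2 * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!usable] <- 0
  abc <- a + b + cc
  abc[!usable] <- 0
  list(a = a, abc = abc, usable = usable)
}

#' Windowed Weir-Cockerham Fst
#'
#' Weir & Cockerham's (1984) variance components are accumulated per
#' window and combined as a ratio of sums (the "weighted" estimator used
#' by VCFtools); window values may be negative.  Sites need at least two
#' called diploid samples in each population.
#'
#' @param g a [genotype_matrix()].
#' @param popA,popB distinct population labels.
#' @param windows a `region_set` of windows, e.g. from [make_windows()].
#' @param min_sites windows with fewer usable sites get `NA` (default 10).
#' @return A `window_table` with columns `n_sites` and `fst`.
#' @export
fst_windows <- function(g, popA, popB, windows, min_sites = 10) {
  if (identical(popA, popB)) stop("popA and popB must differ")
  comp <- wc_site_components(g, popA, popB)
  S <- window_sums(g$sites, windows,
                   cbind(a = comp$a, abc = comp$abc, n = as.numeric(comp$usable)))
  fst <- ifelse(S[, "n"] >= min_sites & S[, "abc"] != 0,
                S[, "a"] / S[, "abc"], NA)
  as_window_table(windows, data.frame(n_sites = S[, "n"], fst = fst))
}

#' Genome-wide Weir-Cockerham Fst
#'
#' Ratio of summed variance components over all usable sites.
#'
#' @inheritParams fst_windows
#' @return A single numeric value.
#' @export
fst_global <- function(g, popA, popB) {
  if (identical(popA, popB)) stop("popA and popB must differ")
  comp <- wc_site_components(g, popA, popB)
  sum(comp$a) / sum(comp$abc)
}

#' Windowed nucleotide divergence d_xy
#'
#' The mean number of differences per site between haplotypes drawn from
#' two populations: per site `p_x (1 - p_y) + (1 - p_x) p_y`, summed over
#' usable sites.  This equals the exhaustive average over all
#' cross-population haplotype pairs.
#'
#' @param g a [genotype_matrix()].
#' @param popX,popY population labels.
#' @param windows a `region_set` of windows.
#' @param denominator `"per_used_site"` (default) divides by the usable
#'   site count; `"per_bp"` divides by window length.
#' @param min_sites windows with fewer usable sites get `NA`.
#' @param min_alleles minimum called alleles per population per site.
#' @return A `window_table` with columns `n_sites` and `dxy`.
#' @export
dxy_windows <- function(g, popX, popY, windows,
                        denominator = c("per_used_site", "per_bp"),
                        min_sites = 10, min_alleles = 2) {
  denominator <- match.arg(denominator)
  fr <- site_frequencies(g, unique(c(popX, popY)), min_alleles)
  px <- fr$alt[, popX] / fr$called[, popX]
  py <- fr$alt[, popY] / fr$called[, popY]
  val <- px * (1 - py) + (1 - px) * py
  val[!fr$usable] <- 0
  S <- window_sums(g$sites, windows,
                   cbind(v = val, n = as.numeric(fr$usable)))
  den <- if (denominator == "per_used_site") S[, "n"] else
    (windows$end - windows$start)
  dxy <- ifelse(S[, "n"] >= min_sites & den > 0, S[, "v"] / den, NA)
  as_window_table(windows, data.frame(n_sites = S[, "n"], dxy = dxy))
}

#' Fraction of windows closer to one population than another
#'
#' Given two windowed d_xy tables over identical windows (target vs donor
#' candidate, target vs other ancestor), the fraction of windows - among
#' those non-missing in both - where the first d_xy is strictly lower.
#' Ties count as not-lower.
#'
#' @param dxy_a,dxy_b `window_table`s from [dxy_windows()] on identical
#'   windows.
#' @return A proportion in `[0, 1]`.
#' @export
dxy_preference_fraction <- function(dxy_a, dxy_b) {
  if (!identical(dxy_a[c("chrom", "start", "end")],
                 dxy_b[c("chrom", "start", "end")])) {
    stop("window lists differ between the two d_xy tables")
  }
  ok <- !is.na(dxy_a$dxy) & !is.na(dxy_b$dxy)
  if (!any(ok)) stop("no windows with d_xy defined in both tables")
  mean(dxy_a$dxy[ok] < dxy_b$dxy[ok])
}
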