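#' Specify the four-taxon quartet for ABBA-BABA statistics
#'
#' Roles follow the topology `((P1, P2), P3, O)`: a significantly negative
#' D indicates gene flow between P2 and P3, positive between P1 and P3.
#' In the admixed-breed design P1 is the European ancestor panel, P2 the
#' target breed, P3 the Asian donor candidate and O the outgroup.
#'
#' @param P1,P2,P3,O four distinct population labels.
#' @return An object of class `quartet_spec`.
#' @export
quartet_spec <- function(P1 = "EU", P2 = "B", P3 = "AS", O = "O") {
  pops <- c(P1 = P1, P2 = P2, P3 = P3, O = O)
  if (anyDuplicated(pops)) stop("quartet populations must be distinct")
  structure(as.list(pops), class = "quartet_spec")
}

# Per-site derived-allele frequencies polarized by the outgroup major
# allele.  Sites are unusable when any population has < min_alleles called
# alleles, the outgroup is uncalled, or the derived allele exceeds
# `outgroup_max_derived` in the outgroup.
polarized_freqs <- function(g, q, min_alleles = 2, outgroup_max_derived = 0.1) {
  stopifnot(inherits(q, "quartet_spec"))
  pops <- unlist(q)
  fr <- site_frequencies(g, pops, min_alleles)
  p_alt <- fr$alt / fr$called       # NaN where called == 0
  anc_is_alt <- !is.na(p_alt[, q$O]) & p_alt[, q$O] > 0.5
  derived <- p_alt
  derived[anc_is_alt, ] <- 1 - p_alt[anc_is_alt, , drop = FALSE]
  usable <- fr$usable & fr$called[, q$O] > 0 &
    !is.na(derived[, q$O]) & derived[, q$O] <= outgroup_max_derived
  list(p1 = derived[, q$P1], p2 = derived[, q$P2], p3 = derived[, q$P3],
       pO = derived[, q$O], usable = usable)
}

# ABBA and BABA pattern weights from population derived-allele frequencies
abba_baba <- function(p1, p2, p3, pO) {
  list(abba = (1 - p1) * p2 * p3 * (1 - pO),
       baba = p1 * (1 - p2) * p3 * (1 - pO))
}

#' Genome-wide Patterson's D with weighted block-jackknife Z
#'
#' D = sum(BABA - ABBA) / sum(BABA + ABBA) over usable polarized sites,
#' with pattern weights from population derived-allele frequencies - the
#' qpDstat orientation, in which a significantly positive D indicates
#' gene flow between P1 and P3 and a significantly negative D gene flow
#' between P2 and P3.  The standard error comes from a weighted
#' delete-one block jackknife over contiguous genomic blocks, weighting
#' blocks by their informative-site counts.
#'
#' @param g a [genotype_matrix()].
#' @param quartet a [quartet_spec()].
#' @param block_size jackknife block length in bp (default 5 Mb).
#' @param min_alleles,outgroup_max_derived site-inclusion rules; sites
#'   where the outgroup carries the derived allele at frequency above
#'   `outgroup_max_derived` are excluded.
#' @return An object of class `dstat`: list with `D`, `Z`, `se`,
#'   `n_blocks`, `n_sites` (informative sites).
#' @export
d_statistic <- function(g, quartet, block_size = 5e6, min_alleles = 2,
                        outgroup_max_derived = 0.1) {
  pf <- polarized_freqs(g, quartet, min_alleles, outgroup_max_derived)
  w <- abba_baba(pf$p1, pf$p2, pf$p3, pf$pO)
  num <- w$baba - w$abba
  den <- w$abba + w$baba
  num[!pf$usable] <- 0; den[!pf$usable] <- 0
  informative <- pf$usable & den > 0
  block <- paste(g$sites$chrom, (g$sites$pos - 1) %/% block_size)
  bn <- tapply(num[informative], block[informative], sum)
  bd <- tapply(den[informative], block[informative], sum)
  bm <- tapply(rep(1, sum(informative)), block[informative], sum)
  if (length(bn) < 2) stop("fewer than 2 non-empty jackknife blocks")
  tot_n <- sum(bn); tot_d <- sum(bd)
  if (tot_d == 0) stop("no ABBA/BABA informative sites")
  D <- tot_n / tot_d
  # Busing-style weighted delete-one jackknife
  theta_j <- (tot_n - bn) / (tot_d - bd)
  n <- sum(bm); B <- length(bm); h <- n / bm
  theta_J <- B * D - sum((1 - bm / n) * theta_j)
  tau <- h * D - (h - 1) * theta_j
  v <- sum((tau - theta_J)^2 / (h - 1)) / B
  if (v <= 0) {
    warning("jackknife variance is zero; Z undefined")
    Z <- NA_real_; se <- 0
  } else {
    se <- sqrt(v); Z <- D / se
  }
  structure(list(D = D, Z = Z, se = se, n_blocks = B,
                 n_sites = sum(informative)), class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f  (Z = %s, se = %.4f, %d blocks, %d informative sites)\n",
              x$D, ifelse(is.na(x$Z), "NA", sprintf("%.3f", x$Z)), x$se,
              x$n_blocks, x$n_sites))
  invisible(x)
}

#' Windowed f_d introgression fraction
#'
#' Martin-style dynamic-donor estimator: the observed ABBA-BABA excess in
#' a window divided by the excess expected were the donor frequency fully
#' transferred, where the donor at each site is whichever of P2/P3 has the
#' higher derived frequency.  Windows with fewer than `min_sites` usable
#' sites are missing; windows with window-D < 0, or window-D > 0 but raw
#' f_d > 1, are set to 0, so reported values lie in `[0, 1]`.
#'
#' @inheritParams d_statistic
#' @param windows a `region_set` of windows (50 kb in the motivating
#'   analysis).
#' @param min_sites minimum usable sites per window (default 100).
#' @return A `window_table` with columns `n_sites`, `D` and `fd`.
#' @export
fd_windows <- function(g, quartet, windows, min_sites = 100,
                       min_alleles = 2, outgroup_max_derived = 0.1) {
  pf <- polarized_freqs(g, quartet, min_alleles, outgroup_max_derived)
  w <- abba_baba(pf$p1, pf$p2, pf$p3, pf$pO)
  pd <- pmax(pf$p2, pf$p3)
  wd <- abba_baba(pf$p1, pd, pd, pf$pO)
  X <- cbind(num = w$abba - w$baba,
             den = w$abba + w$baba,
             fdden = wd$abba - wd$baba,
             n = as.numeric(pf$usable))
  X[!pf$usable, c("num", "den", "fdden")] <- 0
  S <- window_sums(g$sites, windows, X)
  Dw <- ifelse(S[, "den"] > 0, S[, "num"] / S[, "den"], NA)
  fd_raw <- ifelse(S[, "fdden"] > 0, S[, "num"] / S[, "fdden"], 0)
  # the > 1 clamp carries a floating-point guard so a complete-replacement
  # tract (raw f_d = 1 up to rounding) is not zeroed
  fd <- ifelse(is.na(Dw) | Dw < 0 | fd_raw > 1 + 1e-9, 0,
               pmin(pmax(fd_raw, 0), 1))
  low <- S[, "n"] < min_sites
  Dw[low] <- NA; fd[low] <- NA
  as_window_table(windows, data.frame(n_sites = S[, "n"], D = Dw, fd = fd))
}

#' Call introgression regions from f_d and high-ancestry windows
#'
#' Windows in the top `fd_quantile` of the non-missing f_d distribution
#' are merged (gap 0) and intersected with the high-donor-ancestry region
#' set; the intersection is the candidate introgression call.
#'
#' @param fd a `window_table` from [fd_windows()].
#' @param ancestry_top `region_set` of high donor-ancestry windows (see
#'   [top_bottom_ancestry()]).
#' @param fd_quantile fraction of non-missing windows taken as candidates
#'   (default 0.05); ties broken by genomic order.
#' @return A `region_set` tagged `"introgressed"`.
#' @export
call_introgression_regions <- function(fd, ancestry_top, fd_quantile = 0.05) {
  ok <- which(!is.na(fd$fd))
  if (!length(ok)) stop("all f_d windows are missing")
  k <- ceiling(fd_quantile * length(ok))
  top <- ok[order(-fd$fd[ok], seq_along(ok))][seq_len(k)]
  cand <- merge_regions(region_set(fd$chrom[top], fd$start[top], fd$end[top]), 0)
  intersect_regions(cand, ancestry_top, tag = "introgressed")
}
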