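# Independent brute-force oracles.  These deliberately re-derive each
# quantity from first principles (per-base boolean arrays, explicit loops
# over haplotype pairs, literal formula transcription per site) and never
# call the package's own vectorized paths.

# random small genotype matrix; pops get 0/1 haplotypes with optional NAs
random_gm <- function(n_sites = 40, n_per_pop = 4, pops = c("B", "EU"),
                      chrom_len = 4000, miss = 0.05) {
  samples <- unlist(lapply(pops, function(p) paste0(p, seq_len(n_per_pop))))
  popmap <- stats::setNames(rep(pops, each = n_per_pop), samples)
  pos <- sort(sample.int(chrom_len, n_sites))
  haps <- matrix(rbinom(n_sites * 2 * length(samples), 1, runif(n_sites)),
                 nrow = n_sites)
  if (miss > 0) haps[runif(length(haps)) < miss] <- NA
  sites <- data.frame(chrom = "c1", pos = pos, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, haps, samples, popmap,
                  layout = genome_layout("c1", chrom_len))
}

# per-base boolean membership of a region set over a small genome
region_bool <- function(rs, len) {
  v <- rep(FALSE, len)
  for (i in seq_len(nrow(rs))) {
    if (rs$end[i] > rs$start[i]) v[(rs$start[i] + 1):rs$end[i]] <- TRUE
  }
  v
}

random_regions <- function(n, len, max_w = 60) {
  s <- sample.int(len - 1, n, replace = TRUE) - 1
  e <- pmin(s + sample.int(max_w, n, replace = TRUE), len)
  region_set(rep("c1", n), s, e)
}

# d_xy by exhaustive double loop over cross-population haplotype pairs,
# averaging per-site mismatch fractions over pairs with both alleles called
oracle_dxy_persite <- function(g, popX, popY) {
  ix <- admixscan:::pop_hap_idx(g, popX)
  iy <- admixscan:::pop_hap_idx(g, popY)
  vapply(seq_len(nrow(g$sites)), function(s) {
    tot <- 0; n <- 0
    for (a in ix) for (b in iy) {
      xa <- g$haps[s, a]; xb <- g$haps[s, b]
      if (!is.na(xa) && !is.na(xb)) { tot <- tot + (xa != xb); n <- n + 1 }
    }
    if (n == 0) NA_real_ else tot / n
  }, numeric(1))
}

# Weir & Cockerham (1984) two-population components, transcribed per site
# with explicit scalar arithmetic
oracle_wc_site <- function(g, popA, popB, s) {
  one_pop <- function(pop) {
    idx <- which(g$popmap == pop)
    doses <- het <- c()
    for (i in idx) {
      h1 <- g$haps[s, 2 * i - 1]; h2 <- g$haps[s, 2 * i]
      if (!is.na(h1) && !is.na(h2)) {
        doses <- c(doses, h1 + h2); het <- c(het, h1 != h2)
      }
    }
    list(n = length(doses),
         p = if (length(doses)) sum(doses) / (2 * length(doses)) else NA,
         h = if (length(doses)) mean(het) else NA)
  }
  x <- one_pop(popA); y <- one_pop(popB)
  if (x$n < 2 || y$n < 2) return(c(a = 0, abc = 0, usable = 0))
  r <- 2
  nbar <- (x$n + y$n) / r
  nc <- (r * nbar - (x$n^2 + y$n^2) / (r * nbar)) / (r - 1)
  pbar <- (x$n * x$p + y$n * y$p) / (r * nbar)
  s2 <- (x$n * (x$p - pbar)^2 + y$n * (y$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (x$n * x$h + y$n * y$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, abc = a + b + cc, usable = 1)
}

# derived-allele frequencies and ABBA/BABA sums for one window, by a
# direct per-site loop (independent of polarized_freqs/window_sums)
oracle_fd_window <- function(g, q, w_start, w_end, outgroup_max_derived = 0.1) {
  num <- den <- fdden <- 0; n_used <- 0
  for (s in seq_len(nrow(g$sites))) {
    p0 <- g$sites$pos[s] - 1
    if (p0 < w_start || p0 >= w_end) next
    freq <- function(pop) {
      h <- g$haps[s, admixscan:::pop_hap_idx(g, pop)]
      h <- h[!is.na(h)]
      if (length(h) == 0) return(c(NA, 0))
      c(mean(h), length(h))
    }
    fO <- freq(q$O)
    if (fO[2] == 0) next
    ok <- TRUE
    for (pop in c(q$P1, q$P2, q$P3, q$O)) if (freq(pop)[2] < 2) ok <- FALSE
    if (!ok) next
    anc_alt <- fO[1] > 0.5
    dfreq <- function(pop) {
      f <- freq(pop)[1]; if (anc_alt) 1 - f else f
    }
    if (dfreq(q$O) > outgroup_max_derived) next
    n_used <- n_used + 1
    p1 <- dfreq(q$P1); p2 <- dfreq(q$P2); p3 <- dfreq(q$P3); pO <- dfreq(q$O)
    abba <- (1 - p1) * p2 * p3 * (1 - pO)
    baba <- p1 * (1 - p2) * p3 * (1 - pO)
    pd <- max(p2, p3)
    abba_d <- (1 - p1) * pd * pd * (1 - pO)
    baba_d <- p1 * (1 - pd) * pd * (1 - pO)
    num <- num + (abba - baba)
    den <- den + (abba + baba)
    fdden <- fdden + (abba_d - baba_d)
  }
  list(num = num, den = den, fdden = fdden, n = n_used)
}

# bin-wise count of sample pairs with an overlapping IBD segment, by a
# per-base boolean array per pair
oracle_ribd_counts <- function(segs, layout, bin) {
  bins <- make_windows(layout, bin, bin)
  cnt <- numeric(nrow(bins))
  pairs <- unique(paste(segs$sample1, segs$sample2, sep = "\r"))
  for (pr in pairs) {
    parts <- strsplit(pr, "\r", fixed = TRUE)[[1]]
    ss <- segs[segs$sample1 == parts[1] & segs$sample2 == parts[2], ]
    for (bi in seq_len(nrow(bins))) {
      hit <- FALSE
      for (r in seq_len(nrow(ss))) {
        if (ss$chrom[r] == bins$chrom[bi] &&
            ss$start[r] < bins$end[bi] && ss$end[r] > bins$start[bi]) {
          hit <- TRUE; break
        }
      }
      if (hit) cnt[bi] <- cnt[bi] + 1
    }
  }
  cnt
}
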