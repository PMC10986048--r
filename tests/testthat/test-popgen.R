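test_that("site frequencies count alleles and flag thin sites", {
  sites <- data.frame(chrom = "c1", pos = c(10, 20), ref = "A", alt = "G")
  # two diploid B samples: 0/0 and 0/1 at site 1; all-missing at site 2
  haps <- matrix(c(0L, 0L, 0L, 1L,
                   NA, NA, NA, NA), nrow = 2, byrow = TRUE)
  g <- genotype_matrix(sites, haps, c("s1", "s2"),
                       c(s1 = "B", s2 = "B"))
  fr <- site_frequencies(g, "B")
  expect_equal(unname(fr$alt[, "B"]), c(1, 0))
  expect_equal(unname(fr$called[, "B"]), c(4, 0))
  expect_equal(fr$usable, c(TRUE, FALSE))
  expect_error(site_frequencies(g, "nope"), "unknown")
})

test_that("site frequencies match a per-site loop on random matrices", {
  set.seed(5)
  for (i in 1:20) {
    g <- random_gm(n_sites = 25, n_per_pop = 3, miss = 0.15)
    fr <- site_frequencies(g, c("B", "EU"))
    for (pop in c("B", "EU")) {
      idx <- admixscan:::pop_hap_idx(g, pop)
      for (s in seq_len(nrow(g$sites))) {
        h <- g$haps[s, idx]
        expect_equal(unname(fr$alt[s, pop]), sum(h == 1, na.rm = TRUE))
        expect_equal(unname(fr$called[s, pop]), sum(!is.na(h)))
      }
    }
  }
})

test_that("windowed W&C Fst equals the independently coded oracle", {
  set.seed(11)
  for (i in 1:30) {
    g <- random_gm(n_sites = 30, n_per_pop = 4, miss = 0.1)
    w <- make_windows(g$layout, 2000, 2000)
    fst <- fst_windows(g, "B", "EU", w, min_sites = 1)
    comp <- t(vapply(seq_len(nrow(g$sites)),
                     function(s) oracle_wc_site(g, "B", "EU", s),
                     numeric(3)))
    for (k in seq_len(nrow(w))) {
      inw <- g$sites$pos - 1 >= w$start[k] & g$sites$pos - 1 < w$end[k]
      n_used <- sum(comp[inw, "usable"])
      if (n_used >= 1 && sum(comp[inw, "abc"]) != 0) {
        expect_equal(fst$fst[k],
                     sum(comp[inw, "a"]) / sum(comp[inw, "abc"]))
      } else {
        expect_true(is.na(fst$fst[k]))
      }
    }
  }
})

test_that("Fst hits its analytic extremes", {
  sites <- data.frame(chrom = "c1", pos = seq(10, 100, 10), ref = "A",
                      alt = "G")
  n <- length(sites$pos)
  # popA fixed REF, popB fixed ALT at every site
  haps <- cbind(matrix(0L, n, 8), matrix(1L, n, 8))
  samples <- paste0("s", 1:8)
  g <- genotype_matrix(sites, haps, samples,
                       stats::setNames(rep(c("A", "B"), each = 4), samples))
  fst <- fst_windows(g, "A", "B", make_windows(genome_layout("c1", 100), 100),
                     min_sites = 1)
  expect_equal(fst$fst, 1)
  expect_error(fst_windows(g, "A", "A", make_windows(genome_layout("c1", 100),
                                                     100)), "differ")
  # two pseudo-populations drawn from one pool stay near zero
  set.seed(3)
  m <- 1000
  pool <- matrix(rbinom(m * 200, 1, rep(runif(m, 0.1, 0.9), 200)), nrow = m)
  samples2 <- paste0("x", 1:100)
  g2 <- genotype_matrix(data.frame(chrom = "c1", pos = seq_len(m) * 10,
                                   ref = "A", alt = "G"),
                        pool, samples2,
                        stats::setNames(rep(c("P", "Q"), each = 50), samples2))
  f0 <- fst_windows(g2, "P", "Q",
                    make_windows(genome_layout("c1", m * 10 + 1), m * 10 + 1),
                    min_sites = 1)
  expect_lt(abs(f0$fst), 0.02)
})

test_that("d_xy equals brute-force enumeration over haplotype pairs", {
  set.seed(17)
  for (i in 1:30) {
    g <- random_gm(n_sites = 25, n_per_pop = 3, miss = 0.1)
    w <- make_windows(g$layout, 2000, 2000)
    dx <- dxy_windows(g, "B", "EU", w, min_sites = 1)
    per_site <- oracle_dxy_persite(g, "B", "EU")
    fr <- site_frequencies(g, c("B", "EU"))
    for (k in seq_len(nrow(w))) {
      inw <- which(g$sites$pos - 1 >= w$start[k] &
                     g$sites$pos - 1 < w$end[k] & fr$usable)
      if (length(inw) >= 1) {
        expect_equal(dx$dxy[k], mean(per_site[inw]))
      } else {
        expect_true(is.na(dx$dxy[k]))
      }
    }
    # symmetry
    dyx <- dxy_windows(g, "EU", "B", w, min_sites = 1)
    expect_identical(dx$dxy, dyx$dxy)
  }
})

test_that("d_xy analytic cases and per-bp mode behave", {
  sites <- data.frame(chrom = "c1", pos = c(50), ref = "A", alt = "G")
  samples <- paste0("s", 1:4)
  pm <- stats::setNames(rep(c("X", "Y"), each = 2), samples)
  g01 <- genotype_matrix(sites, matrix(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), 1),
                         samples, pm)
  w <- make_windows(genome_layout("c1", 100), 100)
  expect_equal(dxy_windows(g01, "X", "Y", w, min_sites = 1)$dxy, 1)
  expect_equal(dxy_windows(g01, "X", "Y", w, denominator = "per_bp",
                           min_sites = 1)$dxy, 1 / 100)
  gmono <- genotype_matrix(sites, matrix(0L, 1, 8), paste0("m", 1:4),
                           stats::setNames(rep(c("X", "Y"), each = 2),
                                           paste0("m", 1:4)))
  expect_equal(dxy_windows(gmono, "X", "Y", w, min_sites = 1)$dxy, 0)
})

test_that("d_xy preference is 0.5 under symmetry and rises with gene flow", {
  sim0 <- null_sim()
  wins <- make_windows(sim0$genotypes$layout, 2.5e5, 2.5e5)
  da0 <- dxy_windows(sim0$genotypes, "B", "AS", wins)
  de0 <- dxy_windows(sim0$genotypes, "B", "EU", wins)
  pref0 <- dxy_preference_fraction(da0, de0)
  expect_gt(pref0, 0.3)
  expect_lt(pref0, 0.7)
  # planted AS->B tracts pull d_xy(B,AS) below d_xy(B,EU)
  simi <- recovery_sim()
  winsi <- make_windows(simi$genotypes$layout, 2.5e5, 2.5e5)
  dai <- dxy_windows(simi$genotypes, "B", "AS", winsi)
  dei <- dxy_windows(simi$genotypes, "B", "EU", winsi)
  prefi <- dxy_preference_fraction(dai, dei)
  expect_gt(prefi, pref0)
  expect_error(dxy_preference_fraction(da0, dei), "differ")
})
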