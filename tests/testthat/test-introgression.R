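# build a 4-population matrix from per-population allele-dose patterns:
# each row of `freqs` gives the fixed allele (0/1) per population
pattern_gm <- function(freqs, n_per_pop = 2, spacing = 1000) {
  pops <- c("EU", "B", "AS", "O")   # P1, P2, P3, O
  samples <- unlist(lapply(pops, function(p) paste0(p, seq_len(n_per_pop))))
  popmap <- stats::setNames(rep(pops, each = n_per_pop), samples)
  n <- nrow(freqs)
  haps <- matrix(0L, n, 2 * length(samples))
  for (j in seq_along(pops)) {
    cols <- (j - 1) * 2 * n_per_pop + seq_len(2 * n_per_pop)
    haps[, cols] <- matrix(rep(freqs[, pops[j]], length(cols)), n)
  }
  sites <- data.frame(chrom = "c1", pos = seq_len(n) * spacing, ref = "A",
                      alt = "G")
  genotype_matrix(sites, haps, samples, popmap,
                  layout = genome_layout("c1", (n + 1) * spacing))
}

test_that("D hits 0 and +/-1 on pattern-pure inputs", {
  # equal ABBA and BABA weight -> D = 0
  bal <- pattern_gm(data.frame(EU = c(1, 0), B = c(0, 1), AS = c(1, 1),
                               O = c(0, 0)))
  d0 <- d_statistic(bal, quartet_spec(), block_size = 1000)
  expect_equal(d0$D, 0)
  # BABA only (P1 shares derived with P3) -> D = +1
  baba <- pattern_gm(data.frame(EU = c(1, 1), B = c(0, 0), AS = c(1, 1),
                                O = c(0, 0)))
  expect_equal(suppressWarnings(d_statistic(baba, quartet_spec(), block_size = 1000))$D, 1)
  # ABBA only (P2 shares derived with P3) -> D = -1: the orientation in
  # which donor-into-target gene flow is negative
  abba <- pattern_gm(data.frame(EU = c(0, 0), B = c(1, 1), AS = c(1, 1),
                                O = c(0, 0)))
  expect_equal(suppressWarnings(d_statistic(abba, quartet_spec(), block_size = 1000))$D, -1)
})

test_that("jackknife degenerates loudly, never silently", {
  one_block <- pattern_gm(data.frame(EU = 1, B = 0, AS = 1, O = 0))
  expect_error(d_statistic(one_block, quartet_spec(), block_size = 1e6),
               "blocks")
  # identical blocks -> zero variance -> warned NA
  same <- pattern_gm(data.frame(EU = c(1, 1), B = c(0, 0), AS = c(1, 1),
                                O = c(0, 0)))
  expect_warning(d <- d_statistic(same, quartet_spec(), block_size = 1000),
                 "variance")
  expect_true(is.na(d$Z))
})

test_that("D is antisymmetric in P1/P2 and ignores sample order", {
  sim <- null_sim()
  g <- sim$genotypes
  d12 <- d_statistic(g, quartet_spec(P1 = "EU", P2 = "B"), block_size = 5e5)
  d21 <- d_statistic(g, quartet_spec(P1 = "B", P2 = "EU"), block_size = 5e5)
  expect_equal(d12$D, -d21$D)
  expect_equal(d12$se, d21$se)
  # permuting samples within a population leaves D unchanged
  ord <- order(match(g$popmap, c("B", "EU", "AS", "O")),
               rev(seq_along(g$samples)))
  hap_cols <- as.vector(rbind(2L * ord - 1L, 2L * ord))
  g2 <- genotype_matrix(g$sites, g$haps[, hap_cols], g$samples[ord],
                        g$popmap[ord], layout = g$layout)
  expect_equal(d_statistic(g2, quartet_spec(), block_size = 5e5)$D, d12$D)
})

test_that("f_d windows reproduce a per-site pattern-sum recomputation", {
  set.seed(23)
  for (i in 1:15) {
    g <- random_gm(n_sites = 30, n_per_pop = 3,
                   pops = c("EU", "B", "AS", "O"), miss = 0.08)
    w <- make_windows(g$layout, 2000, 2000)
    fd <- fd_windows(g, quartet_spec(), w, min_sites = 1)
    for (k in seq_len(nrow(w))) {
      o <- oracle_fd_window(g, quartet_spec(), w$start[k], w$end[k])
      expect_equal(fd$n_sites[k], o$n)
      if (o$n < 1) {
        expect_true(is.na(fd$fd[k]))
      } else {
        expect_equal(fd$D[k],
                     if (o$den > 0) o$num / o$den else NA_real_)
        raw <- if (o$fdden > 0) o$num / o$fdden else 0
        dw <- if (o$den > 0) o$num / o$den else NA
        exp_fd <- if (is.na(dw) || dw < 0 || raw > 1 + 1e-9) 0 else
          min(max(raw, 0), 1)
        expect_equal(fd$fd[k], exp_fd)
      }
    }
    ok <- !is.na(fd$fd)
    expect_true(all(fd$fd[ok] >= 0 & fd$fd[ok] <= 1))
  }
})

test_that("f_d clamping rules apply: negative-D windows and thin windows", {
  # window dominated by BABA -> window D < 0 -> f_d = 0
  baba <- pattern_gm(data.frame(EU = c(1, 1), B = c(0, 0), AS = c(1, 1),
                                O = c(0, 0)))
  w <- make_windows(baba$layout, 3000, 3000)
  fd <- fd_windows(baba, quartet_spec(), w, min_sites = 1)
  expect_equal(fd$fd[1], 0)
  # 99 usable sites under a 100-site floor -> missing
  g99 <- pattern_gm(data.frame(EU = rep(c(0, 1), length.out = 99),
                               B = rep(c(1, 0), length.out = 99),
                               AS = 1, O = 0), spacing = 10)
  w99 <- make_windows(g99$layout, 1e4, 1e4)
  fd99 <- fd_windows(g99, quartet_spec(), w99, min_sites = 100)
  expect_true(all(is.na(fd99$fd)))
  expect_equal(fd99$n_sites[1], 99)
})

test_that("a fully replaced donor tract gives f_d near one", {
  cfg <- sim_config(genome_layout("c1", 2e6), snp_density = 0.005,
                    n_samples = c(B = 20, EU = 20, AS = 20, O = 6),
                    introgression = data.frame(chrom = "c1", start = 5e5,
                                               end = 1e6, f = 1.0),
                    seed = 8)
  sim <- simulate_cohort(cfg)
  w <- make_windows(sim$genotypes$layout, 5e4, 5e4)
  fd <- fd_windows(sim$genotypes, quartet_spec(), w)
  tract <- w$start >= 5e5 & w$end <= 1e6
  expect_true(all(abs(fd$fd[tract] - 1) <= 0.15))
})

test_that("introgression calling combines the f_d and ancestry gates", {
  fd <- recovery_fd()
  lay <- recovery_sim()$genotypes$layout
  expect_equal(nrow(call_introgression_regions(fd, region_set(), 0.1)), 0)
  whole <- region_set(lay$chrom, c(0, 0), as.numeric(lay$length))
  all_called <- call_introgression_regions(fd, whole, 1.0)
  expect_equal(covered_bp(all_called),
               covered_bp(merge_regions(as_region_set(fd[!is.na(fd$fd), ]), 0)))
  fd_na <- fd; fd_na$fd <- NA_real_
  expect_error(call_introgression_regions(fd_na, whole, 0.05), "missing")
})
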