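test_that("verbatim donor copies are painted as donor ancestry", {
  cfg <- sim_config(genome_layout("c1", 4e5), snp_density = 0.004,
                    n_samples = c(B = 6, EU = 8, AS = 8, O = 2),
                    introgression = data.frame(chrom = "c1", start = 1e5,
                                               end = 3e5, f = 1.0),
                    seed = 14)
  sim <- simulate_cohort(cfg)
  paint <- naive_paint(sim$genotypes)
  rows <- which(sim$genotypes$sites$pos - 1 >= 1e5 &
                  sim$genotypes$sites$pos - 1 < 3e5)
  lab <- paint$labels[rows, ]
  expect_gte(mean(lab == 1, na.rm = TRUE), 0.99)
  expect_error(naive_paint(sim$genotypes, panelA = "NOPE"), "population")
})

test_that("exactly equidistant chunks are left unassigned", {
  # target haplotype differs from each panel's single haplotype at one site
  sites <- data.frame(chrom = "c1", pos = c(100, 200), ref = "A", alt = "G")
  haps <- cbind(c(0L, 0L),          # B hap1
                c(0L, 0L),          # B hap2
                c(1L, 0L), c(1L, 0L),   # EU sample
                c(0L, 1L), c(0L, 1L))   # AS sample
  samples <- c("b1", "e1", "a1")
  g <- genotype_matrix(sites, haps, samples,
                       c(b1 = "B", e1 = "EU", a1 = "AS"))
  paint <- naive_paint(g, chunk = 1000)
  expect_true(all(is.na(paint$labels)))
})

test_that("painter is equivariant under panel haplotype order", {
  g <- random_gm(n_sites = 40, n_per_pop = 3, pops = c("B", "EU", "AS"),
                 miss = 0)
  p1 <- naive_paint(g, chunk = 1000)
  # reverse sample order within the panels
  ord <- order(match(g$popmap, c("B", "EU", "AS")),
               rev(seq_along(g$samples)))
  hap_cols <- as.vector(rbind(2L * ord - 1L, 2L * ord))
  g2 <- genotype_matrix(g$sites, g$haps[, hap_cols], g$samples[ord],
                        g$popmap[ord], layout = g$layout)
  p2 <- naive_paint(g2, chunk = 1000)
  expect_identical(p1$labels,
                   p2$labels[, match(p1$haplotypes, p2$haplotypes)])
})

test_that("window fractions equal a cell-count loop and respect bounds", {
  set.seed(33)
  for (i in 1:10) {
    n <- 60
    labels <- matrix(sample(c(0, 1, NA), n * 6, replace = TRUE,
                            prob = c(0.4, 0.4, 0.2)), n, 6)
    a <- structure(list(labels = labels,
                        sites = data.frame(chrom = "c1",
                                           pos = sort(sample.int(6000, n))),
                        haplotypes = paste0("h", 1:6)),
                   class = "ancestry_matrix")
    w <- make_windows(genome_layout("c1", 6000), 1500, 1500)
    wt <- ancestry_window_fractions(a, w)
    for (k in seq_len(nrow(w))) {
      rows <- which(a$sites$pos - 1 >= w$start[k] & a$sites$pos - 1 < w$end[k])
      cells <- labels[rows, ]
      if (sum(!is.na(cells)) == 0) {
        expect_true(is.na(wt$ancestry[k]))
      } else {
        expect_equal(wt$ancestry[k],
                     sum(cells == 1, na.rm = TRUE) / sum(!is.na(cells)))
      }
    }
    ok <- !is.na(wt$ancestry)
    expect_true(all(wt$ancestry[ok] >= 0 & wt$ancestry[ok] <= 1))
  }
  # all cells 1 / half-half analytic cases
  a1 <- structure(list(labels = matrix(1, 4, 2),
                       sites = data.frame(chrom = "c1", pos = c(10, 20, 30, 40)),
                       haplotypes = c("h1", "h2")), class = "ancestry_matrix")
  w <- make_windows(genome_layout("c1", 50), 50, 50)
  expect_equal(ancestry_window_fractions(a1, w)$ancestry, 1)
  a1$labels <- matrix(c(0, 1), 4, 2)
  expect_equal(ancestry_window_fractions(a1, w)$ancestry, 0.5)
  expect_error(ancestry_window_fractions(a1, make_windows(
    genome_layout("c1", 50), 40, 20)), "non-overlapping")
})

test_that("top/bottom tails take the right windows deterministically", {
  wt <- structure(data.frame(chrom = "c1", start = (0:99) * 100,
                             end = (1:100) * 100, n_assigned = 10,
                             ancestry = (1:100) / 100),
                  class = c("window_table", "data.frame"))
  tails <- top_bottom_ancestry(wt, 0.05)
  expect_equal(tails$high_donor$start, 9500)  # windows ranked 96..100 merge
  expect_equal(tails$high_donor$end, 10000)
  expect_equal(tails$high_other$start, 0)
  expect_equal(tails$high_other$end, 500)
  # constant fractions: ties broken by genomic order
  wt$ancestry <- 0.5
  tc <- top_bottom_ancestry(wt, 0.05)
  expect_equal(covered_bp(tc$high_donor), 500)
  expect_equal(tc$high_donor$start, 0)
  expect_error(top_bottom_ancestry(wt, 0.6), "tail")
  expect_error(top_bottom_ancestry(wt, 0), "tail")
})

test_that("ancestry matrices round-trip through TSV", {
  labels <- matrix(c(0, 1, NA, 1), 2, 2)
  a <- structure(list(labels = labels,
                      sites = data.frame(chrom = "c1", pos = c(10, 20)),
                      haplotypes = c("s1_1", "s1_2")),
                 class = "ancestry_matrix")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ancestry_matrix(a, f)
  b <- read_ancestry_matrix(f)
  expect_equal(unname(b$labels), unname(labels))
  expect_equal(b$haplotypes, a$haplotypes)
})
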