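#' Classify a 4-taxon gene tree by its rooted ingroup topology
#'
#' Rooting at the outgroup `O`, the ingroup cherry determines the class:
#' topology I = `((B,EU),AS)` (matches the species tree), II = `((B,AS),EU)`,
#' III = `((EU,AS),B)`.  Polytomies are `"unresolved"`.  Branch lengths,
#' rotations and label order in the newick string are irrelevant.
#'
#' @param newick a newick string (or an `ape` `phylo` object) whose tip
#'   labels are exactly `B`, `EU`, `AS`, `O`.
#' @param labels optional named character vector remapping tip labels,
#'   e.g. `c(B = "BBP", EU = "YY", AS = "SX", O = "WB")`.
#' @return One of `"I"`, `"II"`, `"III"`, `"unresolved"`.
#' @export
classify_tree <- function(newick, labels = c(B = "B", EU = "EU",
                                             AS = "AS", O = "O")) {
  tr <- if (inherits(newick, "phylo")) newick else
    ape::read.tree(text = newick)
  if (is.null(tr)) stop("could not parse newick string")
  want <- unname(labels)
  if (length(tr$tip.label) != 4 || anyDuplicated(tr$tip.label) ||
      !setequal(tr$tip.label, want)) {
    stop("tree must carry exactly the four tip labels: ",
         paste(want, collapse = ", "))
  }
  # map external labels back to canonical B/EU/AS/O
  tr$tip.label <- names(labels)[match(tr$tip.label, want)]
  tr <- ape::unroot(tr)
  if (tr$Nnode < 2) return("unresolved")
  o_tip <- which(tr$tip.label == "O")
  parent <- tr$edge[tr$edge[, 2] == o_tip, 1]
  sibs <- tr$edge[tr$edge[, 1] == parent, 2]
  tip_sibs <- setdiff(sibs[sibs <= 4], o_tip)
  if (length(tip_sibs) != 1) return("unresolved")
  switch(tr$tip.label[tip_sibs], AS = "I", EU = "II", B = "III")
}

#' Filter gene records by SNP support
#'
#' Genes with fewer than `min_snps` SNPs are removed (default keeps genes
#' with more than ten SNPs, the conventional floor for per-gene trees).
#'
#' @param records data frame with an `n_snps` column.
#' @param min_snps minimum SNPs to keep a gene (default 11).
#' @return The filtered data frame.
#' @export
filter_genes <- function(records, min_snps = 11) {
  stopifnot("n_snps" %in% names(records))
  records[!is.na(records$n_snps) & records$n_snps >= min_snps, , drop = FALSE]
}

#' Census of gene-tree topology classes
#'
#' @param newicks character vector of newick strings (or a data frame with
#'   a `newick` column, e.g. from [simulate_gene_trees()] or
#'   [read_gene_trees()]).
#' @param labels tip-label mapping passed to [classify_tree()].
#' @return An object of class `topology_census`: counts `n_I`, `n_II`,
#'   `n_III`, `n_unresolved` and `total`.
#' @export
topology_census <- function(newicks, labels = c(B = "B", EU = "EU",
                                                AS = "AS", O = "O")) {
  if (is.data.frame(newicks)) newicks <- newicks$newick
  cls <- vapply(newicks, classify_tree, character(1), labels = labels,
                USE.NAMES = FALSE)
  structure(list(n_I = sum(cls == "I"), n_II = sum(cls == "II"),
                 n_III = sum(cls == "III"),
                 n_unresolved = sum(cls == "unresolved"),
                 total = length(cls)), class = "topology_census")
}

#' @export
print.topology_census <- function(x, ...) {
  cat(sprintf(
    "topology census: I=%d  II=%d  III=%d  unresolved=%d  (total %d)\n",
    x$n_I, x$n_II, x$n_III, x$n_unresolved, x$total))
  invisible(x)
}

#' Read gene trees and per-gene SNP counts
#'
#' @param newick_path file with one newick tree per line.
#' @param snp_counts_path optional TSV with header `gene`, `n_snps`
#'   (one row per tree, same order).
#' @return Data frame with `gene`, `newick` and (if supplied) `n_snps`.
#' @export
read_gene_trees <- function(newick_path, snp_counts_path = NULL) {
  lines <- readLines(newick_path)
  lines <- lines[nzchar(trimws(lines))]
  df <- data.frame(gene = sprintf("gene_%05d", seq_along(lines)),
                   newick = lines, stringsAsFactors = FALSE)
  if (!is.null(snp_counts_path)) {
    sc <- utils::read.table(snp_counts_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (nrow(sc) != nrow(df)) stop("SNP-count table and tree file differ in length")
    df$gene <- sc$gene
    df$n_snps <- sc$n_snps
  }
  df
}

#' Test equality of the two discordant topology classes
#'
#' Under pure incomplete lineage sorting the two minor topologies are
#' equally frequent; a 1-df goodness-of-fit chi-square of `(n_II, n_III)`
#' against a 50:50 split tests that.
#'
#' @param census a [topology_census()].
#' @return List with `chi2` and two-sided `p`.
#' @export
minor_topology_equality_test <- function(census) {
  n <- c(census$n_II, census$n_III)
  if (sum(n) == 0) stop("no discordant trees to test")
  ht <- suppressWarnings(stats::chisq.test(n, p = c(0.5, 0.5)))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Test the observed minor-topology ratio against an ILS-only null
#'
#' The species-tree internal branch is calibrated from the concordant
#' fraction (`t_hat = -log(1.5 * (1 - n_I / total))`, coalescent units),
#' `n_reps` censuses of the same size are simulated under the
#' multispecies-coalescent law at `t_hat`, and the simulated
#' `n_III / n_II` ratios are compared with the observed ratio by a
#' one-sample t test and by a two-sided empirical tail probability.
#'
#' @param census a [topology_census()] with concordant fraction in
#'   (1/3, 1).
#' @param n_reps simulated censuses (default 1000).
#' @param seed optional integer seed.
#' @return An object of class `ils_test`: `observed_ratio`, `t_hat`,
#'   `ratios` (simulated), `p_t`, `p_empirical`, `n_reps`.
#' @export
ils_ratio_test <- function(census, n_reps = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- census$n_I + census$n_II + census$n_III
  conc <- census$n_I / total
  if (conc <= 1 / 3 || conc >= 1) {
    stop("concordant fraction must lie in (1/3, 1) to calibrate the branch")
  }
  if (census$n_II == 0) stop("observed ratio undefined (n_II = 0)")
  t_hat <- -log(1.5 * (1 - conc))
  p_disc <- (1 - conc) / 2
  draws <- stats::rmultinom(n_reps, total, c(1 - 2 * p_disc, p_disc, p_disc))
  ratios <- draws[3, ] / draws[2, ]
  ratios <- ratios[is.finite(ratios)]
  obs <- census$n_III / census$n_II
  p_t <- stats::t.test(ratios, mu = obs)$p.value
  k <- length(ratios)
  p_emp <- min(1, 2 * min((1 + sum(ratios <= obs)) / (k + 1),
                          (1 + sum(ratios >= obs)) / (k + 1)))
  structure(list(observed_ratio = obs, t_hat = t_hat, ratios = ratios,
                 p_t = p_t, p_empirical = p_emp, n_reps = n_reps),
            class = "ils_test")
}

#' @export
print.ils_test <- function(x, ...) {
  cat(sprintf(
    "ILS ratio test: observed III/II = %.4f, t_hat = %.3f, simulated mean = %.4f\n  p (t test) = %.3g, p (empirical two-sided) = %.3g  [%d reps]\n",
    x$observed_ratio, x$t_hat, mean(x$ratios), x$p_t, x$p_empirical,
    x$n_reps))
  invisible(x)
}
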