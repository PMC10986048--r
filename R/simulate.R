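#' Configuration for a simulated admixture cohort
#'
#' Describes a cohort of four populations drifted from a common ancestor
#' under the Balding-Nichols model: the admixed target breed `B`, its two
#' ancestor panels `EU` and `AS`, and an outgroup `O` kept nearly
#' monomorphic for the ancestral allele so that outgroup polarization of
#' derived alleles is well defined.  Optional planted structure: donor
#' tracts copied from `AS` into `B` haplotypes (introgression), allele
#' frequency shifts private to `B` (sweeps), and literally identical
#' haplotypes between designated `B`/`EU` samples (IBD sharing).
#'
#' @param layout a [genome_layout()].
#' @param snp_density expected SNPs per bp (default 0.001 = 1 per kb).
#' @param n_samples named integer vector with entries `B`, `EU`, `AS`, `O`.
#' @param F_drift named numeric vector (`B`, `EU`, `AS`) of per-population
#'   Balding-Nichols divergence parameters in (0, 1).
#' @param F_outgroup Balding-Nichols parameter for the outgroup's own
#'   frequency draw around `outgroup_derived_mean`.
#' @param outgroup_derived_mean mean derived-allele frequency in the
#'   outgroup (small, so the outgroup carries the ancestral allele).
#' @param introgression data frame `chrom,start,end,f`: tracts where a
#'   fraction `f` of `B` haplotypes is replaced by copies of random `AS`
#'   haplotypes.
#' @param sweeps data frame `chrom,start,end,delta`: tracts where `B`'s
#'   derived-allele frequency is shifted by `delta` toward the locally
#'   major allele (truncated to `[0, 1]`) before haplotypes are drawn.
#' @param ibd data frame `chrom,start,end`: tracts where designated
#'   `B`/`EU` sample pairs receive literally identical haplotype copies.
#' @param ibd_pairs data frame `sampleB,sampleEU` of designated pairs, or
#'   `NULL` for all `B` x `EU` pairs (a single shared tract haplotype).
#' @param seed integer seed; all randomness flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(layout,
                       snp_density = 0.001,
                       n_samples = c(B = 20, EU = 20, AS = 20, O = 6),
                       F_drift = c(B = 0.15, EU = 0.15, AS = 0.15),
                       F_outgroup = 0.8,
                       outgroup_derived_mean = 0.02,
                       introgression = NULL,
                       sweeps = NULL,
                       ibd = NULL,
                       ibd_pairs = NULL,
                       seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"),
            snp_density > 0,
            all(c("B", "EU", "AS", "O") %in% names(n_samples)),
            all(n_samples >= 1),
            all(c("B", "EU", "AS") %in% names(F_drift)),
            all(F_drift > 0 & F_drift < 1),
            F_outgroup > 0, F_outgroup < 1,
            outgroup_derived_mean > 0, outgroup_derived_mean < 0.5)
  check_tracts <- function(tr, extra = NULL) {
    if (is.null(tr) || nrow(tr) == 0) return(NULL)
    stopifnot(all(c("chrom", "start", "end", extra) %in% names(tr)))
    genome_fraction(region_set(tr$chrom, tr$start, tr$end), layout)  # bounds
    tr
  }
  introgression <- check_tracts(introgression, "f")
  sweeps <- check_tracts(sweeps, "delta")
  ibd <- check_tracts(ibd)
  if (!is.null(introgression)) {
    stopifnot(all(introgression$f >= 0 & introgression$f <= 1))
  }
  if (!is.null(sweeps)) stopifnot(all(sweeps$delta > 0 & sweeps$delta <= 1))
  # the downstream pipeline treats sweeps and introgression as exclusive
  if (!is.null(introgression) && !is.null(sweeps)) {
    ov <- intersect_regions(as_region_set(introgression), as_region_set(sweeps))
    if (nrow(ov) > 0) stop("sweep tracts overlap introgression tracts")
  }
  structure(list(layout = layout, snp_density = snp_density,
                 n_samples = n_samples, F_drift = F_drift,
                 F_outgroup = F_outgroup,
                 outgroup_derived_mean = outgroup_derived_mean,
                 introgression = introgression, sweeps = sweeps,
                 ibd = ibd, ibd_pairs = ibd_pairs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# rows of `sites` falling inside tract [start,end) on tract$chrom (0-based)
tract_rows <- function(sites, chrom, start, end) {
  which(sites$chrom == chrom & sites$pos - 1 >= start & sites$pos - 1 < end)
}

#' Simulate a phased cohort with planted truth
#'
#' Per site an ancestral derived-allele frequency is drawn uniformly on
#' (0.05, 0.95); each ingroup population's frequency is a Balding-Nichols
#' beta draw with that mean and its own F; the outgroup's frequency is a
#' Balding-Nichols draw around a small mean so it carries the ancestral
#' allele.  Haplotypes are sampled binomially (sites independent), then the
#' planted tracts are stamped in: sweeps shift `B`'s frequency before
#' sampling, introgression replaces `B` haplotypes with copies of `AS`
#' haplotypes, and IBD tracts fix one shared `EU` ancestor haplotype on
#' both chromosomes of every designated sample, so each designated pair
#' carries literally identical copies.  The same seed reproduces the
#' cohort exactly.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `genotypes` (a phased [genotype_matrix()])
#'   and `truth` (class `sim_truth`: region sets `introgression` and
#'   `sweeps`, data frame `ibd_segments`, and `ancestral` = "ref",
#'   recording that the REF allele is ancestral at every site).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lay <- cfg$layout
  ns <- cfg$n_samples
  samples <- c(sprintf("B_%02d", seq_len(ns[["B"]])),
               sprintf("EU_%02d", seq_len(ns[["EU"]])),
               sprintf("AS_%02d", seq_len(ns[["AS"]])),
               sprintf("O_%02d", seq_len(ns[["O"]])))
  popmap <- stats::setNames(rep(c("B", "EU", "AS", "O"), times = ns[c("B", "EU", "AS", "O")]),
                            samples)

  site_list <- list(); hap_list <- list()
  for (ch in lay$chrom) {
    len <- lay$length[[ch]]
    n <- max(1L, round(len * cfg$snp_density))
    pos <- sort(sample.int(len, n))
    p_anc <- stats::runif(n, 0.05, 0.95)
    bn <- function(mu, F) {
      stats::rbeta(n, mu * (1 - F) / F, (1 - mu) * (1 - F) / F)
    }
    p <- list(B = bn(p_anc, cfg$F_drift[["B"]]),
              EU = bn(p_anc, cfg$F_drift[["EU"]]),
              AS = bn(p_anc, cfg$F_drift[["AS"]]),
              O = bn(rep(cfg$outgroup_derived_mean, n), cfg$F_outgroup))
    sites <- data.frame(chrom = ch, pos = pos, ref = "A", alt = "G",
                        stringsAsFactors = FALSE)
    # sweep tracts shift B's frequency toward its locally major allele
    if (!is.null(cfg$sweeps)) {
      for (k in seq_len(nrow(cfg$sweeps))) {
        tr <- cfg$sweeps[k, ]
        rows <- tract_rows(sites, tr$chrom, tr$start, tr$end)
        if (!length(rows)) next
        up <- p$B[rows] >= 0.5
        p$B[rows] <- pmin(1, pmax(0, p$B[rows] + ifelse(up, tr$delta, -tr$delta)))
      }
    }
    draw <- function(freq, n_hap) {
      matrix(stats::rbinom(length(freq) * n_hap, 1L, rep(freq, n_hap)),
             ncol = n_hap)
    }
    H <- cbind(draw(p$B, 2L * ns[["B"]]), draw(p$EU, 2L * ns[["EU"]]),
               draw(p$AS, 2L * ns[["AS"]]), draw(p$O, 2L * ns[["O"]]))
    site_list[[ch]] <- sites
    hap_list[[ch]] <- H
  }
  sites <- do.call(rbind, site_list)
  haps <- do.call(rbind, hap_list)
  rownames(sites) <- NULL

  b_cols <- seq_len(2L * ns[["B"]])
  eu_cols <- 2L * ns[["B"]] + seq_len(2L * ns[["EU"]])
  as_cols <- 2L * (ns[["B"]] + ns[["EU"]]) + seq_len(2L * ns[["AS"]])

  # introgression: replace a fraction f of B haplotypes by AS copies
  if (!is.null(cfg$introgression)) {
    for (k in seq_len(nrow(cfg$introgression))) {
      tr <- cfg$introgression[k, ]
      rows <- tract_rows(sites, tr$chrom, tr$start, tr$end)
      if (!length(rows)) next
      n_repl <- round(tr$f * length(b_cols))
      if (n_repl == 0) next
      recip <- sample(b_cols, n_repl)
      # distinct donor haplotypes when the panel allows: full replacement
      # then reproduces the donor panel's allele frequencies exactly
      donor <- sample(as_cols, n_repl, replace = n_repl > length(as_cols))
      haps[rows, recip] <- haps[rows, donor]
    }
  }

  # IBD tracts: copy one EU template haplotype into each designated pair
  ibd_truth <- data.frame(sample1 = character(), sample2 = character(),
                          chrom = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE)
  if (!is.null(cfg$ibd)) {
    b_names <- samples[popmap == "B"]; eu_names <- samples[popmap == "EU"]
    pairs <- cfg$ibd_pairs
    if (is.null(pairs)) {
      pairs <- expand.grid(sampleB = b_names, sampleEU = eu_names,
                           stringsAsFactors = FALSE)
    }
    hap1_col <- function(sample) 2L * match(sample, samples) - 1L
    for (k in seq_len(nrow(cfg$ibd))) {
      tr <- cfg$ibd[k, ]
      rows <- tract_rows(sites, tr$chrom, tr$start, tr$end)
      if (!length(rows)) next
      # one shared ancestor haplotype, fixed (both chromosomes) in every
      # designated sample: mirrors near-complete pairwise sharing
      template <- haps[rows, hap1_col(pairs$sampleEU[1])]
      for (s in unique(c(pairs$sampleB, pairs$sampleEU))) {
        haps[rows, hap1_col(s)] <- template
        haps[rows, hap1_col(s) + 1L] <- template
      }
      ibd_truth <- rbind(ibd_truth,
                         data.frame(sample1 = pairs$sampleB,
                                    sample2 = pairs$sampleEU,
                                    chrom = tr$chrom, start = tr$start,
                                    end = tr$end, stringsAsFactors = FALSE))
    }
  }

  g <- genotype_matrix(sites, haps, samples, popmap,
                       phased = rep(TRUE, length(samples)), layout = lay)
  truth <- structure(list(
    introgression = if (is.null(cfg$introgression)) region_set() else
      as_region_set(transform(cfg$introgression, tag = "introgression_truth")),
    sweeps = if (is.null(cfg$sweeps)) region_set() else
      as_region_set(transform(cfg$sweeps, tag = "sweep_truth")),
    ibd_segments = ibd_truth,
    ancestral = "ref"), class = "sim_truth")
  list(genotypes = g, truth = truth)
}

#' Simulate 4-taxon gene-tree topologies under the multispecies coalescent
#'
#' For species tree `(((B,EU),AS),O)` with an ingroup internal branch of
#' `internal_branch_t` coalescent units, a gene tree matches the species
#' tree (topology I) with probability `1 - (2/3) exp(-t)` and shows each
#' discordant topology (II: B with AS; III: EU with AS) with probability
#' `(1/3) exp(-t)` - pure incomplete lineage sorting.
#'
#' @param n_genes number of gene trees to draw.
#' @param internal_branch_t internal branch length, coalescent units, `>= 0`.
#' @param seed optional integer seed.
#' @return Data frame with columns `gene`, `newick`, `topology`
#'   (`"I"`, `"II"`, `"III"`).
#' @export
simulate_gene_trees <- function(n_genes, internal_branch_t, seed = NULL) {
  stopifnot(internal_branch_t >= 0, n_genes >= 1)
  if (!is.null(seed)) set.seed(seed)
  p_disc <- exp(-internal_branch_t) / 3
  probs <- c(I = 1 - 2 * p_disc, II = p_disc, III = p_disc)
  topo <- sample(names(probs), n_genes, replace = TRUE, prob = probs)
  nwk <- c(I = "(((B,EU),AS),O);",
           II = "(((B,AS),EU),O);",
           III = "(((EU,AS),B),O);")[topo]
  data.frame(gene = sprintf("gene_%05d", seq_len(n_genes)),
             newick = unname(nwk), topology = topo,
             stringsAsFactors = FALSE)
}

#' Write simulator truth to plain-text files
#'
#' @param truth a `sim_truth` object from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(introgression = file.path(dir, "introgression_truth.bed"),
             sweeps = file.path(dir, "sweep_truth.bed"),
             ibd = file.path(dir, "ibd_truth.tsv"))
  write_bed(truth$introgression, paths["introgression"])
  write_bed(truth$sweeps, paths["sweeps"])
  utils::write.table(truth$ibd_segments, paths["ibd"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
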