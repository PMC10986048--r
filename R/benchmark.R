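#' Benchmark cohort configurations with planted truth
#'
#' Ready-made [sim_config()]s for the package's two standard study
#' designs, used throughout the tests, the acceptance script and the
#' vignette:
#'
#' * `"null"` - a tract-free cohort for statistical calibration: 2
#'   chromosomes of 5 Mb, 1 SNP/kb, 20 samples per ingroup population
#'   plus 6 outgroup samples.  Genome-wide D is centred on zero here.
#' * `"recovery"` - a scaled-down twin of an admixed-breed analysis: 2
#'   chromosomes of 10 Mb, 1 SNP/200 bp (so 50-kb windows comfortably
#'   clear the 100-informative-site floor), 30 samples per ingroup
#'   population, with planted AS-into-B introgression tracts (8 tracts of
#'   250 kb, haplotype fraction f = 0.8, 10 percent of the genome),
#'   sweeps private to B (2 tracts of 500 kb, frequency shift 0.4,
#'   5 percent of the genome, matching a top-5 percent scan), and
#'   B/EU shared-haplotype (IBD) tracts (2 tracts of 200 kb shared by
#'   all B x EU pairs).  All tract classes are disjoint.
#'
#' @param type `"null"` or `"recovery"`.
#' @param seed integer seed passed to [sim_config()].
#' @return A [sim_config()].
#' @export
benchmark_config <- function(type = c("recovery", "null"), seed = 1L) {
  type <- match.arg(type)
  if (type == "null") {
    return(sim_config(genome_layout(c("chr1", "chr2"), c(5e6, 5e6)),
                      snp_density = 0.001,
                      n_samples = c(B = 20, EU = 20, AS = 20, O = 6),
                      seed = seed))
  }
  lay <- genome_layout(c("chr1", "chr2"), c(1e7, 1e7))
  introgression <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = 4),
    start = c(5e5, 2.5e6, 5e6, 8e6, 1e6, 3.5e6, 6e6, 9e6),
    end   = c(7.5e5, 2.75e6, 5.25e6, 8.25e6,
              1.25e6, 3.75e6, 6.25e6, 9.25e6),
    f = 0.8)
  sweeps <- data.frame(chrom = c("chr1", "chr2"),
                       start = c(4e6, 2e6), end = c(4.5e6, 2.5e6),
                       delta = 0.4)
  ibd <- data.frame(chrom = c("chr1", "chr2"),
                    start = c(7e6, 7.5e6), end = c(7.2e6, 7.7e6))
  sim_config(lay, snp_density = 0.005,
             n_samples = c(B = 30, EU = 30, AS = 30, O = 6),
             introgression = introgression, sweeps = sweeps, ibd = ibd,
             seed = seed)
}
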