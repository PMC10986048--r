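#' Windowed population branch statistic (PBS)
#'
#' Per window, the three pairwise Weir-Cockerham Fst values are turned
#' into branch lengths `T = -log(1 - Fst)` (Fst clamped to at most
#' `1 - 1e-12`; negative Fst yields negative T) and combined as
#' `PBS = (T_BY + T_BO - T_YO) / 2`, the frequency-change branch of the
#' target since its divergence from the control, with the third
#' population as outgroup.
#'
#' @param g a [genotype_matrix()].
#' @param target,control,outgroup three distinct population labels
#'   (target = the scanned breed, control = its sister, outgroup = the
#'   third population).
#' @param windows a `region_set` of windows (50 kb / 2 kb step in the
#'   motivating analysis, see [make_windows()]).
#' @param min_sites windows with fewer usable sites in any pair get `NA`.
#' @param log_base base of the branch-length logarithm (default natural
#'   log, the original PBS formulation).
#' @return A `window_table` with columns `n_sites` (minimum across the
#'   three pairs), `T_BY`, `T_BO`, `T_YO`, `pbs`.
#' @export
pbs_windows <- function(g, target, control, outgroup, windows,
                        min_sites = 10, log_base = exp(1)) {
  pops <- c(target, control, outgroup)
  if (anyDuplicated(pops)) stop("target, control and outgroup must be distinct")
  f_by <- fst_windows(g, target, control, windows, min_sites)
  f_bo <- fst_windows(g, target, outgroup, windows, min_sites)
  f_yo <- fst_windows(g, control, outgroup, windows, min_sites)
  p <- pbs_from_fst(f_by$fst, f_bo$fst, f_yo$fst, log_base)
  n <- pmin(f_by$n_sites, f_bo$n_sites, f_yo$n_sites)
  as_window_table(windows, data.frame(n_sites = n, T_BY = p$T_BY,
                                      T_BO = p$T_BO, T_YO = p$T_YO,
                                      pbs = p$pbs))
}

#' PBS from three pairwise Fst values
#'
#' `T = -log(1 - Fst)` per pair (Fst clamped to at most `1 - 1e-12`;
#' negative Fst gives negative T) and
#' `PBS = (T_BY + T_BO - T_YO) / 2`.
#'
#' @param fst_by,fst_bo,fst_yo pairwise Fst of target-control,
#'   target-outgroup and control-outgroup (vectors allowed).
#' @param log_base base of the logarithm (default natural log).
#' @return A list with `T_BY`, `T_BO`, `T_YO` and `pbs`.
#' @export
pbs_from_fst <- function(fst_by, fst_bo, fst_yo, log_base = exp(1)) {
  tfun <- function(fst) -log(1 - pmin(fst, 1 - 1e-12), base = log_base)
  t_by <- tfun(fst_by); t_bo <- tfun(fst_bo); t_yo <- tfun(fst_yo)
  list(T_BY = t_by, T_BO = t_bo, T_YO = t_yo,
       pbs = (t_by + t_bo - t_yo) / 2)
}

#' Call selective-sweep regions from PBS windows
#'
#' The empirical `1 - top_quantile` quantile of non-missing PBS values is
#' the threshold; windows at or above it with zero bp overlap with the
#' introgression call are merged (gap 0) into sweep regions.
#'
#' @param pbs a `window_table` from [pbs_windows()].
#' @param introgressed `region_set` of introgression regions to exclude
#'   (any bp of overlap disqualifies a window).
#' @param top_quantile fraction of windows treated as the scan's top tail
#'   (default 0.05).
#' @return List with `threshold` (the PBS cutoff) and `sweeps` (a
#'   `region_set` tagged `"sweep"`).
#' @export
call_sweeps <- function(pbs, introgressed, top_quantile = 0.05) {
  ok <- which(!is.na(pbs$pbs))
  if (!length(ok)) stop("no non-missing PBS windows")
  threshold <- unname(stats::quantile(pbs$pbs[ok], 1 - top_quantile))
  sel <- ok[pbs$pbs[ok] >= threshold]
  if (!length(sel)) return(list(threshold = threshold, sweeps = region_set()))
  cand <- region_set(pbs$chrom[sel], pbs$start[sel], pbs$end[sel], "sweep")
  if (nrow(introgressed)) {
    cand <- cand[!overlaps_any(cand, introgressed), , drop = FALSE]
    class(cand) <- c("region_set", "data.frame")
  }
  if (!nrow(cand)) return(list(threshold = threshold, sweeps = region_set()))
  list(threshold = threshold, sweeps = merge_regions(cand, 0))
}

#' Intersect sweep regions with externally supplied GWAS LD blocks
#'
#' Pure interval intersection; the GWAS itself is out of scope and its LD
#' blocks arrive as a BED-derived `region_set`.
#'
#' @param sweeps `region_set` of sweep regions.
#' @param ld_blocks `region_set` of LD blocks.
#' @return A `region_set` tagged `"core"`.
#' @export
overlap_with_ld_blocks <- function(sweeps, ld_blocks) {
  intersect_regions(sweeps, ld_blocks, tag = "core")
}
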