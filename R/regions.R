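#' Describe a genome as an ordered set of chromosomes
#'
#' @param chrom character vector of unique chromosome names (order kept).
#' @param length integer vector of chromosome lengths in bp, all `> 0`.
#' @return An object of class `genome_layout`: a list with `chrom` and
#'   `length`, the latter named by chromosome.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length)) {
    stop("'chrom' and 'length' must have equal length")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  names(length) <- chrom
  structure(list(chrom = chrom, length = length), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Build a set of genomic regions
#'
#' Regions are 0-based half-open intervals `[start, end)`, the BED
#' convention used throughout the package.
#'
#' @param chrom chromosome of each interval.
#' @param start,end 0-based half-open bounds; `start < end`.
#' @param tag optional provenance tag per interval (recycled).
#' @return A `region_set`: a data frame with columns `chrom`, `start`,
#'   `end`, `tag`, sorted by chromosome then start.
#' @export
region_set <- function(chrom = character(), start = numeric(),
                       end = numeric(), tag = NA_character_) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != length(start) || length(start) != length(end)) {
    stop("chrom, start, end must have equal length")
  }
  if (any(start < 0) || any(start >= end)) {
    stop("regions require 0 <= start < end")
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   tag = rep_len(as.character(tag), length(chrom)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

as_region_set <- function(df) {
  region_set(df$chrom, df$start, df$end,
             if ("tag" %in% names(df)) df$tag else NA_character_)
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", nrow(x), "interval(s),",
      format(covered_bp(x), big.mark = ","), "bp covered\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Total bp covered by a region set
#'
#' Overlapping intervals are collapsed before counting, so the result is
#' the size of the union.
#'
#' @param x a `region_set`.
#' @return Number of distinct bp covered.
#' @export
covered_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  m <- merge_regions(x, max_gap = 0)
  sum(m$end - m$start)
}

#' Tile a genome with (possibly sliding) windows
#'
#' Windows are anchored at position 0 on every chromosome; the final window
#' on each chromosome is truncated at the chromosome end.  `step == size`
#' gives a non-overlapping tiling.
#'
#' @param layout a [genome_layout()].
#' @param size window size in bp.
#' @param step distance between successive window starts; `0 < step <= size`.
#' @return A `region_set` of windows (tag `"window"`).
#' @examples
#' make_windows(genome_layout("chr1", 100000), 50000, 50000)
#' @export
make_windows <- function(layout, size, step = size) {
  stopifnot(inherits(layout, "genome_layout"))
  if (size <= 0) stop("window size must be positive")
  if (step <= 0 || step > size) stop("require 0 < step <= size")
  pieces <- lapply(layout$chrom, function(ch) {
    len <- layout$length[[ch]]
    if (len >= size) {
      starts <- seq(0, len - size, by = step)  # full windows only
      ends <- starts + size
    } else {
      starts <- numeric(0); ends <- numeric(0)
    }
    if (!length(ends) || max(ends) < len) {
      # one truncated terminal window so the tiling reaches the chromosome end
      s <- if (length(starts)) starts[length(starts)] + step else 0
      starts <- c(starts, s); ends <- c(ends, len)
    }
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  region_set(out$chrom, out$start, out$end, "window")
}

#' Merge intervals that touch or are separated by at most a gap
#'
#' @param x a `region_set` (or data frame with chrom/start/end).
#' @param max_gap two intervals merge iff the gap between them is
#'   `<= max_gap`; 0 merges only touching/overlapping intervals.
#' @return A sorted, non-overlapping `region_set`; tags of merged inputs
#'   collapse to the first input's tag.
#' @export
merge_regions <- function(x, max_gap = 0) {
  if (nrow(x) == 0) return(region_set())
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  chrom <- x$chrom; start <- x$start; end <- x$end
  tag <- if ("tag" %in% names(x)) as.character(x$tag) else rep(NA_character_, nrow(x))
  oc <- character(0); os <- numeric(0); oe <- numeric(0); ot <- character(0)
  cur_c <- chrom[1]; cur_s <- start[1]; cur_e <- end[1]; cur_t <- tag[1]
  for (i in seq_len(nrow(x))[-1]) {
    if (chrom[i] == cur_c && start[i] - cur_e <= max_gap) {
      cur_e <- max(cur_e, end[i])
    } else {
      oc <- c(oc, cur_c); os <- c(os, cur_s); oe <- c(oe, cur_e); ot <- c(ot, cur_t)
      cur_c <- chrom[i]; cur_s <- start[i]; cur_e <- end[i]; cur_t <- tag[i]
    }
  }
  oc <- c(oc, cur_c); os <- c(os, cur_s); oe <- c(oe, cur_e); ot <- c(ot, cur_t)
  region_set(oc, os, oe, ot)
}

#' Exact intersection of two region sets
#'
#' @param a,b `region_set`s.
#' @param tag tag applied to the output intervals.
#' @return A `region_set` covering exactly the bp present in both inputs.
#' @export
intersect_regions <- function(a, b, tag = NA_character_) {
  if (nrow(a) == 0 || nrow(b) == 0) return(region_set())
  a <- merge_regions(a, 0); b <- merge_regions(b, 0)
  oc <- character(0); os <- numeric(0); oe <- numeric(0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, ]; bi <- b[b$chrom == ch, ]
    i <- 1L; j <- 1L
    while (i <= nrow(ai) && j <= nrow(bi)) {
      s <- max(ai$start[i], bi$start[j])
      e <- min(ai$end[i], bi$end[j])
      if (s < e) { oc <- c(oc, ch); os <- c(os, s); oe <- c(oe, e) }
      if (ai$end[i] < bi$end[j]) i <- i + 1L else j <- j + 1L
    }
  }
  if (!length(oc)) return(region_set())
  region_set(oc, os, oe, tag)
}

# for each interval in `x`, TRUE iff it overlaps any interval of `other`
# by >= 1 bp (vectorized over x)
overlaps_any <- function(x, other) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(other) == 0) return(rep(FALSE, nrow(x)))
  other <- merge_regions(other, 0)
  out <- rep(FALSE, nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    oi <- other[other$chrom == ch, , drop = FALSE]
    if (!nrow(oi)) next
    # last interval starting at or before the query end
    idx <- findInterval(x$end[xi] - 1, oi$start)
    hit <- idx >= 1 & oi$end[pmax(idx, 1)] > x$start[xi]
    out[xi] <- hit
  }
  out
}

#' Fraction of the genome covered by a region set
#'
#' @param x a `region_set` whose intervals lie within `layout`.
#' @param layout a [genome_layout()].
#' @return Covered bp / total genome bp, in `[0, 1]`.
#' @export
genome_fraction <- function(x, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(x)) {
    bad <- !(x$chrom %in% layout$chrom) |
      x$end > layout$length[x$chrom]
    if (any(bad)) {
      stop("region(s) beyond chromosome end or on unknown chromosome: ",
           paste(utils::head(which(bad)), collapse = ", "))
    }
  }
  covered_bp(x) / sum(layout$length)
}

#' Read a BED file as a region_set
#'
#' Only the first three (plus optional name) columns are used; BED is
#' 0-based half-open, matching the package's internal convention.
#'
#' @param path BED file path.
#' @return A `region_set`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(region_set())
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns: ", path)
  tag <- if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  region_set(df[[1]], df[[2]], df[[3]], tag)
}

#' Write a region_set as BED
#'
#' @param x a `region_set`.
#' @param path output path.
#' @param header optional `#`-prefixed comment lines written first.
#' @export
write_bed <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(x)) {
    nm <- ifelse(is.na(x$tag), ".", x$tag)
    writeLines(paste(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                     format(x$end, scientific = FALSE, trim = TRUE), nm,
                     sep = "\t"), con)
  }
  invisible(path)
}
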