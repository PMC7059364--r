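#' Genomic interval tables
#'
#' Construct a validated table of genomic intervals.  All coordinates in this
#' package are 0-based, half-open (`[start, end)`), expressed on the plus
#' strand of the chromosome; strand is an attribute, never a coordinate flip.
#' Half-open intervals sharing an endpoint do not overlap (BED semantics).
#'
#' @param chrom character vector of sequence identifiers.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `start < end`.
#' @param strand character vector in `"+"`, `"-"`, `"*"` (unstranded).
#' @param chrom_lengths optional named integer vector; when supplied, each
#'   interval is checked to lie within `[0, chrom_lengths[chrom]]`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*",
                              chrom_lengths = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  strand <- rep_len(as.character(strand), n)
  if (anyNA(chrom) || anyNA(start) || anyNA(end) || anyNA(strand)) {
    stop("genomic_intervals: NA in chrom/start/end/strand", call. = FALSE)
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    stop(sprintf("invalid interval at record %d: [%d, %d) violates 0 <= start < end",
                 bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  bad <- which(!strand %in% c("+", "-", "*"))
  if (length(bad)) {
    stop(sprintf("invalid strand '%s' at record %d (must be '+', '-' or '*')",
                 strand[bad[1]], bad[1]), call. = FALSE)
  }
  if (!is.null(chrom_lengths)) {
    L <- chrom_lengths[chrom]
    bad <- which(is.na(L) | end > L)
    if (length(bad)) {
      stop(sprintf("interval at record %d ([%d, %d) on '%s') exceeds chromosome bounds",
                   bad[1], start[bad[1]], end[bad[1]], chrom[bad[1]]),
           call. = FALSE)
    }
  }
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Per-strand protomotif depth profile
#'
#' A depth profile stores, for one chromosome and one strand, the number of
#' contributing intervals covering every genomic position.
#'
#' @param chrom sequence identifier (length-1 character).
#' @param strand `"+"` or `"-"`.
#' @param depth integer vector of non-negative per-position depths; its
#'   length is the chromosome length.
#' @return an object of class `depth_profile`.
#' @export
depth_profile <- function(chrom, strand, depth) {
  stopifnot(length(chrom) == 1L, length(strand) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("depth_profile: strand must be '+' or '-'", call. = FALSE)
  }
  depth <- as.integer(depth)
  if (anyNA(depth) || any(depth < 0L)) {
    stop("depth_profile: depths must be non-negative integers", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), strand = strand, depth = depth),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s (%s strand), length %d, max depth %d, covered %d bp\n",
              x$chrom, x$strand, length(x$depth),
              if (length(x$depth)) max(x$depth) else 0L,
              sum(x$depth > 0L)))
  invisible(x)
}

#' Pile intervals into a depth profile
#'
#' Accumulates a set of intervals on one chromosome and strand into a dense
#' per-position depth vector: `depth[p]` is the number of intervals
#' containing position `p`.  This is the accumulation step that turns
#' individual protomotifs into a profile whose local maxima are peak-heights.
#'
#' @param intervals interval table as from [genomic_intervals()]; all rows
#'   must share one chromosome and one strand.
#' @param chrom_length chromosome length (positive integer).
#' @return a [depth_profile()].
#' @examples
#' iv <- genomic_intervals("chr", c(0, 5), c(10, 15), "+")
#' p <- pileup(iv, 20)
#' max(p$depth)  # 2
#' @export
pileup <- function(intervals, chrom_length) {
  chrom_length <- as.integer(chrom_length)
  stopifnot(length(chrom_length) == 1L, chrom_length >= 1L)
  if (nrow(intervals) == 0L) {
    return(depth_profile("<empty>", "+", integer(chrom_length)))
  }
  chrom <- unique(intervals$chrom)
  strand <- unique(intervals$strand)
  if (length(chrom) != 1L || length(strand) != 1L) {
    stop("pileup: intervals must share one chromosome and one strand",
         call. = FALSE)
  }
  bad <- which(intervals$start < 0L | intervals$end > chrom_length)
  if (length(bad)) {
    stop(sprintf("pileup: interval %d ([%d, %d)) out of bounds for length %d",
                 bad[1], intervals$start[bad[1]], intervals$end[bad[1]],
                 chrom_length), call. = FALSE)
  }
  # difference-array pileup: +1 at starts, -1 at ends, then cumulative sum
  delta <- tabulate(intervals$start + 1L, nbins = chrom_length + 1L) -
    tabulate(intervals$end + 1L, nbins = chrom_length + 1L)
  depth_profile(chrom, strand, cumsum(delta)[seq_len(chrom_length)])
}

#' Maximum depth over a region
#'
#' The peak-height of a region: the maximum accumulated depth at any single
#' position inside it.
#'
#' @param profile a [depth_profile()].
#' @param start,end region bounds, 0-based half-open, within the profile.
#' @return non-negative integer; 0 for a region with no coverage.
#' @export
max_depth_over <- function(profile, start, end) {
  stopifnot(inherits(profile, "depth_profile"))
  start <- as.integer(start); end <- as.integer(end)
  L <- length(profile$depth)
  if (start < 0L || end > L || start >= end) {
    stop(sprintf("max_depth_over: region [%d, %d) out of bounds for profile of length %d",
                 start, end, L), call. = FALSE)
  }
  max(profile$depth[(start + 1L):end])
}

#' Reciprocal overlap fractions of two intervals
#'
#' Returns the shared length as a fraction of each interval's own length,
#' the quantity behind the "at least 20% of the element is covered, or 20%
#' of the signal underlies the element" matching rule.  Strand is not
#' consulted here; strand policy belongs to the evaluator.
#'
#' @param a,b single-row interval tables (or lists with `chrom`, `start`,
#'   `end`).
#' @return numeric length-2: `c(overlap/len(a), overlap/len(b))`; `c(0, 0)`
#'   when the chromosomes differ.
#' @export
overlap_fractions <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(c(0, 0))
  ov <- max(0L, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
  c(ov / (a$end[1] - a$start[1]), ov / (b$end[1] - b$start[1]))
}
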