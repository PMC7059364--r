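#' Profiling parameters
#'
#' Thresholds governing which alignment hits become protomotifs and which
#' pileup runs become coding-signals.
#'
#' @param bit_score_min minimum BLAST bit-score `B` for a hit to count as a
#'   protomotif (closed bound: hits exactly at `B` are kept).  Default 30;
#'   29 and 31 are the conventional more/less permissive settings.
#' @param e_value_max maximum e-value `E`.  Default 10, deliberately
#'   permissive so that low-score alignments are retained.
#' @param peak_height_min peak-height threshold `H`: the minimum pileup
#'   depth a run must reach to be called a coding-signal.  The appropriate
#'   value scales with the protein database: 100 suits a ~20M-sequence
#'   database, 35 a ~4.5M-sequence one, 26 is a permissive variant.
#'   Default 100.
#' @param low_complexity_filter passed through to an external search
#'   backend (SEG masking); has no effect on precomputed reports.
#' @param merge_gap signal runs separated by at most this many
#'   below-threshold positions are merged.  Default 0 (no merging).
#' @param signal_extent `"threshold-run"` (a signal is a maximal run with
#'   depth >= H) or `"support-run"` (a signal is a maximal run of non-zero
#'   depth whose maximum reaches H).
#' @return a list of class `profiler_params`.
#' @export
profiler_params <- function(bit_score_min = 30, e_value_max = 10,
                            peak_height_min = 100L,
                            low_complexity_filter = TRUE,
                            merge_gap = 0L,
                            signal_extent = c("threshold-run", "support-run")) {
  signal_extent <- match.arg(signal_extent)
  if (bit_score_min <= 0) stop("bit_score_min must be > 0", call. = FALSE)
  if (e_value_max < 0) stop("e_value_max must be >= 0", call. = FALSE)
  peak_height_min <- as.integer(peak_height_min)
  if (is.na(peak_height_min) || peak_height_min < 1L) {
    stop("peak_height_min must be a positive integer", call. = FALSE)
  }
  merge_gap <- as.integer(merge_gap)
  if (is.na(merge_gap) || merge_gap < 0L) {
    stop("merge_gap must be a non-negative integer", call. = FALSE)
  }
  structure(list(bit_score_min = bit_score_min, e_value_max = e_value_max,
                 peak_height_min = peak_height_min,
                 low_complexity_filter = isTRUE(low_complexity_filter),
                 merge_gap = merge_gap, signal_extent = signal_extent),
            class = "profiler_params")
}

# frame of a plus-strand span starting at 0-based position s
frame_plus <- function(s) (s %% 3L) + 1L
# frame of a minus-strand span with 0-based exclusive end e on a chromosome
# of length L (codons read right-to-left on the reverse complement)
frame_minus <- function(e, L) -(((L - e) %% 3L) + 1L)

#' Filter raw hits into protomotifs
#'
#' Applies the bit-score/e-value thresholds and normalizes the report's
#' printed 1-based inclusive nucleotide coordinates to internal 0-based
#' half-open plus-strand intervals.  A hit is minus-strand iff its printed
#' `q_start` exceeds `q_end` (equivalently its frame is negative); when the
#' report lacks a frame column the reading frame is reconstructed from the
#' coordinates: `+((start mod 3) + 1)` on the plus strand and
#' `-(((L - end) mod 3) + 1)` on the minus strand of a chromosome of
#' length `L`.
#'
#' @param hits raw hit table from [read_blast_tabular()].
#' @param params a [profiler_params()].
#' @param chrom_lengths named integer vector of query chromosome lengths.
#' @return protomotif table: `chrom`, `start`, `end`, `strand`, `frame`,
#'   `bit_score`, `e_value`, `subject_id`.
#' @export
filter_and_map <- function(hits, params = profiler_params(), chrom_lengths) {
  stopifnot(inherits(params, "profiler_params"))
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      bit_score = numeric(), e_value = numeric(),
                      subject_id = character(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  unknown <- !hits$query_id %in% names(chrom_lengths)
  if (any(unknown)) {
    stop(sprintf("filter_and_map: hit %d references unknown query '%s'",
                 which(unknown)[1], hits$query_id[which(unknown)[1]]),
         call. = FALSE)
  }
  keep <- hits$bit_score >= params$bit_score_min &
    hits$e_value <= params$e_value_max
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)

  start <- pmin(hits$q_start, hits$q_end) - 1L
  end <- pmax(hits$q_start, hits$q_end)
  minus <- hits$q_start > hits$q_end
  L <- unname(chrom_lengths[hits$query_id])
  over <- which(start < 0L | end > L)
  if (length(over)) {
    stop(sprintf("filter_and_map: hit %s:%d-%d (subject %s) exceeds chromosome length %d",
                 hits$query_id[over[1]], hits$q_start[over[1]],
                 hits$q_end[over[1]], hits$subject_id[over[1]], L[over[1]]),
         call. = FALSE)
  }
  frame <- ifelse(minus, frame_minus(end, L), frame_plus(start))
  reported <- hits$frame
  has_rep <- !is.na(reported)
  contradict <- has_rep & ((reported < 0L) != minus)
  if (any(contradict)) {
    i <- which(contradict)[1]
    stop(sprintf("filter_and_map: hit %s:%d-%d (subject %s) has frame %+d contradicting its coordinate orientation",
                 hits$query_id[i], hits$q_start[i], hits$q_end[i],
                 hits$subject_id[i], reported[i]), call. = FALSE)
  }
  frame[has_rep] <- reported[has_rep]
  data.frame(chrom = hits$query_id, start = start, end = end,
             strand = ifelse(minus, "-", "+"), frame = as.integer(frame),
             bit_score = hits$bit_score, e_value = hits$e_value,
             subject_id = hits$subject_id, stringsAsFactors = FALSE)
}

#' Build per-chromosome, per-strand depth profiles
#'
#' Each chromosome yields exactly two profiles: plus-strand protomotifs
#' accumulate only on the `+` profile (regardless of frame index), minus
#' strand only on `-`.
#'
#' @param protomotifs protomotif table from [filter_and_map()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return nested list: `profiles[[chrom]][[strand]]` is a
#'   [depth_profile()].
#' @export
build_profiles <- function(protomotifs, chrom_lengths) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    out[[chrom]] <- list()
    for (strand in c("+", "-")) {
      sub <- protomotifs[protomotifs$chrom == chrom &
                           protomotifs$strand == strand, , drop = FALSE]
      p <- pileup(sub, L)
      p$chrom <- chrom
      p$strand <- strand
      out[[chrom]][[strand]] <- p
    }
  }
  out
}

#' Call coding-signals on a depth profile
#'
#' A coding-signal is a maximal run of consecutive positions whose depth
#' reaches the peak-height threshold `H` (the `threshold-run` extent), or a
#' maximal run of non-zero depth whose internal maximum reaches `H`
#' (`support-run`).  Runs separated by at most `merge_gap` below-threshold
#' positions are merged first.  Each signal carries its peak-height (the
#' maximum depth inside the signal) and, when a protomotif table is
#' supplied, the number of protomotifs intersecting it.
#'
#' @param profile a [depth_profile()].
#' @param params a [profiler_params()]; `peak_height_min`, `merge_gap` and
#'   `signal_extent` are consulted.
#' @param protomotifs optional protomotif table used to count
#'   `n_protomotifs` per signal (intersection, same chromosome and strand).
#' @return `data.frame` of disjoint, sorted signals: `chrom`, `start`,
#'   `end`, `strand`, `peak_height`, `n_protomotifs`.
#' @export
call_coding_signals <- function(profile, params = profiler_params(),
                                protomotifs = NULL) {
  stopifnot(inherits(profile, "depth_profile"),
            inherits(params, "profiler_params"))
  H <- params$peak_height_min
  depth <- profile$depth
  runs <- if (params$signal_extent == "threshold-run") {
    runs_at_least(depth, H, params$merge_gap)
  } else {
    sup <- runs_at_least(depth, 1L, params$merge_gap)
    if (nrow(sup)) {
      keep <- vapply(seq_len(nrow(sup)), function(i) {
        max(depth[(sup$start[i] + 1L):sup$end[i]]) >= H
      }, logical(1))
      sup[keep, , drop = FALSE]
    } else sup
  }
  n <- nrow(runs)
  peak <- integer(n)
  npm <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    peak[i] <- max(depth[(runs$start[i] + 1L):runs$end[i]])
  }
  if (!is.null(protomotifs)) {
    sub <- protomotifs[protomotifs$chrom == profile$chrom &
                         protomotifs$strand == profile$strand, , drop = FALSE]
    npm <- vapply(seq_len(n), function(i) {
      sum(sub$start < runs$end[i] & sub$end > runs$start[i])
    }, integer(1))
  }
  data.frame(chrom = rep(profile$chrom, n), start = runs$start,
             end = runs$end, strand = rep(profile$strand, n),
             peak_height = peak, n_protomotifs = npm,
             stringsAsFactors = FALSE)
}

# maximal 0-based half-open runs where depth >= threshold, with runs
# separated by <= merge_gap positions joined
runs_at_least <- function(depth, threshold, merge_gap = 0L) {
  above <- depth >= threshold
  if (!any(above)) return(data.frame(start = integer(), end = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  s <- starts[r$values]
  e <- ends[r$values]
  if (merge_gap > 0L && length(s) > 1L) {
    ms <- s[1]; me <- e[1]
    out_s <- integer(); out_e <- integer()
    for (i in 2:length(s)) {
      if (s[i] - me <= merge_gap) {
        me <- e[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
    s <- c(out_s, ms); e <- c(out_e, me)
  }
  data.frame(start = s, end = e)
}

#' Run the full protomotif scan
#'
#' The top-level pipeline: filter raw hits into protomotifs
#' ([filter_and_map()]), accumulate them into per-strand depth profiles
#' ([build_profiles()]), and call coding-signals on every profile
#' ([call_coding_signals()]).
#'
#' @param hits raw hit table from [read_blast_tabular()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param params a [profiler_params()].
#' @return object of class `protomotif_scan`: a list with elements
#'   `protomotifs`, `profiles`, `signals`, `params`, `chrom_lengths`,
#'   `n_input_hits`.
#' @seealso [evaluate()] to score the called signals against an annotation.
#' @examples
#' fx <- generate_genome(fixture_params(genome_length = 20000L,
#'                                      n_coding_regions = 2L, seed = 1L))
#' hits <- simulate_hits(fx)
#' scan <- protomotif_scan(hits, fx$chrom_lengths,
#'                         profiler_params(peak_height_min = 20L))
#' scan$signals
#' @export
protomotif_scan <- function(hits, chrom_lengths, params = profiler_params()) {
  pm <- filter_and_map(hits, params, chrom_lengths)
  profiles <- build_profiles(pm, chrom_lengths)
  signals <- do.call(rbind, lapply(unlist(profiles, recursive = FALSE),
                                   call_coding_signals, params = params,
                                   protomotifs = pm))
  if (is.null(signals)) {
    signals <- call_coding_signals(depth_profile("none", "+", 1L), params)[0, ]
  }
  signals <- signals[order(signals$chrom, signals$start), , drop = FALSE]
  rownames(signals) <- NULL
  structure(list(protomotifs = pm, profiles = profiles, signals = signals,
                 params = params, chrom_lengths = chrom_lengths,
                 n_input_hits = nrow(hits)),
            class = "protomotif_scan")
}

#' @export
print.protomotif_scan <- function(x, ...) {
  cat("Protomotif coding-signal scan\n")
  cat(sprintf("  chromosomes : %d (%s bp total)\n", length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ",")))
  cat(sprintf("  input hits  : %d\n", x$n_input_hits))
  cat(sprintf("  protomotifs : %d (bit-score >= %g, e-value <= %g)\n",
              nrow(x$protomotifs), x$params$bit_score_min,
              x$params$e_value_max))
  cat(sprintf("  signals     : %d (peak-height >= %d, %s extent)\n",
              nrow(x$signals), x$params$peak_height_min,
              x$params$signal_extent))
  invisible(x)
}

#' @export
summary.protomotif_scan <- function(object, ...) {
  per_chrom <- lapply(names(object$chrom_lengths), function(chrom) {
    pm <- object$protomotifs[object$protomotifs$chrom == chrom, ]
    sg <- object$signals[object$signals$chrom == chrom, ]
    data.frame(chrom = chrom, length = object$chrom_lengths[[chrom]],
               n_protomotifs = nrow(pm), n_signals = nrow(sg),
               max_peak_height = if (nrow(sg)) max(sg$peak_height) else 0L,
               stringsAsFactors = FALSE)
  })
  out <- list(per_chrom = do.call(rbind, per_chrom),
              params = object$params, n_input_hits = object$n_input_hits)
  class(out) <- "summary.protomotif_scan"
  out
}

#' @export
print.summary.protomotif_scan <- function(x, ...) {
  cat("Protomotif scan summary (per chromosome):\n")
  print(x$per_chrom, row.names = FALSE)
  invisible(x)
}

#' Plot a scan's depth profiles for one chromosome
#'
#' Draws the plus-strand profile upward and the minus-strand profile
#' downward, with called signals marked along the axis and the peak-height
#' threshold as a dashed line.
#'
#' @param x a `protomotif_scan`.
#' @param chrom chromosome to draw (default: the first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.protomotif_scan <- function(x, chrom = names(x$chrom_lengths)[1], ...) {
  plus <- x$profiles[[chrom]][["+"]]$depth
  minus <- x$profiles[[chrom]][["-"]]$depth
  pos <- seq_along(plus) - 1L
  ylim <- c(-max(minus, 1L), max(plus, 1L))
  graphics::plot(pos, plus, type = "h", col = "darkgreen", ylim = ylim,
                 xlab = sprintf("position on %s (bp)", chrom),
                 ylab = "protomotif depth (+ up, - down)", ...)
  graphics::lines(pos, -minus, type = "h", col = "firebrick")
  graphics::abline(h = c(1, -1) * x$params$peak_height_min, lty = 2)
  sg <- x$signals[x$signals$chrom == chrom, ]
  if (nrow(sg)) {
    graphics::segments(sg$start, 0, sg$end, 0, lwd = 3,
                       col = ifelse(sg$strand == "+", "darkgreen", "firebrick"))
  }
  invisible(x)
}
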