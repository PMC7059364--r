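#' Evaluation parameters
#'
#' @param overlap_fraction minimum reciprocal overlap fraction `f`: a
#'   signal matches an element when at least `f` of the element is covered
#'   by the signal OR at least `f` of the signal underlies the element
#'   (closed bounds).  Default 0.20.
#' @param strand_mode `"require_match"` (a signal can only match an element
#'   on the same strand; unstranded elements match either) or `"ignore"`.
#' @param element_flank nucleotides added on both sides of an element
#'   (clipped at chromosome bounds) before measuring its protomotif support
#'   in [bin_elements()].  Default 100.
#' @param fn_min_protomotifs elements supported by fewer protomotifs than
#'   this are binned as undetectable false negatives regardless of
#'   peak-height.  Default 5.
#' @param height_bins ascending integer peak-height bin edges
#'   `c(low, high)`; the middle bin is closed on both ends (`[low, high]`),
#'   the top bin strict (`> high`).  Default `c(26, 35)`.
#' @return a list of class `eval_params`.
#' @export
eval_params <- function(overlap_fraction = 0.20,
                        strand_mode = c("require_match", "ignore"),
                        element_flank = 100L,
                        fn_min_protomotifs = 5L,
                        height_bins = c(26L, 35L)) {
  strand_mode <- match.arg(strand_mode)
  if (!(overlap_fraction > 0 && overlap_fraction <= 1)) {
    stop("overlap_fraction must be in (0, 1]", call. = FALSE)
  }
  element_flank <- as.integer(element_flank)
  if (is.na(element_flank) || element_flank < 0L) {
    stop("element_flank must be a non-negative integer", call. = FALSE)
  }
  fn_min_protomotifs <- as.integer(fn_min_protomotifs)
  if (is.na(fn_min_protomotifs) || fn_min_protomotifs < 1L) {
    stop("fn_min_protomotifs must be a positive integer", call. = FALSE)
  }
  height_bins <- as.integer(height_bins)
  if (length(height_bins) != 2L || anyNA(height_bins) ||
      diff(height_bins) <= 0L) {
    stop("height_bins must be two strictly ascending integers", call. = FALSE)
  }
  structure(list(overlap_fraction = overlap_fraction,
                 strand_mode = strand_mode, element_flank = element_flank,
                 fn_min_protomotifs = fn_min_protomotifs,
                 height_bins = height_bins),
            class = "eval_params")
}

#' Genomic reading frame of a CDS segment
#'
#' Derives the frame (`+1..+3`, `-1..-3`) in which a CDS segment is
#' translated, from its coordinates, strand and phase.  On the plus strand
#' the first in-frame codon starts at `start + phase`; on the minus strand
#' the first in-frame codon's rightmost base is `end - phase`
#' (exclusive-end arithmetic), so the frame index is computed from the
#' distance to the chromosome's right edge.
#'
#' @param elements element table (rows of kind `CDS` with a phase).
#' @param chrom_lengths named integer vector of chromosome lengths
#'   (required for minus-strand elements).
#' @return integer vector of frames, one per row.
#' @export
cds_genomic_frame <- function(elements, chrom_lengths) {
  if (any(elements$kind != "CDS") || anyNA(elements$phase)) {
    stop("cds_genomic_frame: all elements must be CDS records with a phase",
         call. = FALSE)
  }
  L <- unname(chrom_lengths[elements$chrom])
  if (anyNA(L)) {
    stop("cds_genomic_frame: unknown chromosome in elements", call. = FALSE)
  }
  ifelse(elements$strand == "-",
         frame_minus(elements$end - elements$phase, L),
         frame_plus(elements$start + elements$phase))
}

strands_compatible <- function(signal_strand, element_strand, strand_mode) {
  if (strand_mode == "ignore") return(TRUE)
  element_strand == "*" || signal_strand == element_strand
}

#' Match coding-signals to annotation elements
#'
#' A (signal, element) pair matches when they share a chromosome, their
#' strands are compatible under `strand_mode`, and the overlap covers at
#' least `overlap_fraction` of the element or of the signal (closed
#' bounds).
#'
#' @param signals signal table from [call_coding_signals()].
#' @param elements element table from [read_gff3_elements()].
#' @param params an [eval_params()].
#' @return logical matrix with one row per signal, one column per element
#'   (dimnames carry element ids).
#' @export
match_signals_to_elements <- function(signals, elements,
                                      params = eval_params()) {
  stopifnot(inherits(params, "eval_params"))
  f <- params$overlap_fraction
  m <- matrix(FALSE, nrow(signals), nrow(elements),
              dimnames = list(NULL, elements$element_id))
  for (i in seq_len(nrow(signals))) {
    same_chrom <- elements$chrom == signals$chrom[i]
    if (!any(same_chrom)) next
    for (j in which(same_chrom)) {
      if (!strands_compatible(signals$strand[i], elements$strand[j],
                              params$strand_mode)) next
      ov <- max(0L, min(signals$end[i], elements$end[j]) -
                  max(signals$start[i], elements$start[j]))
      if (ov == 0L) next
      m[i, j] <- ov / (elements$end[j] - elements$start[j]) >= f ||
        ov / (signals$end[i] - signals$start[i]) >= f
    }
  }
  m
}

#' Evaluate coding-signals against a reference annotation
#'
#' Partitions signals into true positives (matching at least one element
#' under the overlap rule) and false positives, and elements into found and
#' false negatives, then computes precision and recall in percent:
#' `precision = 100 * TP / (TP + FP)` over signals and
#' `recall = 100 * TP_elements / (TP_elements + FN)` over elements.  The
#' two denominators deliberately differ: precision counts predictions,
#' recall counts annotated elements, and one signal spanning several exons
#' is a single correct prediction that recovers several elements.
#'
#' @param x signal table from [call_coding_signals()], or a
#'   `protomotif_scan` object (its `signals` are used).
#' @param elements element table from [read_gff3_elements()].
#' @param params an [eval_params()].
#' @param ... unused.
#' @return object of class `signal_evaluation`: list with `tp` (signal
#'   table plus `matched_elements`), `fp`, `fn` (element table),
#'   `found_elements`, `precision`, `recall`, `counts`
#'   (`TP`/`FP`/`FN`/`found`), `per_chrom`.
#' @export
evaluate <- function(x, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @export
evaluate.protomotif_scan <- function(x, elements, params = eval_params(), ...) {
  evaluate.data.frame(x$signals, elements, params)
}

#' @rdname evaluate
#' @export
evaluate.data.frame <- function(x, elements, params = eval_params(), ...) {
  signals <- x
  m <- match_signals_to_elements(signals, elements, params)
  sig_hit <- if (ncol(m)) rowSums(m) > 0L else rep(FALSE, nrow(signals))
  ele_hit <- if (nrow(m)) colSums(m) > 0L else rep(FALSE, nrow(elements))
  tp <- signals[sig_hit, , drop = FALSE]
  if (nrow(tp)) {
    tp$matched_elements <- vapply(which(sig_hit), function(i) {
      paste(elements$element_id[m[i, ]], collapse = ",")
    }, character(1))
  } else {
    tp$matched_elements <- character(0)
  }
  fp <- signals[!sig_hit, , drop = FALSE]
  fn <- elements[!ele_hit, , drop = FALSE]
  TP <- nrow(tp); FP <- nrow(fp)
  found <- sum(ele_hit); FN <- nrow(fn)
  precision <- if (TP + FP > 0L) 100 * TP / (TP + FP) else {
    warning("evaluate: no signals; precision undefined")
    NaN
  }
  recall <- if (found + FN > 0L) 100 * found / (found + FN) else {
    warning("evaluate: no elements; recall undefined")
    NaN
  }
  chroms <- sort(unique(c(signals$chrom, elements$chrom)))
  per_chrom <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch,
               tp = sum(tp$chrom == ch), fp = sum(fp$chrom == ch),
               fn = sum(fn$chrom == ch), found = sum(elements$chrom == ch &
                                                       ele_hit),
               stringsAsFactors = FALSE)
  }))
  structure(list(tp = tp, fp = fp, fn = fn,
                 found_elements = elements[ele_hit, , drop = FALSE],
                 precision = precision, recall = recall,
                 counts = c(TP = TP, FP = FP, FN = FN, found = found),
                 per_chrom = per_chrom, params = params),
            class = "signal_evaluation")
}

#' @export
print.signal_evaluation <- function(x, ...) {
  cat("Coding-signal evaluation\n")
  cat(sprintf("  signals  : %d TP + %d FP\n", x$counts["TP"], x$counts["FP"]))
  cat(sprintf("  elements : %d found + %d FN\n", x$counts["found"],
              x$counts["FN"]))
  cat(sprintf("  precision: %.1f%%   recall: %.1f%%\n", x$precision, x$recall))
  invisible(x)
}

#' Precision/recall sweep over peak-height thresholds
#'
#' Re-calls coding-signals on every profile at each threshold `H` and
#' evaluates them, producing one table row per threshold.  The sweep
#' defaults to the `support-run` signal extent, under which a peak is an
#' entity whose extent does not depend on the threshold being swept:
#' raising `H` then only removes peaks, so recall and the TP/FP counts are
#' exactly non-increasing in `H`.  (Under `threshold-run` a peak can split
#' into several signals as `H` rises through an internal dip, which makes
#' the TP count non-monotone.)
#'
#' @param profiles nested profile list from [build_profiles()].
#' @param elements element table.
#' @param H_values ascending positive integer thresholds (non-empty).
#' @param params an [eval_params()].
#' @param profiler_params a [profiler_params()] supplying `merge_gap` and
#'   `signal_extent`; its `peak_height_min` is overridden by each `H`.
#' @param protomotifs optional protomotif table for `n_protomotifs`.
#' @return `data.frame` with columns `H`, `n_signals`, `TP`, `FP`, `FN`,
#'   `precision`, `recall`.
#' @export
sweep_thresholds <- function(profiles, elements, H_values,
                             params = eval_params(),
                             profiler_params = protomotif::profiler_params(
                               signal_extent = "support-run"),
                             protomotifs = NULL) {
  H_values <- as.integer(H_values)
  if (!length(H_values) || anyNA(H_values) || any(H_values < 1L) ||
      is.unsorted(H_values, strictly = TRUE)) {
    stop("sweep_thresholds: H_values must be non-empty, positive, strictly ascending",
         call. = FALSE)
  }
  flat <- unlist(profiles, recursive = FALSE)
  rows <- lapply(H_values, function(H) {
    pp <- profiler_params
    pp$peak_height_min <- H
    signals <- do.call(rbind, lapply(flat, call_coding_signals, params = pp,
                                     protomotifs = protomotifs))
    if (is.null(signals) || !nrow(signals)) {
      signals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            peak_height = integer(),
                            n_protomotifs = integer(),
                            stringsAsFactors = FALSE)
    }
    ev <- suppressWarnings(evaluate(signals, elements, params))
    data.frame(H = H, n_signals = nrow(signals),
               TP = unname(ev$counts["TP"]), FP = unname(ev$counts["FP"]),
               FN = unname(ev$counts["FN"]),
               precision = ev$precision,
               recall = if (is.nan(ev$recall)) NaN else ev$recall,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin annotated elements by protomotif support
#'
#' For each element, extends it by `element_flank` nucleotides on both
#' sides (clipped at chromosome bounds), counts the protomotifs
#' intersecting the flanked span and measures its peak-height on its own
#' strand's profile (maximum over both strands when
#' `strand_mode = "ignore"`), then assigns a discovery bin.  The
#' protomotif-count rule is applied first: elements with fewer than
#' `fn_min_protomotifs` supporting protomotifs are `FN_lt5` regardless of
#' height; the rest fall into `lt26` (below the lower edge), `26_35`
#' (closed on both ends) or `gt35` (strictly above) for the default edges.
#'
#' @param elements element table.
#' @param profiles nested profile list from [build_profiles()].
#' @param protomotifs protomotif table.
#' @param params an [eval_params()].
#' @return `data.frame`: `element_id`, `kind`, `chrom`, `strand`,
#'   `flank_start`, `flank_end`, `n_protomotifs`, `peak_height`, `bin`.
#' @export
bin_elements <- function(elements, profiles, protomotifs,
                         params = eval_params()) {
  stopifnot(inherits(params, "eval_params"))
  lo <- params$height_bins[1]; hi <- params$height_bins[2]
  n <- nrow(elements)
  out <- data.frame(element_id = elements$element_id, kind = elements$kind,
                    chrom = elements$chrom, strand = elements$strand,
                    flank_start = integer(n), flank_end = integer(n),
                    n_protomotifs = integer(n), peak_height = integer(n),
                    bin = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ch <- elements$chrom[i]
    L <- length(profiles[[ch]][["+"]]$depth)
    fs <- max(0L, elements$start[i] - params$element_flank)
    fe <- min(L, elements$end[i] + params$element_flank)
    out$flank_start[i] <- fs
    out$flank_end[i] <- fe
    strands <- if (params$strand_mode == "ignore" ||
                   elements$strand[i] == "*") c("+", "-") else
      elements$strand[i]
    sub <- protomotifs[protomotifs$chrom == ch &
                         protomotifs$strand %in% strands, , drop = FALSE]
    out$n_protomotifs[i] <- sum(sub$start < fe & sub$end > fs)
    out$peak_height[i] <- max(vapply(strands, function(s) {
      max_depth_over(profiles[[ch]][[s]], fs, fe)
    }, integer(1)))
    out$bin[i] <- if (out$n_protomotifs[i] < params$fn_min_protomotifs) {
      "FN_lt5"
    } else if (out$peak_height[i] < lo) {
      sprintf("lt%d", lo)
    } else if (out$peak_height[i] <= hi) {
      sprintf("%d_%d", lo, hi)
    } else {
      sprintf("gt%d", hi)
    }
  }
  out
}

#' Frame distribution of protomotifs over CDS elements
#'
#' Cross-tabulates, for every (protomotif, CDS) overlap incidence, the
#' CDS's genomic reading frame against the protomotif's frame, stratified
#' by bit-score bin.  A protomotif overlapping several CDS records counts
#' once per overlapped CDS.  In data where hits arise from real coding
#' sequence, mass concentrates on the in-frame diagonal and, off-diagonal,
#' on same-strand cells.
#'
#' @param protomotifs protomotif table.
#' @param cds_elements CDS element table (frames derived via
#'   [cds_genomic_frame()]).
#' @param score_bin_edges ascending numeric bit-score bin edges (outer
#'   edges included; hits outside are dropped).
#' @param chrom_lengths named integer vector.
#' @return 3-d integer array `[cds frame, protomotif frame, score bin]`
#'   with frame dimnames `"+1".."-3"`.
#' @export
frame_distribution <- function(protomotifs, cds_elements, score_bin_edges,
                               chrom_lengths) {
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  score_bin_edges <- as.numeric(score_bin_edges)
  if (length(score_bin_edges) < 2L || is.unsorted(score_bin_edges,
                                                  strictly = TRUE)) {
    stop("frame_distribution: need >= 2 ascending score bin edges",
         call. = FALSE)
  }
  nb <- length(score_bin_edges) - 1L
  bin_names <- sprintf("[%g,%g%s", score_bin_edges[-length(score_bin_edges)],
                       score_bin_edges[-1],
                       c(rep(")", nb - 1L), "]"))
  arr <- array(0L, dim = c(6L, 6L, nb),
               dimnames = list(cds_frame = frames, protomotif_frame = frames,
                               score_bin = bin_names))
  if (!nrow(cds_elements) || !nrow(protomotifs)) return(arr)
  cds_frames <- cds_genomic_frame(cds_elements, chrom_lengths)
  fmt <- function(f) sprintf("%+d", f)
  for (j in seq_len(nrow(cds_elements))) {
    sub <- protomotifs[protomotifs$chrom == cds_elements$chrom[j] &
                         protomotifs$start < cds_elements$end[j] &
                         protomotifs$end > cds_elements$start[j], ,
                       drop = FALSE]
    if (!nrow(sub)) next
    bin <- findInterval(sub$bit_score, score_bin_edges,
                        rightmost.closed = TRUE)
    ok <- bin >= 1L & bin <= nb
    for (i in which(ok)) {
      arr[fmt(cds_frames[j]), fmt(sub$frame[i]), bin[i]] <-
        arr[fmt(cds_frames[j]), fmt(sub$frame[i]), bin[i]] + 1L
    }
  }
  arr
}
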