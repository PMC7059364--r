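# Negative controls: a real coding signal should vanish when the query's
# codon structure is destroyed while its composition is preserved.

#' Reversed-sequence negative control
#'
#' `mode = "reverse"` returns the character-reversed sequence: reversal
#' destroys codon structure on both strands, which is what a negative
#' control should do.  `mode = "revcomp"` (the reverse complement) is also
#' offered; note it preserves the sense-strand signal on the opposite
#' strand and is therefore a much weaker control.
#'
#' @param sequence nucleotide string.
#' @param mode `"reverse"` or `"revcomp"`.
#' @return the control sequence.
#' @export
make_reverse_control <- function(sequence, mode = c("reverse", "revcomp")) {
  mode <- match.arg(mode)
  stopifnot(length(sequence) == 1L)
  if (!nzchar(sequence)) {
    stop("make_reverse_control: empty sequence", call. = FALSE)
  }
  if (mode == "reverse") {
    paste(rev(strsplit(sequence, "", fixed = TRUE)[[1]]), collapse = "")
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
  }
}

#' Composition-preserving shuffled controls
#'
#' Generates `n` independent uniform random permutations of the input's
#' characters (mononucleotide shuffle): every replicate has exactly the
#' input's base composition and length, while codon and dinucleotide
#' structure are randomized.  Deterministic given `seed`.
#'
#' @param sequence nucleotide string.
#' @param n number of replicates (>= 1); 100 is the conventional choice.
#' @param seed integer RNG seed.
#' @return character vector of `n` shuffled sequences.
#' @export
make_shuffled_controls <- function(sequence, n = 100L, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) {
    stop("make_shuffled_controls: n must be >= 1", call. = FALSE)
  }
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  vapply(seq_len(n), function(i) paste(sample(chars), collapse = ""),
         character(1))
}

#' Summarize control-replicate scan results
#'
#' @param replicates list with one entry per control replicate; each entry
#'   is a list with `n_protomotifs` (integer) and `max_peak_height`
#'   (integer, 0 when no protomotif was found), e.g. built from
#'   [protomotif_scan()] results via [control_replicate_stats()].
#' @return list of class `control_summary`: `n_replicates`, `n_zero_hit`,
#'   `fraction_zero`, `max_peak_heights` (replicate order preserved).
#' @export
summarize_controls <- function(replicates) {
  if (!length(replicates)) {
    stop("summarize_controls: empty replicate set", call. = FALSE)
  }
  npm <- vapply(replicates, function(r) as.integer(r$n_protomotifs), integer(1))
  heights <- vapply(replicates, function(r) as.integer(r$max_peak_height),
                    integer(1))
  heights[npm == 0L] <- 0L
  n <- length(replicates)
  nz <- sum(npm == 0L)
  structure(list(n_replicates = n, n_zero_hit = nz,
                 fraction_zero = nz / n, max_peak_heights = heights),
            class = "control_summary")
}

#' @export
print.control_summary <- function(x, ...) {
  cat(sprintf("Control summary: %d/%d replicates with no protomotif (%.0f%%)\n",
              x$n_zero_hit, x$n_replicates, 100 * x$fraction_zero))
  nz <- x$max_peak_heights[x$max_peak_heights > 0L]
  if (length(nz)) {
    cat(sprintf("  non-zero replicates: max peak-heights %d-%d\n",
                min(nz), max(nz)))
  }
  invisible(x)
}

#' Per-replicate statistics from a scan
#'
#' Reduces a [protomotif_scan()] to the two numbers
#' [summarize_controls()] needs.
#'
#' @param scan a `protomotif_scan`.
#' @return list with `n_protomotifs` and `max_peak_height` (the global
#'   maximum profile depth over all chromosomes and strands).
#' @export
control_replicate_stats <- function(scan) {
  stopifnot(inherits(scan, "protomotif_scan"))
  depths <- unlist(lapply(unlist(scan$profiles, recursive = FALSE),
                          `[[`, "depth"))
  list(n_protomotifs = nrow(scan$protomotifs),
       max_peak_height = if (length(depths)) max(depths) else 0L)
}
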