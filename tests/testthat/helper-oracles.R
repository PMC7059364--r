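# Independent brute-force oracles.  These deliberately share no code with
# the implementation: pileup by per-position membership counting, run
# detection by position marking, overlap by set intersection, frames by
# explicit codon enumeration.

brute_pileup <- function(intervals, L) {
  depth <- integer(L)
  for (p in seq_len(L) - 1L) {
    depth[p + 1L] <- sum(intervals$start <= p & p < intervals$end)
  }
  depth
}

brute_max_depth <- function(depth, start, end) {
  m <- 0L
  for (p in start:(end - 1L)) m <- max(m, depth[p + 1L])
  m
}

brute_overlap_len <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0L)
  length(intersect(seq(a$start[1], a$end[1] - 1L),
                   seq(b$start[1], b$end[1] - 1L)))
}

# maximal runs of positions with depth >= H, as a data.frame(start, end)
brute_runs <- function(depth, H) {
  marked <- which(depth >= H) - 1L
  if (!length(marked)) return(data.frame(start = integer(), end = integer()))
  breaks <- which(diff(marked) > 1L)
  starts <- marked[c(1L, breaks + 1L)]
  ends <- marked[c(breaks, length(marked))] + 1L
  data.frame(start = starts, end = ends)
}

# frame of a genomic span by locating its codon offset among explicitly
# enumerated codon start positions in all six frames
brute_frame <- function(start, end, strand, L) {
  for (k in 1:3) {
    if (strand == "+") {
      codon_starts <- seq(k - 1L, L - 3L, by = 3L)
      if (start %in% codon_starts) return(k)
    } else {
      # revcomp offset of genomic end e is L - e
      codon_rev_offsets <- seq(k - 1L, L - 3L, by = 3L)
      if ((L - end) %in% codon_rev_offsets) return(-k)
    }
  }
  stop("brute_frame: no frame found")
}

random_intervals <- function(n, L, chrom = "c", strand = "+",
                             max_len = 200L) {
  start <- sample.int(L - 3L, n, replace = TRUE) - 1L
  len <- pmin(sample.int(max_len, n, replace = TRUE) + 2L, L - start)
  genomic_intervals(chrom, start, start + len, strand)
}

# minimal raw-hit table in read_blast_tabular() layout
make_hits <- function(q_start, q_end, bit_score, e_value = 1e-4,
                      query_id = "c", subject_id = "s", frame = NA_integer_) {
  data.frame(query_id = query_id, subject_id = subject_id,
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             s_start = 1L, s_end = 10L, e_value = e_value,
             bit_score = bit_score, frame = as.integer(frame),
             stringsAsFactors = FALSE)
}
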