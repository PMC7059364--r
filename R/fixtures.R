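# Self-contained synthetic test universes: a genome with planted open
# reading frames, a truth annotation, and a simulated hit report whose
# statistics are conditioned on the truth.  The hit model is deliberately
# simple (Poisson counts, uniform scores): it exists to exercise the
# pipeline's mechanics and monotonicity, not to model a real protein
# database.

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                  c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Synthetic fixture parameters
#'
#' @param genome_length chromosome length in nucleotides.
#' @param n_coding_regions number of planted open reading frames.
#' @param coding_length_range `c(min, max)` planted ORF length in
#'   nucleotides; lengths are drawn as multiples of 3.
#' @param frames optional integer vector (length `n_coding_regions`, values
#'   in `{-3..-1, 1..3}`) fixing each region's strand/frame; by default the
#'   six combinations are sampled uniformly.
#' @param hits_per_coding_kb expected simulated hits per kb of planted
#'   coding sequence (Poisson mean).  The default of 600, with the default
#'   hit lengths, piles coding regions to peak-heights of order 40-70 —
#'   the same order as the working peak-height thresholds the method uses
#'   in practice.
#' @param background_hits_per_kb expected hits per kb of non-coding
#'   sequence (default 2: sparse, background depth rarely exceeds 2-3).
#' @param coding_bitscore_range,background_bitscore_range uniform bit-score
#'   ranges for coding/background hits (defaults `[30, 100]` and
#'   `[29, 32]`).
#' @param hit_length_range `c(min, max)` hit span in nucleotides.
#' @param decoy_cluster_rate expected number of dense non-coding hit
#'   clusters per genome (a precision stressor); default 0.
#' @param frame_shift_prob probability a coding hit lands on the coding
#'   strand but in a shifted frame (default 0.1).
#' @param opposite_strand_prob probability a coding hit lands on the
#'   opposite strand (default 0.01).
#' @param seed integer seed; every output is deterministic given it.
#' @return a list of class `fixture_params`.
#' @export
fixture_params <- function(genome_length = 100000L, n_coding_regions = 8L,
                           coding_length_range = c(300L, 900L),
                           frames = NULL,
                           hits_per_coding_kb = 600,
                           background_hits_per_kb = 2,
                           coding_bitscore_range = c(30, 100),
                           background_bitscore_range = c(29, 32),
                           hit_length_range = c(30L, 150L),
                           decoy_cluster_rate = 0,
                           frame_shift_prob = 0.1,
                           opposite_strand_prob = 0.01,
                           seed = 1L) {
  genome_length <- as.integer(genome_length)
  n_coding_regions <- as.integer(n_coding_regions)
  stopifnot(genome_length >= 100L, n_coding_regions >= 0L,
            length(coding_length_range) == 2L,
            coding_length_range[1] >= 9L,
            coding_length_range[1] <= coding_length_range[2],
            length(hit_length_range) == 2L, hit_length_range[1] >= 3L,
            hit_length_range[1] <= hit_length_range[2],
            hits_per_coding_kb >= 0, background_hits_per_kb >= 0,
            decoy_cluster_rate >= 0,
            frame_shift_prob >= 0, opposite_strand_prob >= 0,
            frame_shift_prob + opposite_strand_prob <= 1)
  if (!is.null(frames)) {
    frames <- as.integer(frames)
    if (length(frames) != n_coding_regions ||
        !all(frames %in% c(-3:-1, 1:3))) {
      stop("fixture_params: frames must be length n_coding_regions with values in {-3..-1, 1..3}",
           call. = FALSE)
    }
  }
  if (n_coding_regions * (coding_length_range[2] + 250) >= genome_length) {
    stop("fixture_params: infeasible packing: planted regions plus spacing exceed genome_length",
         call. = FALSE)
  }
  structure(list(genome_length = genome_length,
                 n_coding_regions = n_coding_regions,
                 coding_length_range = as.integer(coding_length_range),
                 frames = frames,
                 hits_per_coding_kb = hits_per_coding_kb,
                 background_hits_per_kb = background_hits_per_kb,
                 coding_bitscore_range = coding_bitscore_range,
                 background_bitscore_range = background_bitscore_range,
                 hit_length_range = as.integer(hit_length_range),
                 decoy_cluster_rate = decoy_cluster_rate,
                 frame_shift_prob = frame_shift_prob,
                 opposite_strand_prob = opposite_strand_prob,
                 seed = as.integer(seed)),
            class = "fixture_params")
}

#' Generate a synthetic genome with planted open reading frames
#'
#' Builds an i.i.d.-uniform ACGT chromosome and plants non-overlapping real
#' ORFs (ATG, sense codons, terminal stop) at the assigned strand/frame
#' combinations: a region assigned frame `+k` starts at a position
#' congruent to `k - 1` (mod 3); a region assigned `-k` is placed so its
#' reverse-complement reading begins at revcomp offset `k - 1`.  Regions
#' are separated by at least 250 nt so flanked elements stay disjoint.
#' Byte-identical output under the same seed.
#'
#' @param params a [fixture_params()].
#' @return list of class `fixture_genome`: `genome` (named character
#'   vector, one chromosome), `chrom_lengths`, `elements` (truth
#'   gene/exon/CDS table in [read_gff3_elements()] layout), `regions`
#'   (one row per planted ORF with its `frame` and `peptide`), `params`.
#' @export
generate_genome <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  with_seed(params$seed, {
    L <- params$genome_length
    chrom <- "synth_chr1"
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    n <- params$n_coding_regions
    frames <- params$frames
    if (is.null(frames) && n > 0L) {
      frames <- sample(c(-3:-1, 1:3), n, replace = TRUE)
    }
    lens <- if (n > 0L) {
      choices <- seq(params$coding_length_range[1],
                     params$coding_length_range[2], by = 3L)
      choices[1 + (sample.int(length(choices), n, replace = TRUE) - 1L)]
    } else integer()
    # place non-overlapping starts with >= 250 nt separation (and from ends)
    starts <- integer(n)
    if (n > 0L) {
      placed_s <- integer(); placed_e <- integer()
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(2000L)) {
          s <- sample.int(L - lens[i] - 500L, 1L) + 250L
          if (!any(s < placed_e + 250L & s + lens[i] > placed_s - 250L)) {
            ok <- TRUE; break
          }
        }
        if (!ok) {
          stop("generate_genome: could not pack planted regions (infeasible parameters)",
               call. = FALSE)
        }
        k <- abs(frames[i])
        if (frames[i] > 0L) {
          s <- s + ((k - 1L - s) %% 3L)
        } else {
          e_target <- (L - (k - 1L)) %% 3L
          s <- s + ((e_target - (s + lens[i])) %% 3L)
        }
        placed_s <- c(placed_s, s); placed_e <- c(placed_e, s + lens[i])
        starts[i] <- s
      }
    }
    peptides <- character(n)
    for (i in seq_len(n)) {
      ncod <- lens[i] %/% 3L
      codons <- c("ATG",
                  SENSE_CODONS[sample.int(length(SENSE_CODONS), ncod - 2L,
                                          replace = TRUE)],
                  STOP_CODONS[sample.int(3L, 1L)])
      orf <- paste(codons, collapse = "")
      peptides[i] <- as.character(Biostrings::translate(
        Biostrings::DNAString(orf), no.init.codon = TRUE))
      planted <- if (frames[i] > 0L) orf else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
      bases[(starts[i] + 1L):(starts[i] + lens[i])] <-
        strsplit(planted, "", fixed = TRUE)[[1]]
    }
    genome <- paste(bases, collapse = "")
    names(genome) <- chrom
    if (n > 0L) {
      o <- order(starts)
      starts <- starts[o]; lens <- lens[o]; frames <- frames[o]
      peptides <- peptides[o]
      strand <- ifelse(frames > 0L, "+", "-")
      elements <- do.call(rbind, lapply(seq_len(n), function(i) {
        data.frame(
          element_id = sprintf(c("gene_%02d", "exon_%02d", "cds_%02d"), i),
          kind = c("gene", "exon", "CDS"),
          chrom = chrom, start = starts[i], end = starts[i] + lens[i],
          strand = strand[i],
          phase = c(NA_integer_, NA_integer_, 0L),
          parent_id = c(NA_character_, sprintf("gene_%02d", i),
                        sprintf("gene_%02d", i)),
          stringsAsFactors = FALSE)
      }))
      regions <- data.frame(region_id = sprintf("gene_%02d", seq_len(n)),
                            chrom = chrom, start = starts,
                            end = starts + lens, strand = strand,
                            frame = frames, peptide = peptides,
                            stringsAsFactors = FALSE)
    } else {
      elements <- read_gff3_elements(textConnection_gff_empty())
      regions <- data.frame(region_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), frame = integer(),
                            peptide = character(), stringsAsFactors = FALSE)
    }
    structure(list(genome = genome,
                   chrom_lengths = stats::setNames(L, chrom),
                   elements = elements, regions = regions, params = params),
              class = "fixture_genome")
  })
}

# empty element table with the right columns
textConnection_gff_empty <- function() {
  tf <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", tf)
  tf
}

#' @export
print.fixture_genome <- function(x, ...) {
  cat(sprintf("<fixture_genome> %s: %d bp, %d planted ORFs (seed %d)\n",
              names(x$genome), x$chrom_lengths[[1]],
              nrow(x$regions), x$params$seed))
  invisible(x)
}

snap_plus_start <- function(s, k) s + ((k - 1L - s) %% 3L)
snap_minus_end <- function(e, k, L) e - ((e - (L - (k - 1L))) %% 3L)

#' Simulate a BLAST-style hit report conditioned on the planted truth
#'
#' Draws Poisson-many hits over each planted region (frame equal to the
#' region's true frame, with small same-strand frame-shift and
#' opposite-strand probabilities), sparse background hits over the
#' non-coding gaps, and optional dense decoy clusters.  Coordinates are
#' written in the report dialect: 1-based inclusive with
#' `q_start > q_end` for minus-strand hits; the frame column is always
#' consistent with the coordinate orientation.  Deterministic given the
#' fixture seed (the hit stream is derived from `seed + 1`).
#'
#' @param fixture a [generate_genome()] result.
#' @param params a [fixture_params()]; defaults to the fixture's own.
#' @return raw hit `data.frame` in [read_blast_tabular()] layout, with a
#'   `decoy_windows` attribute (0-based half-open decoy intervals).
#' @export
simulate_hits <- function(fixture, params = fixture$params) {
  stopifnot(inherits(fixture, "fixture_genome"),
            inherits(params, "fixture_params"))
  L <- fixture$chrom_lengths[[1]]
  chrom <- names(fixture$genome)
  regions <- fixture$regions
  with_seed(params$seed + 1L, {
    rows <- list()
    add <- function(start, end, strand, k, bit) {
      # start/end 0-based half-open on plus strand; k = frame index 1..3
      frame <- if (strand == "+") k else -k
      qs <- if (strand == "+") start + 1L else end
      qe <- if (strand == "+") end else start + 1L
      alen <- max(1L, (end - start) %/% 3L)
      rows[[length(rows) + 1L]] <<- data.frame(
        query_id = chrom,
        subject_id = sprintf("UP%05d", sample.int(99999L, 1L)),
        q_start = qs, q_end = qe, s_start = 1L, s_end = alen,
        e_value = signif(10^stats::runif(1, -8, 0.9), 3),
        bit_score = round(stats::runif(1, bit[1], bit[2]), 1),
        frame = frame, stringsAsFactors = FALSE)
    }
    sample_len <- function() {
      r <- params$hit_length_range
      r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
    }
    # coding hits
    for (i in seq_len(nrow(regions))) {
      rs <- regions$start[i]; re <- regions$end[i]
      strand0 <- regions$strand[i]; k0 <- abs(regions$frame[i])
      nh <- stats::rpois(1, params$hits_per_coding_kb * (re - rs) / 1000)
      for (h in seq_len(nh)) {
        u <- stats::runif(1)
        if (u < params$opposite_strand_prob) {
          strand <- if (strand0 == "+") "-" else "+"
          k <- sample.int(3L, 1L)
        } else if (u < params$opposite_strand_prob + params$frame_shift_prob) {
          strand <- strand0
          k <- sample(setdiff(1:3, k0), 1L)
        } else {
          strand <- strand0
          k <- k0
        }
        l <- min(sample_len(), re - rs)
        s <- rs + sample.int(max(1L, re - rs - l + 1L), 1L) - 1L
        e <- s + l
        if (strand == "+") {
          s <- snap_plus_start(s, k)
          e <- min(e, re)
          if (s + 3L > e) { s <- snap_plus_start(max(rs, e - l), k) }
        } else {
          e <- snap_minus_end(e, k, L)
          s <- max(rs, e - l)
        }
        if (e - s >= 3L && s >= 0L && e <= L) {
          add(s, e, strand, k, params$coding_bitscore_range)
        }
      }
    }
    # non-coding gaps
    gaps <- if (nrow(regions)) {
      bounds <- c(0L, as.vector(rbind(regions$start, regions$end)), L)
      gs <- bounds[seq(1, length(bounds), by = 2)]
      ge <- bounds[seq(2, length(bounds), by = 2)]
      data.frame(start = gs, end = ge)[ge - gs >= 10L, , drop = FALSE]
    } else data.frame(start = 0L, end = L)
    gap_len <- sum(gaps$end - gaps$start)
    nb <- stats::rpois(1, params$background_hits_per_kb * gap_len / 1000)
    for (h in seq_len(nb)) {
      g <- sample.int(nrow(gaps), 1L,
                      prob = (gaps$end - gaps$start) / gap_len)
      l <- min(sample_len(), gaps$end[g] - gaps$start[g])
      s <- gaps$start[g] +
        sample.int(max(1L, gaps$end[g] - gaps$start[g] - l + 1L), 1L) - 1L
      e <- min(s + l, gaps$end[g])
      strand <- sample(c("+", "-"), 1L)
      k <- if (strand == "+") frame_plus(s) else abs(frame_minus(e, L))
      if (e - s >= 3L) add(s, e, strand, k, params$background_bitscore_range)
    }
    # decoy clusters: dense hit piles in non-coding sequence
    decoys <- data.frame(start = integer(), end = integer())
    nclust <- stats::rpois(1, params$decoy_cluster_rate)
    big <- gaps[gaps$end - gaps$start >= 600L, , drop = FALSE]
    for (cl in seq_len(min(nclust, nrow(big)))) {
      g <- sample.int(nrow(big), 1L)
      ws <- big$start[g] + 150L +
        sample.int(max(1L, big$end[g] - big$start[g] - 600L), 1L) - 1L
      we <- min(ws + 300L, big$end[g] - 150L)
      if (we - ws < 100L) next
      decoys <- rbind(decoys, data.frame(start = ws, end = we))
      strand <- sample(c("+", "-"), 1L)
      nh <- stats::rpois(1, params$hits_per_coding_kb * (we - ws) / 1000)
      for (h in seq_len(nh)) {
        l <- min(sample_len(), we - ws)
        s <- ws + sample.int(max(1L, we - ws - l + 1L), 1L) - 1L
        e <- min(s + l, we)
        k <- if (strand == "+") frame_plus(s) else abs(frame_minus(e, L))
        if (e - s >= 3L) add(s, e, strand, k, params$coding_bitscore_range)
      }
    }
    hits <- if (length(rows)) do.call(rbind, rows) else
      data.frame(query_id = character(), subject_id = character(),
                 q_start = integer(), q_end = integer(),
                 s_start = integer(), s_end = integer(),
                 e_value = numeric(), bit_score = numeric(),
                 frame = integer(), stringsAsFactors = FALSE)
    rownames(hits) <- NULL
    attr(hits, "decoy_windows") <- decoys
    hits
  })
}

#' Small protein database from the planted ORFs
#'
#' Translates each planted region and applies random point substitutions —
#' a convenience for driving a real translated-search backend over a
#' fixture, not an evolutionary model.
#'
#' @param fixture a [generate_genome()] result.
#' @param n_variants mutated copies per planted peptide.
#' @param mutation_rate per-residue substitution probability.
#' @param seed RNG seed.
#' @return named character vector of protein sequences.
#' @export
fixture_protein_db <- function(fixture, n_variants = 3L,
                               mutation_rate = 0.05, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    out <- character(); ids <- character()
    for (i in seq_len(nrow(fixture$regions))) {
      pep <- sub("\\*$", "", fixture$regions$peptide[i])
      for (v in seq_len(n_variants)) {
        p <- strsplit(pep, "", fixed = TRUE)[[1]]
        mut <- stats::runif(length(p)) < mutation_rate
        p[mut] <- aa[sample.int(20L, sum(mut), replace = TRUE)]
        out <- c(out, paste(p, collapse = ""))
        ids <- c(ids, sprintf("%s_var%d", fixture$regions$region_id[i], v))
      }
    }
    stats::setNames(out, ids)
  })
}

#' Write a protein FASTA
#'
#' @param seqs named character vector of protein sequences.
#' @param path output path.
#' @export
write_protein_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
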