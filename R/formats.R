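# Readers/writers for the plain-text formats the pipeline touches.  All
# coordinate-dialect normalization happens here: files carry their native
# conventions (GFF3/BLAST 1-based inclusive, BED/bedGraph 0-based half-open);
# everything in memory is 0-based half-open on the plus strand.

read_lines_norm <- function(path) {
  x <- readLines(path, warn = FALSE)
  sub("\r$", "", x)
}

#' Read a multi-record nucleotide FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences (ambiguity codes
#'   preserved); names are the first whitespace-delimited token of each
#'   header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("read_fasta: duplicate sequence id '%s' in %s",
                 ids[anyDuplicated(ids)], path), call. = FALSE)
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop(sprintf("read_fasta: empty sequence '%s' in %s",
                 ids[which(Biostrings::width(set) == 0L)[1]], path),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read annotation elements from a GFF3 file
#'
#' Parses the standard 9-column GFF3 dialect, converting 1-based inclusive
#' coordinates to the internal 0-based half-open convention and keeping only
#' the requested feature kinds.
#'
#' @param path GFF3 file path.
#' @param feature_kinds character vector of feature types (column 3) to
#'   keep, a subset of `c("gene", "exon", "CDS", "pseudogene")`.
#' @return `data.frame` with columns `element_id`, `kind`, `chrom`, `start`,
#'   `end`, `strand`, `phase` (`NA` except for CDS), `parent_id` (`NA` when
#'   no `Parent` attribute is present).
#' @export
read_gff3_elements <- function(path,
                               feature_kinds = c("gene", "exon", "CDS",
                                                 "pseudogene")) {
  allowed <- c("gene", "exon", "CDS", "pseudogene")
  if (!all(feature_kinds %in% allowed)) {
    stop("read_gff3_elements: feature_kinds must be a subset of gene/exon/CDS/pseudogene",
         call. = FALSE)
  }
  lines <- read_lines_norm(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop(sprintf("read_gff3_elements: line %d of %s has %d columns (9 expected)",
                   lineno[i], path, length(f)), call. = FALSE)
    }
    if (!f[3] %in% feature_kinds) next
    s1 <- suppressWarnings(as.integer(f[4]))
    e1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(s1) || is.na(e1)) {
      stop(sprintf("read_gff3_elements: line %d of %s: unparsable coordinates",
                   lineno[i], path), call. = FALSE)
    }
    if (e1 < s1) {
      stop(sprintf("read_gff3_elements: line %d of %s: end (%d) < start (%d)",
                   lineno[i], path, e1, s1), call. = FALSE)
    }
    attrs <- f[9]
    id <- gff3_attr(attrs, "ID")
    parent <- gff3_attr(attrs, "Parent")
    phase <- if (f[3] == "CDS") suppressWarnings(as.integer(f[8])) else NA_integer_
    if (f[3] == "CDS" && (is.na(phase) || !phase %in% 0:2)) {
      stop(sprintf("read_gff3_elements: line %d of %s: CDS without a valid phase",
                   lineno[i], path), call. = FALSE)
    }
    out[[i]] <- data.frame(
      element_id = if (is.na(id)) sprintf("%s_line%d", f[3], lineno[i]) else id,
      kind = f[3], chrom = f[1],
      start = s1 - 1L, end = e1,
      strand = if (f[7] %in% c("+", "-")) f[7] else "*",
      phase = phase, parent_id = parent,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(element_id = character(), kind = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), phase = integer(),
                      parent_id = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs))[[1]]
  if (length(m) == 2L) m[2] else NA_character_
}

#' Write annotation elements as GFF3
#'
#' Inverse of [read_gff3_elements()] for the fields that function declares.
#'
#' @param elements element table as returned by [read_gff3_elements()].
#' @param path output path.
#' @param source value for GFF3 column 2.
#' @param header_comments optional character vector written as `#` comment
#'   lines after the version pragma.
#' @export
write_gff3_elements <- function(elements, path, source = "protomotif",
                                header_comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(header_comments)) writeLines(paste0("# ", header_comments), con)
  if (nrow(elements)) {
    attrs <- paste0("ID=", elements$element_id)
    has_parent <- !is.na(elements$parent_id)
    attrs[has_parent] <- paste0(attrs[has_parent], ";Parent=",
                                elements$parent_id[has_parent])
    writeLines(paste(elements$chrom, source, elements$kind,
                     elements$start + 1L, elements$end,
                     ".", elements$strand,
                     ifelse(is.na(elements$phase), ".", elements$phase),
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BLAST-style tabular hit report
#'
#' Supports the standard 12-column tabular dialect (`std12`: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore)
#' and a 13-column extension with a trailing query-frame column
#' (`std12+qframe`).  Records with `q_start > q_end` (minus-strand hits) are
#' retained as printed; normalization to internal coordinates happens in
#' [filter_and_map()].  Lines starting with `#` are skipped.
#'
#' @param path report path.
#' @param dialect `"std12"` or `"std12+qframe"`.
#' @return `data.frame` with columns `query_id`, `subject_id`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`, `frame` (`NA`
#'   for the 12-column dialect).
#' @export
read_blast_tabular <- function(path, dialect = c("std12", "std12+qframe")) {
  dialect <- match.arg(dialect)
  ncol_want <- if (dialect == "std12") 12L else 13L
  lines <- read_lines_norm(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      e_value = numeric(), bit_score = numeric(),
                      frame = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc != ncol_want)) {
    i <- which(nc != ncol_want)[1]
    stop(sprintf("read_blast_tabular: line %d of %s has %d columns (%d expected for dialect %s)",
                 lineno[i], path, nc[i], ncol_want, dialect), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = ncol_want, byrow = TRUE)
  num <- function(col, what, integer = FALSE) {
    v <- suppressWarnings(if (integer) as.integer(m[, col]) else as.numeric(m[, col]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("read_blast_tabular: line %d of %s: unparsable %s '%s'",
                   lineno[i], path, what, m[i, col]), call. = FALSE)
    }
    v
  }
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    q_start = num(7L, "qstart", TRUE), q_end = num(8L, "qend", TRUE),
    s_start = num(9L, "sstart", TRUE), s_end = num(10L, "send", TRUE),
    e_value = num(11L, "evalue"), bit_score = num(12L, "bitscore"),
    frame = if (ncol_want == 13L) num(13L, "qframe", TRUE) else NA_integer_,
    stringsAsFactors = FALSE)
  if (any(hits$e_value < 0)) {
    stop("read_blast_tabular: negative e-value", call. = FALSE)
  }
  if (ncol_want == 13L && !all(hits$frame %in% c(-3:-1, 1:3))) {
    stop("read_blast_tabular: frame column outside {-3..-1, 1..3}", call. = FALSE)
  }
  hits
}

#' Write a hit table in BLAST tabular format
#'
#' @param hits hit table as returned by [read_blast_tabular()] (percent
#'   identity / alignment-length bookkeeping columns are emitted as
#'   placeholders when absent).
#' @param path output path.
#' @param dialect `"std12"` or `"std12+qframe"`.
#' @param header_comments optional `#` comment lines.
#' @export
write_blast_tabular <- function(hits, path,
                                dialect = c("std12", "std12+qframe"),
                                header_comments = character()) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments)) writeLines(paste0("# ", header_comments), con)
  if (nrow(hits)) {
    alen <- ceiling(abs(hits$q_end - hits$q_start + 1L) / 3)
    base <- paste(hits$query_id, hits$subject_id, "100.00", alen, 0L, 0L,
                  hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                  format(hits$e_value, scientific = TRUE, digits = 3),
                  format(round(hits$bit_score, 1), nsmall = 1, trim = TRUE),
                  sep = "\t")
    if (dialect == "std12+qframe") base <- paste(base, hits$frame, sep = "\t")
    writeLines(base, con)
  }
  invisible(path)
}

#' Write a depth profile as bedGraph
#'
#' Emits runs of constant non-zero depth as 0-based half-open bedGraph
#' records.  The chromosome length and strand are recorded in comment lines
#' so [read_profile_bedgraph()] can reconstruct the identical profile
#' (including trailing zero-depth positions).
#'
#' @param profile a [depth_profile()].
#' @param path output path.
#' @export
write_profile_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"protomotif depth %s (%s)\"",
                     profile$chrom, profile$strand), con)
  writeLines(sprintf("# chrom=%s chrom_length=%d strand=%s",
                     profile$chrom, length(profile$depth), profile$strand), con)
  r <- rle(profile$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  nz <- r$values != 0L
  if (any(nz)) {
    writeLines(paste(profile$chrom, starts[nz], ends[nz], r$values[nz],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph written by [write_profile_bedgraph()]
#'
#' @param path bedGraph path.
#' @return a [depth_profile()].
#' @export
read_profile_bedgraph <- function(path) {
  lines <- read_lines_norm(path)
  meta <- grep("^# chrom=", lines, value = TRUE)
  if (!length(meta)) {
    stop("read_profile_bedgraph: missing '# chrom=... chrom_length=... strand=...' metadata line",
         call. = FALSE)
  }
  m <- regmatches(meta[1], regexec(
    "^# chrom=(\\S+) chrom_length=(\\d+) strand=([+-])", meta[1]))[[1]]
  if (length(m) != 4L) {
    stop("read_profile_bedgraph: malformed metadata line", call. = FALSE)
  }
  L <- as.integer(m[3])
  depth <- integer(L)
  data <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  for (ln in data) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    s <- as.integer(f[2]); e <- as.integer(f[3])
    depth[(s + 1L):e] <- as.integer(f[4])
  }
  depth_profile(m[2], m[4], depth)
}

#' Write called coding-signals as BED6
#'
#' One line per signal: chrom, start, end, name, score = peak-height,
#' strand; sorted by (chrom, start).
#'
#' @param signals signal table as returned by [call_coding_signals()].
#' @param path output path.
#' @export
write_signals_bed <- function(signals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(signals)) {
    o <- order(signals$chrom, signals$start)
    signals <- signals[o, , drop = FALSE]
    name <- if ("name" %in% names(signals)) signals$name else
      sprintf("signal_%d", seq_len(nrow(signals)))
    writeLines(paste(signals$chrom, signals$start, signals$end, name,
                     signals$peak_height, signals$strand, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BED6 coding-signal file
#'
#' @param path BED6 path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `peak_height`, `strand`.
#' @export
read_signals_bed <- function(path) {
  lines <- read_lines_norm(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), peak_height = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 6L)) {
    stop(sprintf("read_signals_bed: line %d of %s is not BED6",
                 which(lengths(fields) != 6L)[1], path), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]), name = m[, 4],
             peak_height = as.integer(m[, 5]), strand = m[, 6],
             stringsAsFactors = FALSE)
}
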