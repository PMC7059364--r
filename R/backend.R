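#' Run a local translated search backend (NCBI blastx)
#'
#' Convenience wrapper that formats a protein database with `makeblastdb`
#' and runs `blastx` on a genomic FASTA, requesting tabular output with the
#' query-frame column so the resulting report can be fed straight to
#' [read_blast_tabular()] with dialect `"std12+qframe"`.  The rest of the
#' pipeline never assumes this ran: precomputed reports are equally valid
#' input.
#'
#' @param genome_fasta_path nucleotide query FASTA.
#' @param protein_db_path protein FASTA to search against.
#' @param params a [profiler_params()]; `e_value_max` and
#'   `low_complexity_filter` are forwarded to blastx (`-evalue`, `-seg`).
#'   Bit-score filtering is applied downstream by [filter_and_map()].
#' @param out_path path for the tabular report (default: a tempfile).
#' @return the report path, invisibly usable with
#'   `read_blast_tabular(dialect = "std12+qframe")`.
#' @export
run_search_backend <- function(genome_fasta_path, protein_db_path,
                               params = profiler_params(),
                               out_path = tempfile(fileext = ".tsv")) {
  blastx <- Sys.which("blastx")
  makedb <- Sys.which("makeblastdb")
  if (!nzchar(blastx) || !nzchar(makedb)) {
    stop("run_search_backend: NCBI BLAST+ (blastx/makeblastdb) not found on PATH; ",
         "supply a precomputed tabular report to read_blast_tabular() instead",
         call. = FALSE)
  }
  dbdir <- tempfile("blastdb")
  dir.create(dbdir)
  on.exit(unlink(dbdir, recursive = TRUE), add = TRUE)
  dbprefix <- file.path(dbdir, "db")
  res <- system2(makedb, c("-in", shQuote(protein_db_path), "-dbtype", "prot",
                           "-out", shQuote(dbprefix)),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0L) {
    stop("run_search_backend: makeblastdb failed:\n",
         paste(res, collapse = "\n"), call. = FALSE)
  }
  fmt <- "6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore qframe"
  args <- c("-query", shQuote(genome_fasta_path), "-db", shQuote(dbprefix),
            "-outfmt", shQuote(fmt),
            "-evalue", format(params$e_value_max, scientific = FALSE),
            "-seg", if (params$low_complexity_filter) "yes" else "no",
            "-out", shQuote(out_path))
  res <- system2(blastx, args, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0L) {
    unlink(out_path)
    stop("run_search_backend: blastx failed:\n",
         paste(res, collapse = "\n"), call. = FALSE)
  }
  out_path
}
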