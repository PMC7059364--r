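#' Six-frame translation with genomic coordinate maps
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code.  Frames `+1..+3` read the sequence at offsets
#' 0..2; frames `-1..-3` read the reverse complement at offsets 0..2.
#' Codons containing `N` translate to `X`; stop codons are rendered as `*`
#' (no ORF splitting).  Each peptide position maps back to the 0-based
#' half-open genomic interval of its codon, so frame `-k`'s first codon
#' covers the rightmost bases of the sequence.
#'
#' @param sequence nucleotide string over `A`, `C`, `G`, `T`, `N`; length
#'   at least 3.
#' @return named list over frames `"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`,
#'   `"-3"`; each element is a list with `peptide` (character string) and
#'   `codon_map` (two-column integer matrix `start`, `end`: the genomic
#'   interval of codon *i* in row *i*).
#' @examples
#' six_frame_translate("ATGAAA")[["+1"]]$peptide  # "MK"
#' @export
six_frame_translate <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 3L) {
    stop("six_frame_translate: sequence shorter than one codon", call. = FALSE)
  }
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (k in 1:3) {
    off <- k - 1L
    for (sgn in c(1L, -1L)) {
      src <- if (sgn > 0L) fwd else rev
      ncod <- (L - off) %/% 3L
      if (ncod < 1L) {
        pep <- ""
        cmap <- matrix(integer(), ncol = 2L,
                       dimnames = list(NULL, c("start", "end")))
      } else {
        sub <- Biostrings::subseq(src, off + 1L, off + 3L * ncod)
        pep <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                                  no.init.codon = TRUE))
        i <- seq_len(ncod)
        if (sgn > 0L) {
          s <- off + 3L * (i - 1L)
        } else {
          # codon i sits at offset off+3(i-1) on the reverse complement;
          # revcomp position j corresponds to genomic L-1-j
          s <- L - off - 3L * i
        }
        cmap <- cbind(start = s, end = s + 3L)
      }
      out[[sprintf("%+d", sgn * k)]] <- list(peptide = pep, codon_map = cmap)
    }
  }
  out[c("+1", "+2", "+3", "-1", "-2", "-3")]
}
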