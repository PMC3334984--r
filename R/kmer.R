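# Canonical k-mer counting over a genome assembly, built on Biostrings
# PDict/vcountPDict batch matching. A k-mer's count is the number of
# occurrences of the k-mer itself plus those of its reverse complement
# anywhere in the assembly (both strands collapsed). Odd k avoids
# palindromic double counting; the two default ks in this package (31 for
# copy number, 25 for probe tails) are both odd.

#' Count genomic occurrences of k-mers
#'
#' @param genome A [genome_assembly].
#' @param kmers Character vector of equal-length DNA words (may repeat).
#' @param canonical Count reverse-complement occurrences too (default).
#' @return Integer vector of occurrence counts aligned with `kmers`;
#'   `NA` for words containing non-ACGT characters.
#' @export
count_genome_kmers <- function(genome, kmers, canonical = TRUE) {
  stopifnot(inherits(genome, "genome_assembly"))
  if (length(kmers) == 0) return(integer())
  w <- unique(nchar(kmers))
  if (length(w) != 1) {
    abort("count_genome_kmers: k-mers must share one length",
          class = "snparray_invalid_config")
  }
  clean <- !grepl("[^ACGT]", kmers)
  out <- rep(NA_integer_, length(kmers))
  uq <- unique(kmers[clean])
  if (length(uq) == 0) return(out)
  pats <- Biostrings::DNAStringSet(uq)
  counts <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(pats),
                                            genome$seq))
  if (canonical) {
    rc <- Biostrings::reverseComplement(pats)
    counts <- counts +
      rowSums(Biostrings::vcountPDict(Biostrings::PDict(rc), genome$seq))
  }
  out[clean] <- as.integer(counts[match(kmers[clean], uq)])
  out
}

# 1-based inclusive substring of one assembly sequence.
genome_subseq <- function(genome, chrom, start, end) {
  i <- match(chrom, names(genome$seq))
  if (is.na(i)) {
    abort(paste0("unknown chromosome: ", chrom),
          class = "snparray_reference_mismatch")
  }
  as.character(Biostrings::subseq(genome$seq[[i]], start, end))
}
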