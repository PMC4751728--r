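#' The 88-bp protein G amplicon used throughout the benchmark
#'
#' The clonal target region is an 88-nt stretch of the protein G
#' antibody-interacting domain (including both primer annealing regions).
#' Its GC content (54.5 %) is within the typical range of human genes, which
#' makes it a reasonable stand-in for amplicon targets in rare-variant
#' applications.
#'
#' @return A single 88-character DNA string (A/C/G/T).
#' @examples
#' nchar(protein_g_template())  # 88
#' gc_content(protein_g_template())
#' @export
protein_g_template <- function() {
  paste0(
    "AGTACGCTAACGACAACGGTGTCGACGGTGAATGGACCTACGACGACGCT",
    "ACCAAAACCTTCACGGTTACCGAATCCGGAGGATCCGA"
  )
}

#' GC content of a DNA string
#'
#' @param x A character scalar over A/C/G/T/N.
#' @return Fraction of G+C among non-N bases, in `[0, 1]`.
#' @export
gc_content <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) > 0L)
  b <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  b <- b[b != "N"]
  mean(b %in% c("G", "C"))
}

#' Size of the random-tag space
#'
#' A tag of `tag_len` random nucleotides can take `4^tag_len` values; with the
#' default 16 combined random positions (8 per primer) the complexity is
#' about 4.3e9 per sample, so tag collisions among ~6e6 molecules are rare.
#'
#' @param tag_len Total number of random nucleotides (default 16).
#' @return Number of distinct tags (double, since 4^16 exceeds integer range).
#' @export
tag_space <- function(tag_len = 16L) {
  stopifnot(tag_len >= 1)
  4^tag_len
}

#' Expected sequenced copies per tagged molecule
#'
#' The sequencing depth divided by the number of tagged template molecules:
#' with ~30 million reads over ~6 million molecules one expects ~5 copies of
#' each tagged molecule to be sequenced.
#'
#' @param total_reads Total sequencing reads.
#' @param n_molecules Number of tagged input molecules.
#' @return Expected copies per tag (double).
#' @export
expected_copies_per_tag <- function(total_reads, n_molecules) {
  stopifnot(total_reads >= 0, n_molecules > 0)
  total_reads / n_molecules
}

# Reverse complement of a character vector of DNA strings (keeps N).
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
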