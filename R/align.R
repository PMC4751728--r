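# Local alignment against the reference amplicon and error classification.

#' Alignment scoring parameters
#'
#' The benchmark scores +1 for identical bases, -1 for a mismatch, -1 for
#' opening a gap and -0.5 for extending it, under the convention that a
#' length-g gap costs `gap_open + (g - 1) * gap_extend` (the first gap column
#' is charged the opening penalty only). N scores as a mismatch against any
#' base, including another N.
#'
#' @param match Match score (> 0, default 1).
#' @param mismatch Mismatch score (< 0, default -1).
#' @param gap_open Gap opening score (default -1).
#' @param gap_extend Gap extension score (default -0.5); must satisfy
#'   `gap_open <= gap_extend <= 0`.
#' @return A `scoring_params` object.
#' @export
scoring_params <- function(match = 1, mismatch = -1,
                           gap_open = -1, gap_extend = -0.5) {
  stopifnot(match > 0, mismatch < 0, gap_open <= gap_extend, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 mode = "local"),
            class = "scoring_params")
}

subst_matrix <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m)[1:4] <- params$match
  m
}

# Map our gap convention (first gap column costs gap_open, later columns
# gap_extend) onto pairwiseAlignment's (a length-g gap costs
# gapOpening + g * gapExtension).
pa_gap <- function(params) {
  list(opening = params$gap_extend - params$gap_open,
       extension = -params$gap_extend)
}

# Shared pairwiseAlignment call; queries as character vector.
pa_align <- function(queries, reference, params) {
  gp <- pa_gap(params)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries),
    Biostrings::DNAString(reference),
    substitutionMatrix = subst_matrix(params),
    gapOpening = gp$opening,
    gapExtension = gp$extension,
    type = "local"
  )
}

#' Local alignment of reads against the reference
#'
#' Maximal-scoring Smith-Waterman local alignment under the benchmark
#' scoring. Ties between co-optimal alignments are resolved by the aligner's
#' deterministic traceback, so repeated runs give identical alignments. Note
#' that local alignment clips terminal mismatches: an error on the first or
#' last reference position scores better clipped than aligned, so the
#' reference termini cannot display errors (see the package vignette).
#'
#' @param query Character vector of read sequences over A/C/G/T/N.
#' @param reference Reference sequence (single string).
#' @param params A [scoring_params()].
#' @return Tibble with one row per query: `score`, `ref_start`, `ref_end`,
#'   `query_start`, `query_end` (1-based, inclusive), `aligned_ref`,
#'   `aligned_query` (gap symbol `-`).
#' @export
align_local <- function(query, reference, params = scoring_params()) {
  stopifnot(is.character(query), is.character(reference),
            length(reference) == 1L)
  if (length(query) == 0L) {
    return(tibble(score = numeric(0), ref_start = integer(0),
                  ref_end = integer(0), query_start = integer(0),
                  query_end = integer(0), aligned_ref = character(0),
                  aligned_query = character(0)))
  }
  if (any(!nzchar(query)) || !nzchar(reference)) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", c(query, reference)))) {
    stop("sequences must contain only A/C/G/T/N", call. = FALSE)
  }
  pa <- pa_align(query, reference, params)
  tibble(
    score = BiocGenerics::score(pa),
    ref_start = BiocGenerics::start(Biostrings::subject(pa)),
    ref_end = BiocGenerics::end(Biostrings::subject(pa)),
    query_start = BiocGenerics::start(Biostrings::pattern(pa)),
    query_end = BiocGenerics::end(Biostrings::pattern(pa)),
    aligned_ref = as.character(Biostrings::alignedSubject(pa)),
    aligned_query = as.character(Biostrings::alignedPattern(pa))
  )
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")
ERROR_TYPES <- c("transition", "transversion", "insertion", "deletion")

classify_substitution <- function(ref_base, obs_base, n_policy = "transversion") {
  out <- ifelse(paste0(ref_base, ">", obs_base) %in% TRANSITIONS,
                "transition", "transversion")
  if (n_policy == "separate") {
    out[ref_base == "N" | obs_base == "N"] <- "n"
  }
  out
}

#' Classify alignment discrepancies into error events
#'
#' Walks the alignment columns: a mismatch column is a transition (A<->G,
#' C<->T) or a transversion (the remaining base pairs); a query-gap column is
#' a deletion at that reference position; a reference-gap column is an
#' insertion assigned to the reference position immediately 5' of the
#' inserted base (position 0 for an insertion before the first aligned
#' base). A run of g gap columns yields g single-base events. A read N
#' against a reference base counts as a transversion by default
#' (`n_policy = "separate"` classes it as type `"n"` instead).
#'
#' @param aligned_ref,aligned_query Gapped alignment strings of equal length
#'   (gap symbol `-`), e.g. from [align_local()].
#' @param ref_start 1-based reference coordinate of the first aligned
#'   reference base.
#' @param n_policy `"transversion"` (default) or `"separate"`.
#' @return Tibble with `position` (1-based reference coordinate), `type`,
#'   `ref_base`, `obs_base` (`-` for the gap side of an indel).
#' @export
classify_errors <- function(aligned_ref, aligned_query, ref_start = 1L,
                            n_policy = c("transversion", "separate")) {
  n_policy <- match.arg(n_policy)
  stopifnot(length(aligned_ref) == 1L, length(aligned_query) == 1L,
            nchar(aligned_ref) == nchar(aligned_query))
  r <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  q <- strsplit(aligned_query, "", fixed = TRUE)[[1]]
  ref_pos <- ref_start - 1L + cumsum(r != "-")
  is_mm <- r != "-" & q != "-" & r != q
  is_del <- q == "-" & r != "-"
  is_ins <- r == "-" & q != "-"
  bind_rows(
    tibble(position = ref_pos[is_mm],
           type = classify_substitution(r[is_mm], q[is_mm], n_policy),
           ref_base = r[is_mm], obs_base = q[is_mm]),
    tibble(position = ref_pos[is_del], type = "deletion",
           ref_base = r[is_del], obs_base = "-"),
    # at a reference-gap column cumsum has not advanced, so ref_pos is
    # already the reference position immediately 5' of the insertion
    tibble(position = ref_pos[is_ins], type = "insertion",
           ref_base = "-", obs_base = q[is_ins])
  ) %>% arrange(position)
}

#' Probability of at least one error in the tag
#'
#' With a per-nucleotide error rate `p`, the chance that a tag of `L` random
#' nucleotides carries at least one error is `1 - (1 - p)^L`. A read whose
#' tag is hit leaves its true cluster and (almost always) founds a spurious
#' singleton cluster, which is why singleton tags are so abundant.
#'
#' @param p Per-nt error rate in `[0, 1]`.
#' @param L Tag length (default 16, the combined two-primer tag).
#' @return Probability in `[0, 1]`.
#' @export
tag_error_probability <- function(p, L = 16L) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("`p` must be in [0, 1]", call. = FALSE)
  }
  stopifnot(L >= 1)
  1 - (1 - p)^L
}
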