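# The four error-correction schemes and the Phred quality filter.
#
# Scheme 1: raw reads, no correction.
# Scheme 2: read-pairing consensus -- keep a pair only if the forward payload
#   equals the reverse complement of the reverse payload, exactly.
# Scheme 3: tag-clustering consensus -- group reads by the combined 16-nt tag
#   (per strand), drop groups smaller than min_group_size, keep a group only
#   if all member payloads are identical (strict unanimity, no majority vote).
# Scheme 4: scheme 2 followed by scheme 3 on the paired consensus reads.

new_consensus_result <- function(consensus, scheme, per_strand, discarded) {
  structure(list(consensus = consensus, scheme = scheme,
                 per_strand = per_strand, discarded = discarded),
            class = "consensus_result")
}

empty_consensus <- function() {
  tibble(sequence = character(0), scheme = integer(0), strand = character(0),
         support = integer(0), tag_key = character(0))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> scheme", x$scheme, "\n")
  ps <- x$per_strand
  for (i in seq_len(nrow(ps))) {
    cat(sprintf("  %-8s raw %d -> consensus %d (retention %.3f)\n",
                ps$strand[i], ps$raw_in[i], ps$retained[i],
                if (ps$raw_in[i] > 0) ps$retained[i] / ps$raw_in[i] else NA))
  }
  if (length(x$discarded)) {
    cat("  discarded:", paste(names(x$discarded), x$discarded,
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Retention of an error-correction scheme
#'
#' The fraction of raw reads that survive as consensus records; its
#' reciprocal is the per-nucleotide sequencing-cost fold increase.
#'
#' @param x A `consensus_result`.
#' @param by_strand If `TRUE`, return the per-strand retentions (the
#'   ec3f/ec3r convention: the tag-clustering scheme is measured against
#'   each strand's own raw total); otherwise pooled.
#' @return Retention fraction(s) in `[0, 1]`.
#' @export
retention <- function(x, by_strand = FALSE) {
  stopifnot(inherits(x, "consensus_result"))
  ps <- x$per_strand
  if (by_strand) {
    setNames(ps$retained / ps$raw_in, ps$strand)
  } else {
    sum(ps$retained) / sum(ps$raw_in)
  }
}

#' Scheme 1: raw reads (no correction)
#'
#' Pass-through: every demultiplexed read becomes its own consensus record
#' with support 1; forward and reverse streams are kept separate.
#'
#' @param records Per-mate record tibble (from [extract_tag_payload()] or
#'   [tagged_records()]): columns `mate`, `payload`, optionally
#'   `combined_tag`.
#' @return A `consensus_result`.
#' @export
scheme1_raw <- function(records) {
  consensus <- tibble(
    sequence = records$payload,
    scheme = 1L,
    strand = records$mate,
    support = 1L,
    tag_key = if ("combined_tag" %in% names(records))
      records$combined_tag else NA_character_
  )
  per_strand <- consensus %>%
    count(strand, name = "raw_in") %>%
    mutate(retained = raw_in)
  if (nrow(per_strand) == 0L) {
    per_strand <- tibble(strand = character(0), raw_in = integer(0),
                         retained = integer(0))
  }
  new_consensus_result(consensus, 1L, per_strand, integer(0))
}

#' Scheme 2: read-pairing consensus
#'
#' A pair is retained iff the forward payload equals the reverse complement
#' of the reverse payload, exactly (N is an ordinary fifth symbol: it matches
#' only an N at the mirrored position). A retained pair emits one consensus
#' record -- the forward payload, support 2. Pairs with unequal payload
#' lengths are counted separately from sequence mismatches.
#'
#' @param pairs Pair tibble from [as_read_pairs()] / [pair_records()].
#' @return A `consensus_result` (strand `"paired"`, raw reads counted as
#'   2 per pair).
#' @export
scheme2_read_pairing <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(new_consensus_result(
      empty_consensus(), 2L,
      tibble(strand = "paired", raw_in = 0L, retained = 0L),
      c(mate_mismatch = 0L, length_mismatch = 0L)))
  }
  len_ok <- nchar(pairs$fwd_payload) == nchar(pairs$rev_payload)
  match_ <- rep(FALSE, n)
  match_[len_ok] <- pairs$fwd_payload[len_ok] ==
    revcomp_chr(pairs$rev_payload[len_ok])
  kept <- pairs[match_, , drop = FALSE]
  consensus <- tibble(
    sequence = kept$fwd_payload,
    scheme = 2L,
    strand = "paired",
    support = 2L,
    tag_key = kept$combined_tag
  ) %>% arrange(tag_key)
  new_consensus_result(
    consensus, 2L,
    tibble(strand = "paired", raw_in = 2L * n, retained = nrow(consensus)),
    c(mate_mismatch = sum(len_ok & !match_),
      length_mismatch = sum(!len_ok))
  )
}

# Unanimity grouping shared by schemes 3 and 4: bucket sequences by tag key,
# drop small groups, keep a group only if all members are identical.
unanimous_groups <- function(tag_key, sequences, min_group_size) {
  g <- tibble(tag_key = tag_key, sequence = sequences) %>%
    group_by(tag_key) %>%
    summarise(size = n(), uniq = n_distinct(sequence),
              sequence = first(sequence), .groups = "drop")
  list(
    emitted = g %>% filter(size >= min_group_size, uniq == 1L) %>%
      arrange(tag_key),
    n_groups = nrow(g),
    n_small = sum(g$size < min_group_size),
    n_discordant = sum(g$size >= min_group_size & g$uniq > 1L)
  )
}

#' Scheme 3: tag-clustering consensus
#'
#' Reads are bucketed by the exact combined 16-nt tag key, independently on
#' the forward-read and the reverse-read stream. Groups smaller than
#' `min_group_size` are discarded; a surviving group is emitted as one
#' consensus record iff all member payloads are identical, otherwise the
#' whole group is discarded. Consensus records are emitted in lexicographic
#' tag-key order.
#'
#' @param records Per-mate record tibble with `combined_tag` (see
#'   [tagged_records()]).
#' @param min_group_size Minimum reads per group (default 3).
#' @return A `consensus_result` with per-strand retention bookkeeping.
#' @export
scheme3_tag_clustering <- function(records, min_group_size = 3L) {
  stopifnot(min_group_size >= 1L,
            "combined_tag" %in% names(records))
  strands <- unique(records$mate)
  cons <- list()
  ps <- list()
  disc <- c(groups_small = 0L, groups_discordant = 0L)
  for (s in strands) {
    r <- records[records$mate == s, , drop = FALSE]
    u <- unanimous_groups(r$combined_tag, r$payload, min_group_size)
    cons[[s]] <- tibble(
      sequence = u$emitted$sequence, scheme = 3L, strand = s,
      support = u$emitted$size, tag_key = u$emitted$tag_key
    )
    ps[[s]] <- tibble(strand = s, raw_in = nrow(r),
                      retained = nrow(u$emitted))
    disc <- disc + c(groups_small = u$n_small,
                     groups_discordant = u$n_discordant)
  }
  new_consensus_result(bind_rows(cons), 3L, bind_rows(ps), disc)
}

#' Scheme 4: combined consensus (read-pairing then tag-clustering)
#'
#' Literally the composition: [scheme2_read_pairing()] is applied first, and
#' the surviving paired consensus reads are grouped by combined tag with the
#' same minimum-size and unanimity rules as scheme 3 -- grouping runs on the
#' paired reads, not per strand.
#'
#' @param pairs Pair tibble.
#' @param min_group_size Minimum paired reads per group (default 3).
#' @return A `consensus_result`; `support` counts underlying raw reads
#'   (2 per paired read), retention is measured against all raw reads.
#' @export
scheme4_combined <- function(pairs, min_group_size = 3L) {
  s2 <- scheme2_read_pairing(pairs)
  u <- unanimous_groups(s2$consensus$tag_key, s2$consensus$sequence,
                        min_group_size)
  consensus <- tibble(
    sequence = u$emitted$sequence, scheme = 4L, strand = "paired",
    support = 2L * u$emitted$size, tag_key = u$emitted$tag_key
  )
  new_consensus_result(
    consensus, 4L,
    tibble(strand = "paired", raw_in = 2L * nrow(pairs),
           retained = nrow(consensus)),
    c(s2$discarded,
      groups_small = u$n_small, groups_discordant = u$n_discordant)
  )
}

min_phred <- function(quals) {
  n <- length(quals)
  if (n == 0L) return(integer(0))
  len <- nchar(quals)
  if (length(unique(len)) == 1L) {
    m <- matrix(as.integer(charToRaw(paste(quals, collapse = ""))),
                nrow = len[1L])
    mins <- m[1L, ]
    if (len[1L] > 1L) for (i in 2:len[1L]) mins <- pmin(mins, m[i, ])
    mins - 33L
  } else {
    vapply(quals, function(q) min(as.integer(charToRaw(q))), 0L,
           USE.NAMES = FALSE) - 33L
  }
}

#' Phred quality filter over the target region
#'
#' Discards a read if any payload base has Phred quality below `threshold`
#' (default 30). The filter looks only at the 88-bp target region -- low
#' quality in the trimmed 12-bp prefix does not discard a read. Applied to a
#' pair tibble, both mates must pass. Usable as a pre-filter to any scheme.
#'
#' @param x A per-mate record tibble (column `payload_quals`) or a pair
#'   tibble (columns `fwd_quals`, `rev_quals`).
#' @param threshold Minimum acceptable Phred score (default 30).
#' @return List with `retained` (filtered tibble) and `counts`
#'   (`reads_in`/`pairs_in`, `retained`, `filtered`).
#' @export
quality_filter <- function(x, threshold = 30L) {
  if ("payload_quals" %in% names(x)) {
    ok <- min_phred(x$payload_quals) >= threshold
    nm <- "reads_in"
  } else if (all(c("fwd_quals", "rev_quals") %in% names(x))) {
    ok <- min_phred(x$fwd_quals) >= threshold &
      min_phred(x$rev_quals) >= threshold
    nm <- "pairs_in"
  } else {
    stop("`x` must carry `payload_quals` or `fwd_quals`/`rev_quals`",
         call. = FALSE)
  }
  list(retained = x[ok, , drop = FALSE],
       counts = setNames(c(nrow(x), sum(ok), sum(!ok)),
                         c(nm, "retained", "filtered")))
}

#' Ideal retention fractions under zero errors
#'
#' With error-free reads and exactly `c` copies per tagged molecule, the
#' read-pairing scheme keeps one consensus per 2 raw reads (50 %), the
#' tag-clustering scheme one per `c` reads in a stream, and the combined
#' scheme one per `2c` reads. Note the singleton limit: at `c = 1` the
#' closed form gives 1.0 for tag-clustering, but the minimum group size of 3
#' makes realized retention 0 -- the closed form deliberately describes the
#' grouping arithmetic, not the size cut-off.
#'
#' @param c Copies per tagged molecule (>= 1).
#' @return Named numeric vector `scheme2`, `scheme3`, `scheme4`.
#' @export
ideal_retention <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 1) {
    stop("`c` must be a single number >= 1", call. = FALSE)
  }
  c(scheme2 = 0.5, scheme3 = 1 / c, scheme4 = 0.5 / c)
}

#' Run all four schemes over one demultiplexed pair set
#'
#' Convenience orchestration used by the analysis drivers: optionally
#' applies the quality filter first (per read for schemes 1 and 3, per pair
#' for schemes 2 and 4), then runs the four schemes.
#'
#' @param pairs Pair tibble from [as_read_pairs()].
#' @param min_group_size Minimum group size for schemes 3/4 (default 3).
#' @param quality_threshold If non-`NULL`, apply [quality_filter()] at this
#'   Phred threshold before each scheme.
#' @return Named list of `consensus_result`s: `s1`, `s2`, `s3`, `s4`.
#' @export
run_schemes <- function(pairs, min_group_size = 3L, quality_threshold = NULL) {
  records <- tagged_records(pairs)
  pairs_in <- pairs
  if (!is.null(quality_threshold)) {
    records <- quality_filter(records, quality_threshold)$retained
    pairs_in <- quality_filter(pairs, quality_threshold)$retained
  }
  list(
    s1 = scheme1_raw(records),
    s2 = scheme2_read_pairing(pairs_in),
    s3 = scheme3_tag_clustering(records, min_group_size),
    s4 = scheme4_combined(pairs_in, min_group_size)
  )
}
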