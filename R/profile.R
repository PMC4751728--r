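# Per-position error-rate profiles: align every (consensus) read locally to
# the reference, classify discrepancies, accumulate counts over a
# position x error-type matrix with an alignment-spanning coverage
# denominator.

new_error_profile <- function(counts, coverage, labels, n_records,
                              n_unalignable, reference) {
  structure(list(counts = counts, coverage = coverage, labels = labels,
                 n_records = n_records, n_unalignable = n_unalignable,
                 reference = reference),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  lb <- x$labels
  cat("<error_profile>",
      paste(names(lb), unlist(lapply(lb, format)), sep = "=", collapse = " "),
      "\n  ", x$n_records, "records aligned,", x$n_unalignable,
      "unalignable;", sum(x$counts), "error events over",
      nrow(x$counts), "positions\n")
  invisible(x)
}

#' Build a per-position error profile for one stratum
#'
#' Aligns every record locally against the reference (see [align_local()]),
#' classifies each discrepancy as transition, transversion, insertion or
#' deletion, and accumulates counts per 1-based reference position. Coverage
#' at a position is the number of records whose local alignment spans it
#' (local alignment may clip read ends, so coverage is not simply the record
#' count). Records scoring below `min_score` are counted as unalignable and
#' excluded from coverage. Insertions before the first aligned reference
#' base (position 0) cannot survive an optimal local alignment and are
#' dropped if they arise.
#'
#' Input sequences must be in reference orientation; use
#' [profile_consensus()] to profile scheme output with automatic
#' reverse-complementing of the reverse stream.
#'
#' @param sequences Character vector of payload/consensus sequences.
#' @param reference Reference amplicon (single string).
#' @param params A [scoring_params()].
#' @param min_score Minimum alignment score to accept a record (default 40).
#' @param scheme,strand,replicate Stratum labels stored on the profile.
#' @param n_policy How a read N against a reference base is classed:
#'   `"transversion"` (default; the benchmark counted the N-rich
#'   position-57 events as transversions) or `"separate"` (own `"n"` type).
#' @return An `error_profile`: list with `counts` (position x type matrix),
#'   `coverage`, `labels`, `n_records`, `n_unalignable`, `reference`.
#' @export
build_profile <- function(sequences, reference, params = scoring_params(),
                          min_score = 40,
                          scheme = NA, strand = NA_character_,
                          replicate = NA_character_,
                          n_policy = c("transversion", "separate")) {
  n_policy <- match.arg(n_policy)
  L <- nchar(reference)
  types <- if (n_policy == "separate") c(ERROR_TYPES, "n") else ERROR_TYPES
  counts <- matrix(0L, nrow = L, ncol = length(types),
                   dimnames = list(NULL, types))
  labels <- list(scheme = scheme, strand = strand, replicate = replicate)
  if (length(sequences) == 0L) {
    return(new_error_profile(counts, integer(L), labels, 0L, 0L, reference))
  }
  stopifnot(!anyNA(sequences), all(nzchar(sequences)))

  pa <- pa_align(sequences, reference, params)
  sc <- BiocGenerics::score(pa)
  keep <- which(sc >= min_score)
  n_unalignable <- length(sequences) - length(keep)
  if (length(keep) == 0L) {
    return(new_error_profile(counts, integer(L), labels, 0L,
                             n_unalignable, reference))
  }
  pa <- pa[keep]
  seqs <- sequences[keep]
  subj <- Biostrings::subject(pa)
  patt <- Biostrings::pattern(pa)
  st <- BiocGenerics::start(subj)
  en <- BiocGenerics::end(subj)
  qst <- BiocGenerics::start(patt)
  qen <- BiocGenerics::end(patt)

  # coverage via difference array over [st, en]
  d <- integer(L + 1L)
  d[seq_len(L)] <- tabulate(st, L)
  dec <- tabulate(en + 1L, L + 1L)
  coverage <- cumsum(d - dec)[seq_len(L)]

  add_events <- function(pos, type) {
    ok <- pos >= 1L & pos <= L
    if (!all(ok)) { pos <- pos[ok]; type <- type[ok] }
    if (!length(pos)) return(invisible())
    t2 <- table(factor(type, levels = types), factor(pos, levels = seq_len(L)))
    counts <<- counts + t(t2)
  }

  # Gapless alignments with query position == reference position (the
  # overwhelming majority) are scored by direct byte comparison, which
  # avoids the expensive per-alignment string extraction; reads with gaps
  # (or a shifted gapless mapping) take a per-read column walk instead.
  gapless <- S4Vectors::elementNROWS(Biostrings::insertion(pa)) == 0L &
    S4Vectors::elementNROWS(Biostrings::deletion(pa)) == 0L
  lens <- nchar(seqs)
  fast <- which(gapless & st == qst & lens == lens[1L])
  walk <- setdiff(seq_along(pa), fast)

  if (length(fast)) {
    Lq <- lens[fast[1L]]
    Qb <- matrix(charToRaw(paste(seqs[fast], collapse = "")), nrow = Lq)
    refb <- charToRaw(reference)[seq_len(min(Lq, L))]
    mm <- which(Qb[seq_along(refb), , drop = FALSE] != refb)
    if (length(mm)) {
      ai <- arrayInd(mm, c(length(refb), length(fast)))
      pos <- ai[, 1L]
      ridx <- fast[ai[, 2L]]
      inside <- pos >= qst[ridx] & pos <= qen[ridx]  # clipped ends: no event
      pos <- pos[inside]
      if (length(pos)) {
        obs <- rawToChar(Qb[mm[inside]], multiple = TRUE)
        refc <- rawToChar(refb[pos], multiple = TRUE)
        add_events(pos, classify_substitution(refc, obs, n_policy))
      }
    }
  }
  if (length(walk)) {
    # Reconstruct events from the stored gap ranges with a two-pointer walk
    # over query and reference (far cheaper than extracting aligned
    # strings). insertion() ranges are relative to the aligned pattern
    # region, deletion() ranges to the aligned subject region.
    refb <- charToRaw(reference)
    insL <- Biostrings::insertion(pa)
    delL <- Biostrings::deletion(pa)
    acc_pos <- vector("list", length(walk))
    acc_type <- vector("list", length(walk))
    for (k in seq_along(walk)) {
      i <- walk[k]
      qb <- charToRaw(seqs[i])
      ir <- insL[[i]]
      dr <- delL[[i]]
      ins_s <- BiocGenerics::start(ir) + qst[i] - 1L
      ins_w <- BiocGenerics::width(ir)
      del_s <- BiocGenerics::start(dr) + st[i] - 1L
      del_w <- BiocGenerics::width(dr)
      qp <- qst[i]; rp <- st[i]; ii <- 1L; di <- 1L
      pos <- integer(0); type <- character(0)
      while (qp <= qen[i] || rp <= en[i]) {
        if (di <= length(del_s) && rp == del_s[di]) {
          w <- del_w[di]
          pos <- c(pos, rp:(rp + w - 1L))
          type <- c(type, rep.int("deletion", w))
          rp <- rp + w; di <- di + 1L
        } else if (ii <= length(ins_s) && qp == ins_s[ii]) {
          w <- ins_w[ii]
          pos <- c(pos, rep.int(rp - 1L, w))
          type <- c(type, rep.int("insertion", w))
          qp <- qp + w; ii <- ii + 1L
        } else if (qp <= qen[i] && rp <= en[i]) {
          if (qb[qp] != refb[rp]) {
            pos <- c(pos, rp)
            type <- c(type, classify_substitution(rawToChar(refb[rp]),
                                                  rawToChar(qb[qp]),
                                                  n_policy))
          }
          qp <- qp + 1L; rp <- rp + 1L
        } else {
          break  # inconsistent ranges; never reached for a valid alignment
        }
      }
      acc_pos[[k]] <- pos
      acc_type[[k]] <- type
    }
    add_events(unlist(acc_pos), unlist(acc_type))
  }

  new_error_profile(counts, coverage, labels, length(keep),
                    n_unalignable, reference)
}

#' Profile the output of an error-correction scheme
#'
#' Splits a [scheme1_raw()]/.../[scheme4_combined()] result by strand,
#' reverse-complements the reverse stream into reference orientation, and
#' builds one [build_profile()] per strand.
#'
#' @param result A `consensus_result`.
#' @param reference Reference amplicon.
#' @param replicate Replicate label for the profiles.
#' @param ... Passed on to [build_profile()].
#' @return Named list of `error_profile`s, one per strand present.
#' @export
profile_consensus <- function(result, reference, replicate = NA_character_,
                              ...) {
  stopifnot(inherits(result, "consensus_result"))
  strands <- unique(result$consensus$strand)
  out <- lapply(strands, function(s) {
    seqs <- result$consensus$sequence[result$consensus$strand == s]
    if (s == "reverse") seqs <- revcomp_chr(seqs)
    build_profile(seqs, reference, scheme = result$scheme, strand = s,
                  replicate = replicate, ...)
  })
  setNames(out, strands)
}

#' Sum two error profiles
#'
#' Profiles over the same reference and type set add element-wise: counts,
#' coverage and record tallies; differing labels collapse to `NA`.
#'
#' @param e1,e2 `error_profile` objects.
#' @return An `error_profile`.
#' @export
"+.error_profile" <- function(e1, e2) {
  stopifnot(identical(e1$reference, e2$reference),
            identical(colnames(e1$counts), colnames(e2$counts)))
  merge_lab <- function(a, b) if (identical(a, b)) a else NA
  new_error_profile(
    e1$counts + e2$counts,
    e1$coverage + e2$coverage,
    Map(merge_lab, e1$labels, e2$labels),
    e1$n_records + e2$n_records,
    e1$n_unalignable + e2$n_unalignable,
    e1$reference
  )
}

#' Tidy per-position error-rate table
#'
#' @param profile An `error_profile`.
#' @return Tibble with `scheme`, `strand`, `replicate`, `position`, `type`,
#'   `count`, `coverage`, `rate` (`NA` where coverage is 0).
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  L <- nrow(profile$counts)
  types <- colnames(profile$counts)
  tibble(
    scheme = profile$labels$scheme,
    strand = profile$labels$strand,
    replicate = profile$labels$replicate,
    position = rep(seq_len(L), times = length(types)),
    type = rep(types, each = L),
    count = as.integer(profile$counts),
    coverage = rep(profile$coverage, times = length(types))
  ) %>%
    mutate(rate = ifelse(coverage > 0, count / coverage, NA_real_))
}

#' Per-type summary of an error profile
#'
#' Median and mean of the per-position rates for each error type, over
#' positions with nonzero coverage.
#'
#' @param profile An `error_profile`.
#' @return Tibble with `type`, `n_positions`, `median_rate`, `mean_rate`.
#' @export
profile_summary <- function(profile) {
  profile_table(profile) %>%
    filter(coverage > 0) %>%
    group_by(type) %>%
    summarise(n_positions = n(),
              median_rate = median(rate),
              mean_rate = mean(rate),
              .groups = "drop")
}

#' Pooled error rate over selected positions and types
#'
#' Total error count divided by total coverage, restricted to the given
#' error types and reference positions. Because optimal local alignment
#' cannot place an error on the reference termini (terminal mismatches are
#' clipped), unbiased rate-recovery checks restrict to interior positions,
#' e.g. `positions = 3:86` on the 88-nt amplicon.
#'
#' @param profile An `error_profile`.
#' @param types Error types to pool (default the substitution types).
#' @param positions Reference positions to pool (default all).
#' @return A single rate (errors per sequenced nucleotide).
#' @export
mean_rate <- function(profile, types = c("transition", "transversion"),
                      positions = NULL) {
  stopifnot(inherits(profile, "error_profile"),
            all(types %in% colnames(profile$counts)))
  if (is.null(positions)) positions <- seq_len(nrow(profile$counts))
  sum(profile$counts[positions, types, drop = FALSE]) /
    sum(profile$coverage[positions])
}
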