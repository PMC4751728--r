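# Paired FASTQ input, replicate demultiplexing, and tag/payload extraction.

write_fastq <- function(ids, seqs, quals, path, suffix = "") {
  con <- file(path, "wt")
  on.exit(close(con))
  out <- character(4L * length(ids))
  out[seq(1L, length(out), 4L)] <- paste0("@", ids, suffix)
  out[seq(2L, length(out), 4L)] <- seqs
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- quals
  writeLines(out, con)
  invisible(path)
}

# Strict 4-line FASTQ reader (plain or gzip). Aborts on the first malformed
# record with its line number.
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(path, ": truncated FASTQ, ", n, " lines is not a multiple of 4",
         call. = FALSE)
  }
  hdr <- seq(1L, n, 4L)
  sep <- seq(3L, n, 4L)
  bad <- which(!startsWith(lines[hdr], "@"))
  if (length(bad)) {
    stop(path, ": line ", hdr[bad[1L]], ": expected '@' header", call. = FALSE)
  }
  bad <- which(!startsWith(lines[sep], "+"))
  if (length(bad)) {
    stop(path, ": line ", sep[bad[1L]], ": expected '+' separator",
         call. = FALSE)
  }
  seqs <- lines[seq(2L, n, 4L)]
  quals <- lines[seq(4L, n, 4L)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(path, ": line ", 4L * bad[1L],
         ": quality string length differs from sequence length", call. = FALSE)
  }
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) {
    stop(path, ": line ", 4L * bad[1L] - 2L,
         ": sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  tibble(read_id = sub("^@", "", lines[hdr]), seq = seqs, qual = quals)
}

#' Read a pair of FASTQ files as ordered mate pairs
#'
#' Mates are matched strictly by file order; read ids (after stripping a
#' trailing `/1`/`/2` or space-delimited comment) must correspond. Malformed
#' records abort with a line-numbered error.
#'
#' @param path_fwd,path_rev FASTQ files (plain or gzip), forward and reverse
#'   mates in the same order.
#' @return List with tibbles `fwd` and `rev` (`read_id`, `seq`, `qual`; ids
#'   have the mate suffix stripped), aligned row-by-row.
#' @export
read_paired_fastq <- function(path_fwd, path_rev) {
  for (p in c(path_fwd, path_rev)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  fwd <- read_fastq(path_fwd)
  rev_ <- read_fastq(path_rev)
  if (nrow(fwd) != nrow(rev_)) {
    shorter <- if (nrow(fwd) < nrow(rev_)) path_fwd else path_rev
    stop("unequal record counts (", nrow(fwd), " vs ", nrow(rev_),
         "); shorter file: ", shorter, call. = FALSE)
  }
  strip <- function(id) sub("[ /].*$", "", id)
  fwd$read_id <- strip(fwd$read_id)
  rev_$read_id <- strip(rev_$read_id)
  bad <- which(fwd$read_id != rev_$read_id)
  if (length(bad)) {
    stop("mate id mismatch at record ", bad[1L], ": '", fwd$read_id[bad[1L]],
         "' vs '", rev_$read_id[bad[1L]], "'", call. = FALSE)
  }
  list(fwd = fwd, rev = rev_)
}

#' Read prefix layout of a tagged amplicon read
#'
#' Describes how a raw read splits into the random tag, the 3-bp replicate
#' barcode, and the payload. With defaults, the first 12 bases are trimmed:
#' positions 1-4 and 8-11 are the 8 random tag nucleotides, positions 5-7 the
#' barcode, and position 12 (the first primer-annealing base) is ignored for
#' the tag key. The designed prefix is 11 nt while 12 bases are trimmed; both
#' are configurable because the one-base discrepancy is inherent to the
#' protocol description.
#'
#' @param n_prefix Random nt before the barcode (default 4).
#' @param barcode_len Barcode length (default 3).
#' @param n_suffix Random nt after the barcode (default 4).
#' @param trim_len Total prefix trimmed from the read (default 12).
#' @param payload_len Target-region length (default 88).
#' @return A `tag_layout` object.
#' @export
tag_layout <- function(n_prefix = 4L, barcode_len = 3L, n_suffix = 4L,
                       trim_len = 12L, payload_len = 88L) {
  stopifnot(n_prefix >= 0, barcode_len >= 1, n_suffix >= 0, payload_len >= 1,
            n_prefix + barcode_len + n_suffix <= trim_len)
  structure(list(n_prefix = as.integer(n_prefix),
                 barcode_len = as.integer(barcode_len),
                 n_suffix = as.integer(n_suffix),
                 trim_len = as.integer(trim_len),
                 payload_len = as.integer(payload_len)),
            class = "tag_layout")
}

#' Split raw reads into tag, barcode and payload
#'
#' Extraction is a pure slice: the tag is the `n_prefix` + `n_suffix` random
#' positions of the trimmed prefix, the barcode the `barcode_len` positions
#' between them, and the payload the `payload_len` bases after `trim_len`.
#' Reads shorter than `trim_len + payload_len` are discarded and counted.
#' Payloads containing N are retained (their fate is decided by the
#' downstream schemes and the profiling N policy).
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual` (one mate).
#' @param layout A [tag_layout()].
#' @param mate `"forward"` or `"reverse"`, recorded on each record.
#' @return List with `records` (tibble: `read_id`, `mate`, `barcode`, `tag`,
#'   `payload`, `payload_quals`) and `counts` (named integer vector:
#'   `reads_in`, `retained`, `too_short`).
#' @export
extract_tag_payload <- function(reads, layout = tag_layout(),
                                mate = c("forward", "reverse")) {
  mate <- match.arg(mate)
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  need <- layout$trim_len + layout$payload_len
  ok <- nchar(reads$seq) >= need
  r <- reads[ok, , drop = FALSE]
  tag <- paste0(
    substr(r$seq, 1L, layout$n_prefix),
    substr(r$seq, layout$n_prefix + layout$barcode_len + 1L,
           layout$n_prefix + layout$barcode_len + layout$n_suffix)
  )
  records <- tibble(
    read_id = r$read_id,
    mate = mate,
    barcode = substr(r$seq, layout$n_prefix + 1L,
                     layout$n_prefix + layout$barcode_len),
    tag = tag,
    payload = substr(r$seq, layout$trim_len + 1L, need),
    payload_quals = substr(r$qual, layout$trim_len + 1L, need)
  )
  list(records = records,
       counts = c(reads_in = nrow(reads), retained = nrow(records),
                  too_short = nrow(reads) - nrow(records)))
}

#' Pair forward and reverse tagged records by read id
#'
#' Joins the two mate streams on `read_id` (order of the forward stream is
#' preserved) and combines the two 8-nt tags into the 16-nt tag key used by
#' the tag-clustering schemes. Reads whose mate was discarded upstream are
#' counted as orphans.
#'
#' @param fwd_records,rev_records Record tibbles from
#'   [extract_tag_payload()] for the forward and reverse mate.
#' @return List with `pairs` (tibble: `read_id`, `barcode_fwd`,
#'   `barcode_rev`, `combined_tag`, `fwd_payload`, `rev_payload`,
#'   `fwd_quals`, `rev_quals`) and `counts` (`pairs`, `orphans`).
#' @export
pair_records <- function(fwd_records, rev_records) {
  f <- fwd_records[fwd_records$read_id %in% rev_records$read_id, , drop = FALSE]
  ridx <- match(f$read_id, rev_records$read_id)
  r <- rev_records[ridx, , drop = FALSE]
  pairs <- tibble(
    read_id = f$read_id,
    barcode_fwd = f$barcode,
    barcode_rev = r$barcode,
    combined_tag = paste0(f$tag, r$tag),
    fwd_payload = f$payload,
    rev_payload = r$payload,
    fwd_quals = f$payload_quals,
    rev_quals = r$payload_quals
  )
  orphans <- (nrow(fwd_records) - nrow(pairs)) +
    (nrow(rev_records) - nrow(pairs))
  list(pairs = pairs, counts = c(pairs = nrow(pairs), orphans = orphans))
}

#' Demultiplex read pairs by the 3-bp replicate barcode
#'
#' A pair is assigned to a replicate only when BOTH mates carry the same
#' mapped barcode (exact match; 3 bp is too short for mismatch tolerance).
#' All other pairs are discarded and counted, not errored.
#'
#' @param pairs Pair tibble from [pair_records()].
#' @param barcode_map Named character vector mapping barcode to replicate
#'   label, e.g. `c(ACA = "replicate1", GTG = "replicate2")` (the default).
#' @return List with `pairs` (retained pairs plus a `replicate` column) and
#'   `counts` (`pairs_in`, one entry per replicate, `inconsistent`,
#'   `unknown_barcode`).
#' @export
demultiplex <- function(pairs,
                        barcode_map = c(ACA = "replicate1", GTG = "replicate2")) {
  stopifnot(is.character(barcode_map), !is.null(names(barcode_map)))
  lab_f <- unname(barcode_map[pairs$barcode_fwd])
  lab_r <- unname(barcode_map[pairs$barcode_rev])
  known <- !is.na(lab_f) & !is.na(lab_r)
  consistent <- known & lab_f == lab_r
  out <- pairs[consistent, , drop = FALSE]
  out$replicate <- lab_f[consistent]
  per_rep <- table(factor(out$replicate, levels = unname(barcode_map)))
  counts <- c(pairs_in = nrow(pairs),
              setNames(as.integer(per_rep), names(per_rep)),
              inconsistent = sum(known & !consistent),
              unknown_barcode = sum(!known))
  list(pairs = out, counts = counts)
}

#' Extract demultiplexed read pairs from a simulated library in memory
#'
#' Convenience composition of [extract_tag_payload()], [pair_records()] and
#' [demultiplex()] applied directly to a `sim_library`, skipping the FASTQ
#' round trip (which is exercised separately by [write_library()] and
#' [read_paired_fastq()]).
#'
#' @param lib A `sim_library`.
#' @param layout A [tag_layout()].
#' @param barcode_map As in [demultiplex()]; defaults to the library's own
#'   barcode mapped to `"replicate1"`.
#' @return The `pairs` tibble (with `replicate` column).
#' @export
as_read_pairs <- function(lib, layout = tag_layout(), barcode_map = NULL) {
  stopifnot(inherits(lib, "sim_library"))
  if (is.null(barcode_map)) {
    barcode_map <- setNames("replicate1", lib$config$barcode)
  }
  f <- extract_tag_payload(lib$fwd, layout, "forward")
  r <- extract_tag_payload(lib$rev, layout, "reverse")
  p <- pair_records(f$records, r$records)
  demultiplex(p$pairs, barcode_map)$pairs
}

#' Explode read pairs into per-mate tagged records
#'
#' Returns one record per mate with the pair's combined 16-nt tag attached to
#' both mates, the form consumed by the per-strand tag-clustering scheme.
#'
#' @param pairs Pair tibble from [pair_records()] or [as_read_pairs()].
#' @return Tibble with `read_id`, `mate`, `combined_tag`, `payload`,
#'   `payload_quals`.
#' @export
tagged_records <- function(pairs) {
  bind_rows(
    tibble(read_id = pairs$read_id, mate = "forward",
           combined_tag = pairs$combined_tag,
           payload = pairs$fwd_payload, payload_quals = pairs$fwd_quals),
    tibble(read_id = pairs$read_id, mate = "reverse",
           combined_tag = pairs$combined_tag,
           payload = pairs$rev_payload, payload_quals = pairs$rev_quals)
  )
}
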