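# Synthetic clonal tagged amplicon libraries with recorded ground truth.
#
# Read layout (as sequenced, both mates): a 12-nt prefix -- 4 random tag nt,
# the 3-nt replicate barcode, 4 more random tag nt, and one fixed spacer base
# (the first primer-annealing base; 'A' on the forward primer, 'T' on the
# reverse) -- followed by the payload: the template (forward mate) or its
# reverse complement (reverse mate). Trimming the first 12 bases therefore
# leaves exactly the 88-bp target region.

PREFIX_LEN <- 12L

.bases <- c("A", "C", "G", "T")
.base_raw <- charToRaw("ACGT")
# byte -> 0:3 code lookup (index by as.integer(byte) + 1)
.base_code <- local({
  z <- rep(NA_integer_, 256L)
  z[as.integer(.base_raw) + 1L] <- 0:3
  z
})

random_tags <- function(n, len) {
  m <- matrix(sample(.bases, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate tagged template molecules
#'
#' Assigns every molecule an independent uniform-random tag (8 random nt per
#' primer, 16 combined; collisions are possible and are not deduplicated) and
#' a true sequence: the clonal template, or one of the planted variants drawn
#' by its population frequency.
#'
#' @param config A [sim_config()].
#' @return A `sim_molecules` object: list with `molecules` (tibble with
#'   columns `molecule_id`, `tag_fwd`, `tag_rev`, `tag`, `variant`,
#'   `true_seq`) and `config`.
#' @export
generate_molecules <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_molecules
    half <- config$tag_len_per_primer
    tag_fwd <- random_tags(n, half)
    tag_rev <- random_tags(n, half)
    pv <- config$planted_variants
    if (is.null(pv) || nrow(pv) == 0L) {
      variant <- rep.int(0L, n)
    } else {
      variant <- sample.int(nrow(pv) + 1L, n, replace = TRUE,
                            prob = c(1 - sum(pv$frequency), pv$frequency)) - 1L
    }
    true_seq <- ifelse(variant == 0L, config$template, NA_character_)
    if (any(variant > 0L)) {
      true_seq[variant > 0L] <- pv$sequence[variant[variant > 0L]]
    }
    molecules <- tibble(
      molecule_id = seq_len(n),
      tag_fwd = tag_fwd,
      tag_rev = tag_rev,
      tag = paste0(tag_fwd, tag_rev),
      variant = variant,
      true_seq = true_seq
    )
  })
  structure(list(molecules = molecules, config = config),
            class = "sim_molecules")
}

# Simulate one strand: substitution errors over the whole read (prefix
# optional), single-base indels over the payload, qualities coupled to error
# status. Returns list(seq, qual, events) where events is a tibble of
# injected errors in pre-indel read coordinates.
.sim_strand <- function(mol_reads, midx, mate, config) {
  L <- nchar(config$template)
  L_read <- PREFIX_LEN + L
  n <- length(midx)
  qm <- config$quality

  M <- matrix(unlist(lapply(mol_reads, charToRaw), use.names = FALSE),
              nrow = L_read)[, midx, drop = FALSE]
  Q <- matrix(as.raw(33L + qm$correct), nrow = L_read, ncol = n)

  sub_rate <- if (mate == "forward") config$sub_rate_fwd else config$sub_rate_rev
  rate_payload <- rep_len(sub_rate, L)              # reference coordinates
  hs <- config$hotspots
  if (!is.null(hs)) {
    hs <- hs[hs$strand == mate, , drop = FALSE]
    rate_payload[hs$position] <- hs$rate
  }
  # read coordinates: forward payload position j reads reference j;
  # reverse payload position j reads reference L + 1 - j
  rate_read_payload <- if (mate == "forward") rate_payload else rev(rate_payload)
  rate_prefix <- if (config$tag_errors) mean(rate_payload) else 0
  rate_row <- c(rep(rate_prefix, PREFIX_LEN), rate_read_payload)

  err_idx <- which(runif(length(M)) < rate_row)
  events <- NULL
  if (length(err_idx)) {
    from <- M[err_idx]
    code <- .base_code[as.integer(from) + 1L]
    to <- .base_raw[((code + sample.int(3L, length(err_idx), replace = TRUE)) %% 4L) + 1L]
    M[err_idx] <- to
    Q[err_idx] <- as.raw(33L + sample(seq(qm$error_range[1], qm$error_range[2]),
                                      length(err_idx), replace = TRUE))
    ai <- arrayInd(err_idx, dim(M))
    events <- tibble(
      read_index = ai[, 2L],
      region = ifelse(ai[, 1L] <= PREFIX_LEN, "prefix", "payload"),
      payload_pos = ifelse(ai[, 1L] <= PREFIX_LEN, NA_integer_,
                           ai[, 1L] - PREFIX_LEN),
      type = "substitution",
      ref_base = rawToChar(from, multiple = TRUE),
      obs_base = rawToChar(to, multiple = TRUE)
    )
  }

  # single-base indels on the payload; rare, handled per affected read
  ins_idx <- if (config$ins_rate > 0) which(runif(L * n) < config$ins_rate) else integer(0)
  del_idx <- if (config$del_rate > 0) which(runif(L * n) < config$del_rate) else integer(0)
  if (length(ins_idx) || length(del_idx)) {
    iev <- if (length(ins_idx)) {
      ai <- arrayInd(ins_idx, c(L, n))
      data.frame(read = ai[, 2L], pos = ai[, 1L], type = "insertion")
    }
    dev <- if (length(del_idx)) {
      ai <- arrayInd(del_idx, c(L, n))
      data.frame(read = ai[, 2L], pos = ai[, 1L], type = "deletion")
    }
    ev <- rbind(iev, dev)
    ev$obs <- NA_character_
    ev$ref <- NA_character_
    ins_rows <- ev$type == "insertion"
    if (any(ins_rows)) ev$obs[ins_rows] <- sample(.bases, sum(ins_rows), replace = TRUE)
    ev$ins_qual <- NA_integer_
    ev$ins_qual[ins_rows] <- sample(seq(qm$error_range[1], qm$error_range[2]),
                                    sum(ins_rows), replace = TRUE)
    pad_byte <- charToRaw("A")
    pieces <- split(ev, ev$read)
    done <- vector("list", length(pieces))
    for (j in seq_along(pieces)) {
      er <- pieces[[j]]
      r <- er$read[1L]
      er <- er[order(-er$pos, er$type), , drop = FALSE]  # edit right-to-left
      v <- M[(PREFIX_LEN + 1L):L_read, r]
      q <- Q[(PREFIX_LEN + 1L):L_read, r]
      for (k in seq_len(nrow(er))) {
        p <- er$pos[k]
        if (er$type[k] == "deletion") {
          er$ref[k] <- rawToChar(v[p])
          v <- v[-p]; q <- q[-p]
        } else {
          er$ref[k] <- NA_character_
          v <- append(v, charToRaw(er$obs[k]), after = p - 1L)
          q <- append(q, as.raw(33L + er$ins_qual[k]), after = p - 1L)
        }
      }
      if (length(v) < L) {
        q <- c(q, rep(as.raw(33L + qm$correct), L - length(v)))
        v <- c(v, rep(pad_byte, L - length(v)))
      } else if (length(v) > L) {
        v <- v[seq_len(L)]; q <- q[seq_len(L)]
      }
      M[(PREFIX_LEN + 1L):L_read, r] <- v
      Q[(PREFIX_LEN + 1L):L_read, r] <- q
      done[[j]] <- er
    }
    ev <- do.call(rbind, done)
    events <- bind_rows(events, tibble(
      read_index = ev$read,
      region = "payload",
      payload_pos = ev$pos,
      type = ev$type,
      ref_base = ev$ref,
      obs_base = ev$obs
    ))
  }

  seqs <- vapply(seq_len(n), function(i) rawToChar(M[, i]), character(1))
  quals <- vapply(seq_len(n), function(i) rawToChar(Q[, i]), character(1))
  list(seq = seqs, qual = quals,
       events = if (is.null(events)) tibble(
         read_index = integer(0), region = character(0),
         payload_pos = integer(0), type = character(0),
         ref_base = character(0), obs_base = character(0)
       ) else events)
}

#' Simulate paired sequencing reads from tagged molecules
#'
#' Samples each molecule `copies` times; every copy yields a forward read
#' (12-nt prefix + template payload) and a reverse read (its own 12-nt prefix
#' + reverse-complement payload), emitted 5'->3' as sequenced. Substitution
#' errors are drawn per nucleotide at the strand rate (uniform over the three
#' alternative bases), single-base insertions/deletions at the indel rates
#' over the payload, and every injected error is logged in the truth tables.
#'
#' Error positions in `truth_errors` are pre-indel payload coordinates of the
#' as-sequenced read: applying the substitutions to the molecule's true
#' as-sequenced payload, then the indels right-to-left, then truncating or
#' 'A'-padding to the payload length, reconstructs the emitted payload.
#'
#' @param molecules A `sim_molecules` object from [generate_molecules()].
#' @param config Optional [sim_config()]; defaults to the one stored in
#'   `molecules`.
#' @return A `sim_library` object: list with `fwd` and `rev` read tibbles
#'   (`read_id`, `molecule_id`, `seq`, `qual`; row i of each is one mate
#'   pair), `truth_reads`, `truth_errors`, `molecules`, `config`.
#' @export
simulate_reads <- function(molecules, config = NULL) {
  stopifnot(inherits(molecules, "sim_molecules"))
  if (is.null(config)) config <- molecules$config
  stopifnot(inherits(config, "sim_config"))
  mol <- molecules$molecules
  if (nrow(mol) == 0L) stop("no molecules to sequence", call. = FALSE)

  withr::with_seed(config$seed + 1L, {
    copies <- draw_copies(config$copies, nrow(mol))
    midx <- rep(seq_len(nrow(mol)), copies)
    read_id <- sprintf("m%07d_c%d", mol$molecule_id[midx], sequence(copies))

    half <- config$tag_len_per_primer
    pre <- function(tags, spacer) {
      paste0(substr(tags, 1L, half %/% 2L), config$barcode,
             substr(tags, half %/% 2L + 1L, half), spacer)
    }
    fwd_mol <- paste0(pre(mol$tag_fwd, "A"), mol$true_seq)
    rev_mol <- paste0(pre(mol$tag_rev, "T"), revcomp_chr(mol$true_seq))

    fwd <- .sim_strand(fwd_mol, midx, "forward", config)
    rev_ <- .sim_strand(rev_mol, midx, "reverse", config)
  })

  mk_events <- function(s, mate) {
    ev <- s$events
    tibble(read_id = read_id[ev$read_index], mate = mate,
           region = ev$region, payload_pos = ev$payload_pos,
           type = ev$type, ref_base = ev$ref_base, obs_base = ev$obs_base)
  }
  truth_errors <- bind_rows(mk_events(fwd, "forward"), mk_events(rev_, "reverse"))
  n_err <- table(factor(paste(truth_errors$read_id, truth_errors$mate),
                        levels = c(paste(read_id, "forward"),
                                   paste(read_id, "reverse"))))
  n_reads <- length(read_id)
  truth_reads <- tibble(
    read_id = rep(read_id, 2L),
    molecule_id = rep(mol$molecule_id[midx], 2L),
    mate = rep(c("forward", "reverse"), each = n_reads),
    n_errors = as.integer(n_err)
  )

  structure(list(
    fwd = tibble(read_id = read_id, molecule_id = mol$molecule_id[midx],
                 seq = fwd$seq, qual = fwd$qual),
    rev = tibble(read_id = read_id, molecule_id = mol$molecule_id[midx],
                 seq = rev_$seq, qual = rev_$qual),
    truth_reads = truth_reads,
    truth_errors = truth_errors,
    molecules = mol,
    config = config
  ), class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat("<sim_library>", nrow(x$fwd), "read pairs from",
      nrow(x$molecules), "molecules;",
      nrow(x$truth_errors), "injected errors\n")
  invisible(x)
}

#' Generate molecules and simulate reads in one call
#'
#' @param config A [sim_config()].
#' @return A `sim_library`, see [simulate_reads()].
#' @export
simulate_library <- function(config) {
  simulate_reads(generate_molecules(config))
}

#' Write a simulated library to paired FASTQ plus truth tables
#'
#' Emits standard 4-line FASTQ (Phred+33), mates in matching order with ids
#' suffixed `/1` and `/2`, and tab-separated truth tables
#' (`*_truth_molecules.tsv`, `*_truth_reads.tsv`, `*_truth_errors.tsv`).
#'
#' @param lib A `sim_library` from [simulate_reads()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_library <- function(lib, dir, prefix = "sim") {
  stopifnot(inherits(lib, "sim_library"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, paste0(prefix, f))
  paths <- c(r1 = p("_R1.fastq"), r2 = p("_R2.fastq"),
             molecules = p("_truth_molecules.tsv"),
             reads = p("_truth_reads.tsv"),
             errors = p("_truth_errors.tsv"))
  write_fastq(lib$fwd$read_id, lib$fwd$seq, lib$fwd$qual, paths["r1"], "/1")
  write_fastq(lib$rev$read_id, lib$rev$seq, lib$rev$qual, paths["r2"], "/2")
  wt <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(lib$molecules, paths["molecules"])
  wt(lib$truth_reads, paths["reads"])
  wt(lib$truth_errors, paths["errors"])
  invisible(paths)
}
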