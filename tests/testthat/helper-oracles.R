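# Independent oracles used across the suite.

# Exhaustive Gotoh local-alignment score (affine gaps under the package's
# convention: a length-g gap costs gap_open + (g-1) * gap_extend). Written
# as a plain dynamic program, deliberately independent of the alignment
# backend it checks.
dp_local_score <- function(query, ref, match = 1, mismatch = -1,
                           gap_open = -1, gap_extend = -0.5) {
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(qc)
  m <- length(rc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # ends with query base against a gap
  F <- matrix(-Inf, n + 1, m + 1)  # ends with reference base against a gap
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (qc[i - 1L] == rc[j - 1L] && qc[i - 1L] != "N") match else mismatch
      E[i, j] <- max(H[i - 1L, j] + gap_open, E[i - 1L, j] + gap_extend)
      F[i, j] <- max(H[i, j - 1L] + gap_open, F[i, j - 1L] + gap_extend)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Mutate one position of a DNA string to a different base (deterministic
# choice: next base in ACGT order).
mutate_at <- function(x, pos) {
  b <- substr(x, pos, pos)
  nxt <- c(A = "C", C = "G", G = "T", T = "A")[[b]]
  substr(x, pos, pos) <- nxt
  x
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Rebuild a read payload from its molecule's true as-sequenced payload and
# the logged truth events (substitutions in true coordinates, then indels
# right-to-left, then truncate/pad with 'A').
reconstruct_payload <- function(true_payload, events, payload_len = 88L) {
  v <- strsplit(true_payload, "", fixed = TRUE)[[1]]
  ev <- events[events$region == "payload", , drop = FALSE]
  subs <- ev[ev$type == "substitution", , drop = FALSE]
  for (k in seq_len(nrow(subs))) {
    stopifnot(v[subs$payload_pos[k]] == subs$ref_base[k])
    v[subs$payload_pos[k]] <- subs$obs_base[k]
  }
  ind <- ev[ev$type != "substitution", , drop = FALSE]
  if (nrow(ind)) {
    ind <- ind[order(-ind$payload_pos, ind$type), , drop = FALSE]
    for (k in seq_len(nrow(ind))) {
      p <- ind$payload_pos[k]
      if (ind$type[k] == "deletion") {
        v <- v[-p]
      } else {
        v <- append(v, ind$obs_base[k], after = p - 1L)
      }
    }
  }
  if (length(v) < payload_len) v <- c(v, rep("A", payload_len - length(v)))
  paste(v[seq_len(payload_len)], collapse = "")
}
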