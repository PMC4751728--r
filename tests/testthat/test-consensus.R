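pair_row <- function(fwd, rev, tag = strrep("A", 16), id = "p1",
                     fq = NULL, rq = NULL) {
  tibble::tibble(
    read_id = id, barcode_fwd = "ACA", barcode_rev = "ACA",
    combined_tag = tag, fwd_payload = fwd, rev_payload = rev,
    fwd_quals = if (is.null(fq)) strrep("F", nchar(fwd)) else fq,
    rev_quals = if (is.null(rq)) strrep("F", nchar(rev)) else rq
  )
}

test_that("scheme 1 is a counted pass-through", {
  recs <- tibble::tibble(read_id = c("a", "b", "c"),
                         mate = c("forward", "forward", "reverse"),
                         payload = c("ACGT", "AAAA", "TTTT"),
                         payload_quals = "FFFF")
  s1 <- scheme1_raw(recs)
  expect_equal(nrow(s1$consensus), 3)
  expect_true(all(s1$consensus$support == 1))
  expect_equal(retention(s1), 1)
  expect_equal(unname(retention(s1, by_strand = TRUE)["forward"]), 1)
  expect_equal(nrow(scheme1_raw(recs[0, ])$consensus), 0)
})

test_that("scheme 2 keeps exactly the reverse-complementary pairs", {
  good <- pair_row("ACGTACGT", revcomp("ACGTACGT"), id = "g")
  bad <- pair_row("ACGTACGT", revcomp("ACGAACGT"), id = "b")  # one mismatch
  short <- pair_row("ACGTACGT", "ACG", id = "s")
  s2 <- scheme2_read_pairing(dplyr::bind_rows(good, bad, short))
  expect_equal(nrow(s2$consensus), 1)
  expect_equal(s2$consensus$sequence, "ACGTACGT")
  expect_equal(s2$consensus$support, 2L)
  expect_equal(s2$consensus$strand, "paired")
  expect_equal(unname(s2$discarded["mate_mismatch"]), 1L)
  expect_equal(unname(s2$discarded["length_mismatch"]), 1L)
  expect_equal(retention(s2), 1 / 6)  # 1 consensus from 6 raw reads

  # N is a fifth symbol: it survives only when mirrored on both mates
  n_same <- pair_row("ACNT", revcomp("ACNT"), id = "n1")
  n_diff <- pair_row("ACNT", revcomp("ACGT"), id = "n2")
  s2n <- scheme2_read_pairing(dplyr::bind_rows(n_same, n_diff))
  expect_equal(s2n$consensus$sequence, "ACNT")
})

test_that("scheme 3 enforces group size and strict unanimity", {
  mk <- function(tag, payloads) {
    tibble::tibble(read_id = paste0(tag, seq_along(payloads)),
                   mate = "forward", combined_tag = tag,
                   payload = payloads,
                   payload_quals = strrep("F", nchar(payloads[1])))
  }
  recs <- dplyr::bind_rows(
    mk("TTTTAAAACCCCGGGG", rep("ACGT", 5)),          # unanimous, size 5
    mk("AAAAAAAAAAAAAAAA", rep("ACGT", 2)),          # too small
    mk("CCCCCCCCCCCCCCCC", c(rep("ACGT", 3), "ACGA")) # discordant
  )
  s3 <- scheme3_tag_clustering(recs)
  expect_equal(nrow(s3$consensus), 1)
  expect_equal(s3$consensus$tag_key, "TTTTAAAACCCCGGGG")
  expect_equal(s3$consensus$support, 5L)
  expect_equal(unname(s3$discarded["groups_small"]), 1L)
  expect_equal(unname(s3$discarded["groups_discordant"]), 1L)
  expect_equal(unname(retention(s3, by_strand = TRUE)["forward"]), 1 / 11)

  # grouping runs per strand: same tag on the other strand is independent
  both <- dplyr::bind_rows(recs, within(mk("TTTTAAAACCCCGGGG",
                                           rep("TTTT", 3)),
                                        mate <- "reverse"))
  s3b <- scheme3_tag_clustering(both)
  expect_equal(sort(s3b$consensus$strand), c("forward", "reverse"))
  # output emitted in lexicographic tag-key order within strand
  mixed <- dplyr::bind_rows(mk("ZZZ", rep("AC", 3)), mk("AAA", rep("GT", 3)))
  expect_equal(scheme3_tag_clustering(mixed)$consensus$tag_key,
               c("AAA", "ZZZ"))
})

test_that("scheme 4 equals the explicit composition of schemes 2 and 3", {
  cfg <- sim_config(400, copies = copies_fixed(4),
                    sub_rate_fwd = 5e-3, sub_rate_rev = 0.015,
                    ins_rate = 1e-3, del_rate = 1e-3, seed = 29)
  pairs <- as_read_pairs(simulate_library(cfg))
  s4 <- scheme4_combined(pairs, min_group_size = 3)

  # independent composition: run scheme 2, regroup its consensus manually
  s2 <- scheme2_read_pairing(pairs)
  split_seqs <- split(s2$consensus$sequence, s2$consensus$tag_key)
  manual <- lapply(names(split_seqs), function(tg) {
    ss <- split_seqs[[tg]]
    if (length(ss) >= 3 && length(unique(ss)) == 1) {
      data.frame(tag_key = tg, sequence = ss[1],
                 support = 2L * length(ss))
    }
  })
  manual <- do.call(rbind, manual)
  manual <- manual[order(manual$tag_key), ]
  expect_equal(s4$consensus$tag_key, manual$tag_key)
  expect_equal(s4$consensus$sequence, manual$sequence)
  expect_equal(s4$consensus$support, manual$support)

  # a group failing scheme 2 for all members is absent from scheme 4
  all_bad <- pair_row("AAGT", "AAGT", tag = "GGGGGGGGGGGGGGGG")  # not revcomp
  bad3 <- dplyr::bind_rows(all_bad, all_bad, all_bad)
  expect_equal(nrow(scheme4_combined(bad3)$consensus), 0)
})

test_that("retention monotonicity: scheme 4 never beats schemes 2 or 3", {
  cfg <- sim_config(600, copies = copies_poisson(3.5), seed = 31)
  pairs <- as_read_pairs(simulate_library(cfg))
  res <- run_schemes(pairs)
  expect_lte(retention(res$s4), retention(res$s2))
  expect_lte(retention(res$s4), retention(res$s3))
})

test_that("quality filter looks only at the 88-bp target region", {
  ok <- tibble::tibble(read_id = "a", mate = "forward", payload = "ACGT",
                       payload_quals = "FFFF")
  low <- within(ok, payload_quals <- "FF>F")  # '>' is Phred 29
  qf <- quality_filter(dplyr::bind_rows(ok, low), threshold = 30)
  expect_equal(qf$retained$read_id, "a")
  expect_equal(unname(qf$counts), c(2L, 1L, 1L))

  # low quality confined to the trimmed prefix never reaches the filter:
  # extraction slices payload qualities before filtering
  reads <- tibble::tibble(
    read_id = "p",
    seq = strrep("A", 100),
    qual = paste0(strrep("#", 12), strrep("F", 88))  # '#' is Phred 2
  )
  rec <- extract_tag_payload(reads)$records
  expect_equal(nrow(quality_filter(rec, 30)$retained), 1)

  # pair form: both mates must pass
  pr <- pair_row("ACGT", "ACGT", fq = "FFFF", rq = "FF#F")
  expect_equal(nrow(quality_filter(pr, 30)$retained), 0)
  # boundary: Phred exactly 30 ('?') is retained
  pr30 <- pair_row("ACGT", "ACGT", fq = "?FFF", rq = "FFFF")
  expect_equal(nrow(quality_filter(pr30, 30)$retained), 1)
})

test_that("ideal retention closed forms", {
  expect_equal(ideal_retention(5),
               c(scheme2 = 0.5, scheme3 = 0.2, scheme4 = 0.1))
  expect_equal(unname(ideal_retention(1)["scheme3"]), 1)
  expect_error(ideal_retention(0.5), ">= 1")
})

test_that("zero-error fixed-copies library realizes the ideal retentions", {
  cfg <- sim_config(300, copies = copies_fixed(5),
                    sub_rate_fwd = 0, sub_rate_rev = 0,
                    ins_rate = 0, del_rate = 0, seed = 37)
  pairs <- as_read_pairs(simulate_library(cfg))
  res <- run_schemes(pairs)
  ideal <- ideal_retention(5)
  expect_equal(retention(res$s2), unname(ideal["scheme2"]))
  expect_equal(unname(retention(res$s3, by_strand = TRUE)),
               rep(unname(ideal["scheme3"]), 2))
  expect_equal(retention(res$s4), unname(ideal["scheme4"]))
})
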