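tpl <- protein_g_template()

test_that("alignment scores match the stated conventions", {
  # reference against itself: 88 matches
  self <- align_local(tpl, tpl)
  expect_equal(self$score, 88)
  expect_equal(c(self$ref_start, self$ref_end), c(1, 88))
  expect_false(grepl("-", self$aligned_query, fixed = TRUE))

  # one interior substitution: 87 matches - 1 mismatch
  expect_equal(align_local(mutate_at(tpl, 40), tpl)$score, 86)

  # one deleted base: a length-1 gap costs gap_open only (-1)
  del <- paste0(substr(tpl, 1, 39), substr(tpl, 41, 88))
  expect_equal(align_local(del, tpl)$score, 86)
  # a length-2 gap costs gap_open + gap_extend: 86 matches - 1.5
  del2 <- paste0(substr(tpl, 1, 39), substr(tpl, 42, 88))
  expect_equal(align_local(del2, tpl)$score, 84.5)

  expect_error(align_local("", tpl), "nonempty")
  expect_error(align_local("ACGT", "ACXT"), "A/C/G/T/N")
})

test_that("alignment scores equal the exhaustive DP oracle on short pairs", {
  set.seed(101)
  cases <- list()
  for (i in 1:150) {
    lq <- sample(1:12, 1)
    lr <- sample(1:12, 1)
    cases[[i]] <- c(random_dna(lq), random_dna(lr))
  }
  # edge cases: identical, disjoint alphabets, single bases, N content
  cases <- c(cases, list(c("ACGTACGTACGT", "ACGTACGTACGT"),
                         c("AAAAAA", "CCCCCC"), c("A", "A"), c("A", "C"),
                         c("ACGNACGT", "ACGTACGT"), c("NNNN", "ACGT")))
  qs <- vapply(cases, `[`, "", 1)
  rs <- vapply(cases, `[`, "", 2)
  got <- vapply(seq_along(cases), function(i) {
    align_local(qs[i], rs[i])$score
  }, 0)
  want <- vapply(seq_along(cases), function(i) {
    dp_local_score(qs[i], rs[i])
  }, 0)
  expect_equal(got, want)
})

test_that("error classification covers the four types and gap conventions", {
  # transitions and transversions by the base-pair table
  ev <- classify_errors("AG", "GG")
  expect_equal(ev$type, "transition")
  ev <- classify_errors("AG", "CG")
  expect_equal(ev$type, "transversion")
  for (pair in list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))) {
    expect_equal(classify_errors(pair[1], pair[2])$type, "transition")
  }
  for (pair in list(c("A", "C"), c("A", "T"), c("G", "C"), c("G", "T"))) {
    expect_equal(classify_errors(pair[1], pair[2])$type, "transversion")
    expect_equal(classify_errors(pair[2], pair[1])$type, "transversion")
  }

  # deletion lands on its reference position; a run of g gap columns
  # yields g single-base events
  ev <- classify_errors("ACGTACGT", "AC--ACGT", ref_start = 11)
  expect_equal(ev$type, c("deletion", "deletion"))
  expect_equal(ev$position, c(13, 14))

  # insertion is assigned to the reference position immediately 5'
  ev <- classify_errors("AC--GT", "ACTAGT", ref_start = 21)
  expect_equal(ev$type, c("insertion", "insertion"))
  expect_equal(ev$position, c(22, 22))
  expect_equal(ev$obs_base, c("T", "A"))
  # insertion before the first reference base gets position ref_start - 1
  ev <- classify_errors("-CG", "ACG", ref_start = 1)
  expect_equal(ev$position, 0)

  # N against a base: transversion by default, own type on request
  expect_equal(classify_errors("A", "N")$type, "transversion")
  expect_equal(classify_errors("A", "N", n_policy = "separate")$type, "n")

  # event conservation: mismatch columns = transitions + transversions,
  # gap columns = insertions + deletions
  ar <- "ACGT-ACGTAC"
  aq <- "AGGTTAC-TAA"
  ev <- classify_errors(ar, aq)
  cols_r <- strsplit(ar, "")[[1]]
  cols_q <- strsplit(aq, "")[[1]]
  n_mm <- sum(cols_r != "-" & cols_q != "-" & cols_r != cols_q)
  n_gap <- sum(cols_r == "-" | cols_q == "-")
  expect_equal(sum(ev$type %in% c("transition", "transversion")), n_mm)
  expect_equal(sum(ev$type %in% c("insertion", "deletion")), n_gap)
})

test_that("profiles count what the generator injected", {
  # all records identical to the reference: all rates zero
  p0 <- build_profile(rep(tpl, 10), tpl)
  expect_equal(sum(p0$counts), 0)
  expect_equal(p0$coverage, rep(10L, 88))
  expect_equal(p0$n_records, 10)

  # a known mix: substitutions at separated interior positions (adjacent
  # substitutions in repeat context can legitimately realign as indels)
  q1 <- mutate_at(tpl, 30)
  q2 <- mutate_at(mutate_at(tpl, 50), 60)
  pr <- build_profile(c(q1, q2, tpl), tpl)
  expect_equal(sum(pr$counts), 3)
  expect_equal(unname(rowSums(pr$counts)[c(30, 50, 60)]), c(1, 1, 1))

  # deletion and insertion reads route through the gap walk
  qdel <- paste0(substr(tpl, 1, 39), substr(tpl, 41, 88), "A")
  qins <- substr(paste0(substr(tpl, 1, 40), "T", substr(tpl, 41, 88)), 1, 88)
  pg <- build_profile(c(qdel, qins), tpl)
  expect_equal(unname(pg$counts[40, "deletion"]), 1L)
  expect_equal(unname(pg$counts[40, "insertion"]), 1L)

  # unalignable records are excluded from coverage and counted
  junk <- strrep("T", 88)
  pj <- build_profile(c(tpl, junk), tpl, min_score = 40)
  expect_equal(pj$n_unalignable, 1)
  expect_equal(pj$coverage, rep(1L, 88))
})

test_that("simulated substitution spectrum: rate and 1:2 ti:tv ratio", {
  e <- 5e-3
  cfg <- sim_config(4000, copies = copies_fixed(1),
                    sub_rate_fwd = e, sub_rate_rev = e,
                    ins_rate = 0, del_rate = 0, tag_errors = FALSE,
                    seed = 41)
  lib <- simulate_library(cfg)
  pr <- build_profile(substr(lib$fwd$seq, 13, 100), tpl,
                      scheme = 1, strand = "forward")
  got <- mean_rate(pr, positions = 3:86)
  n_nt <- sum(pr$coverage[3:86])
  expect_true(abs(got - e) <= 3 * sqrt(e * (1 - e) / n_nt))
  # uniform errors hit 1 transition and 2 transversion alternatives
  ti <- sum(pr$counts[3:86, "transition"])
  tv <- sum(pr$counts[3:86, "transversion"])
  expect_true(abs(ti / (ti + tv) - 1 / 3) <=
                3 * sqrt((1 / 3) * (2 / 3) / (ti + tv)))
})

test_that("profiles are additive over disjoint record sets", {
  set.seed(43)
  qa <- vapply(1:30, function(i) mutate_at(tpl, sample(88, 1)), "")
  qb <- vapply(1:20, function(i) mutate_at(tpl, sample(88, 1)), "")
  pa <- build_profile(qa, tpl, scheme = 1)
  pb <- build_profile(qb, tpl, scheme = 1)
  pab <- build_profile(c(qa, qb), tpl, scheme = 1)
  ps <- pa + pb
  expect_equal(ps$counts, pab$counts)
  expect_equal(ps$coverage, pab$coverage)
  expect_equal(ps$n_records, pab$n_records)
  # profile_table is consistent with the matrices
  tab <- profile_table(ps)
  expect_equal(sum(tab$count), sum(ps$counts))
  expect_equal(nrow(tab), 88 * 4)
})

test_that("tag error probability closed form", {
  expect_equal(tag_error_probability(0), 0)
  expect_equal(tag_error_probability(0.001, 16), 1 - 0.999^16)
  expect_equal(round(tag_error_probability(0.001, 16), 5), 0.01588)
  expect_equal(round(tag_error_probability(0.01, 16), 4), 0.1485)
  expect_error(tag_error_probability(1.5), "\\[0, 1\\]")
})
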