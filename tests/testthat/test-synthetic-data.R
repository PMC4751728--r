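test_that("config validation names the offending field", {
  expect_error(sim_config(0), "n_molecules")
  expect_error(sim_config(10, template = "ACGU"), "template")
  expect_error(sim_config(10, sub_rate_fwd = 1.2), "sub_rate_fwd")
  expect_error(sim_config(10, sub_rate_rev = -0.1), "sub_rate_rev")
  expect_error(sim_config(10, ins_rate = 2), "ins_rate")
  expect_error(
    sim_config(10, planted_variants = data.frame(
      sequence = protein_g_template(), frequency = 1.0)),
    "planted_variants")
  expect_error(
    sim_config(10, planted_variants = data.frame(
      sequence = "ACGT", frequency = 0.01)),
    "planted_variants")
  expect_error(sim_config(10, barcode = "ACAG"), "barcode")
  expect_error(copies_fixed(0))
  expect_error(copies_poisson(-1))
})

test_that("molecule generation: tags, variants, and the no-variant case", {
  cfg <- sim_config(500, seed = 3)
  mols <- generate_molecules(cfg)$molecules
  expect_equal(nrow(mols), 500)
  expect_true(all(nchar(mols$tag) == 16))
  expect_true(all(grepl("^[ACGT]+$", mols$tag)))
  # no planted variants: every molecule is the clonal template
  expect_true(all(mols$true_seq == protein_g_template()))
  # the 16 random nt give a tag space of ~4e9
  expect_equal(tag_space(16), 4^16)
  expect_equal(signif(tag_space(16), 1), 4e9)

  # planted variant drawn by its frequency: Binomial(n, f) within 3 sigma
  n <- 10000
  f <- 0.01
  v <- mutate_at(protein_g_template(), 40)
  cfgv <- sim_config(n, planted_variants = data.frame(sequence = v,
                                                      frequency = f),
                     seed = 5)
  molv <- generate_molecules(cfgv)$molecules
  hits <- sum(molv$variant == 1L)
  expect_true(abs(hits - n * f) <= 3 * sqrt(n * f * (1 - f)))
  expect_true(all(molv$true_seq[molv$variant == 1L] == v))
})

test_that("zero-error reads reproduce the true sequence exactly", {
  cfg <- sim_config(40, copies = copies_fixed(1),
                    sub_rate_fwd = 0, sub_rate_rev = 0,
                    ins_rate = 0, del_rate = 0, seed = 11)
  lib <- simulate_library(cfg)
  expect_equal(nrow(lib$fwd), 40)
  expect_equal(substr(lib$fwd$seq, 13, 100),
               lib$molecules$true_seq[lib$fwd$molecule_id])
  expect_equal(substr(lib$rev$seq, 13, 100),
               revcomp(lib$molecules$true_seq[lib$rev$molecule_id]))
  expect_equal(nrow(lib$truth_errors), 0)
  # qualities are all at the correct-base Phred (37 -> 'F')
  expect_true(all(lib$fwd$qual == strrep("F", 100)))
})

test_that("identical seed and config give byte-identical output files", {
  cfg <- sim_config(30, seed = 42)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  p1 <- write_library(simulate_library(cfg), d1)
  p2 <- write_library(simulate_library(cfg), d2)
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  }
  # and a different seed gives a different library
  cfg2 <- sim_config(30, seed = 43)
  lib2 <- simulate_library(cfg2)
  expect_false(identical(lib2$fwd$seq, simulate_library(cfg)$fwd$seq))
})

test_that("copies models behave: fixed exact, poisson zero-truncated", {
  cfg <- sim_config(200, copies = copies_fixed(5), seed = 1)
  lib <- simulate_library(cfg)
  expect_equal(nrow(lib$fwd), 1000)
  expect_true(all(table(lib$fwd$molecule_id) == 5))

  cfgp <- sim_config(2000, copies = copies_poisson(3.5), seed = 2)
  libp <- simulate_library(cfgp)
  sizes <- table(libp$fwd$molecule_id)
  expect_true(all(sizes >= 1))
  # zero-truncated Poisson(3.5) mean is lambda / (1 - exp(-lambda)) ~ 3.61
  mu <- 3.5 / (1 - exp(-3.5))
  expect_true(abs(mean(sizes) - mu) < 3 * sd(sizes) / sqrt(length(sizes)))
})

test_that("injected error rates match the configuration (truth-level)", {
  n <- 4000
  cfg <- sim_config(n, copies = copies_fixed(1),
                    sub_rate_fwd = 0.01, sub_rate_rev = 0.03,
                    ins_rate = 0, del_rate = 0, seed = 7)
  lib <- simulate_library(cfg)
  te <- lib$truth_errors
  nt <- n * 88
  for (m in c("forward", "reverse")) {
    e <- if (m == "forward") 0.01 else 0.03
    k <- sum(te$mate == m & te$region == "payload" &
               te$type == "substitution")
    expect_true(abs(k - nt * e) <= 3 * sqrt(nt * e * (1 - e)),
                label = paste("payload substitution count,", m))
  }
  # configured 3x strand asymmetry is realized
  kf <- sum(te$mate == "forward" & te$region == "payload" &
              te$type == "substitution")
  kr <- sum(te$mate == "reverse" & te$region == "payload" &
              te$type == "substitution")
  ratio <- kr / kf
  se <- ratio * sqrt(1 / kf + 1 / kr)
  expect_true(abs(ratio - 3) <= 3 * se)
})

test_that("every logged error is recoverable from the truth table", {
  cfg <- sim_config(300, copies = copies_fixed(2),
                    sub_rate_fwd = 0.01, sub_rate_rev = 0.02,
                    ins_rate = 0.003, del_rate = 0.003, seed = 13)
  lib <- simulate_library(cfg)
  true_pay <- setNames(lib$molecules$true_seq, lib$molecules$molecule_id)
  for (m in c("forward", "reverse")) {
    reads <- if (m == "forward") lib$fwd else lib$rev
    ev <- lib$truth_errors[lib$truth_errors$mate == m, , drop = FALSE]
    tp <- true_pay[as.character(reads$molecule_id)]
    if (m == "reverse") tp <- revcomp(tp)
    rebuilt <- vapply(seq_len(nrow(reads)), function(i) {
      reconstruct_payload(tp[i], ev[ev$read_id == reads$read_id[i], ,
                                    drop = FALSE])
    }, character(1))
    expect_equal(rebuilt, substr(reads$seq, 13, 100),
                 label = paste("reconstructed", m, "payloads"))
  }
  # every emitted read id appears exactly once per mate in truth_reads
  expect_equal(sort(lib$truth_reads$read_id[lib$truth_reads$mate == "forward"]),
               sort(lib$fwd$read_id))
  expect_equal(anyDuplicated(paste(lib$truth_reads$read_id,
                                   lib$truth_reads$mate)), 0L)
})

test_that("hotspot overrides raise the rate at the chosen positions", {
  hs <- data.frame(position = c(20, 50), strand = "forward", rate = 0.2)
  cfg <- sim_config(2000, copies = copies_fixed(1),
                    sub_rate_fwd = 1e-4, sub_rate_rev = 1e-4,
                    ins_rate = 0, del_rate = 0,
                    hotspots = hs, tag_errors = FALSE, seed = 17)
  lib <- simulate_library(cfg)
  ev <- lib$truth_errors
  hot <- sum(ev$mate == "forward" & ev$payload_pos %in% c(20, 50))
  # Binomial(2000 * 2, 0.2) within 3 sigma
  expect_true(abs(hot - 4000 * 0.2) <= 3 * sqrt(4000 * 0.2 * 0.8))
  # non-hotspot positions stay at the base rate (expect ~17 events)
  cold <- sum(ev$mate == "forward" & !ev$payload_pos %in% c(20, 50))
  expect_lt(cold, 60)
})
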