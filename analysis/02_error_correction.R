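#!/usr/bin/env Rscript
# Step 2: demultiplex the lane and run the four error-correction schemes.
#
# Reads the paired FASTQ produced by 01_simulate_library.R, trims the 12-nt
# prefix into tag + barcode + 88-bp payload, demultiplexes on the 3-bp
# barcode (both mates must agree), and applies each scheme per replicate,
# with and without the Phred >= 30 quality pre-filter. Writes the coverage /
# fold-cost report (the benchmark's bar-plot table) and the consensus sets
# for step 3.

suppressPackageStartupMessages(library(ampliconec))

if (!file.exists("scratch/library/lane_R1.fastq")) {
  stop("run analysis/01_simulate_library.R first")
}

lane <- read_paired_fastq("scratch/library/lane_R1.fastq",
                          "scratch/library/lane_R2.fastq")
fx <- extract_tag_payload(lane$fwd, mate = "forward")
rx <- extract_tag_payload(lane$rev, mate = "reverse")
paired <- pair_records(fx$records, rx$records)
dm <- demultiplex(paired$pairs)
cat("demultiplexing:", paste(names(dm$counts), dm$counts, collapse = ", "),
    "\n\n")

results <- list()
rows <- list()
for (rep_ in c("replicate1", "replicate2")) {
  pairs <- dm$pairs[dm$pairs$replicate == rep_, , drop = FALSE]
  for (qf in c(FALSE, TRUE)) {
    res <- run_schemes(pairs, min_group_size = 3,
                       quality_threshold = if (qf) 30 else NULL)
    results[[paste0(rep_, if (qf) "_qf" else "")]] <- res
    # retention is reported against the raw (pre-filter) read counts,
    # so the quality-filtered strata show the combined coverage cost
    raw_pairs <- nrow(pairs)
    tally <- rbind(
      data.frame(scheme = "ec1f", raw = raw_pairs,
                 retained = sum(res$s1$per_strand$retained[
                   res$s1$per_strand$strand == "forward"])),
      data.frame(scheme = "ec1r", raw = raw_pairs,
                 retained = sum(res$s1$per_strand$retained[
                   res$s1$per_strand$strand == "reverse"])),
      data.frame(scheme = "ec2", raw = 2L * raw_pairs,
                 retained = nrow(res$s2$consensus)),
      data.frame(scheme = "ec3f", raw = raw_pairs,
                 retained = sum(res$s3$consensus$strand == "forward")),
      data.frame(scheme = "ec3r", raw = raw_pairs,
                 retained = sum(res$s3$consensus$strand == "reverse")),
      data.frame(scheme = "ec4", raw = 2L * raw_pairs,
                 retained = nrow(res$s4$consensus))
    )
    tally$replicate <- rep_
    tally$quality_filtered <- qf
    rows[[length(rows) + 1L]] <- tally
  }
}

report <- coverage_report(do.call(rbind, rows))
write.table(format(report, digits = 4), "results/coverage_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(results, "scratch/consensus_sets.rds")

cat("coverage without quality filtering (replicate 1):\n")
print(as.data.frame(report[report$replicate == "replicate1" &
                             !report$quality_filtered,
                           c("scheme", "raw", "retained", "retention",
                             "fold_cost")]),
      row.names = FALSE, digits = 3)
cat("\nwritten: results/coverage_report.tsv\n")
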