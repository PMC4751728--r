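#!/usr/bin/env Rscript
# Step 1: simulate the benchmark library.
#
# Two technical replicates of a clonal 88-bp protein G amplicon library are
# generated under the default error model: per-nt substitution rates 1e-3
# (forward) and 3e-3 (reverse, the ~3x strand asymmetry), single-base indel
# rates 1e-4, zero-truncated Poisson(3.5) read pairs per tagged molecule,
# and substitution errors inside the 12-nt tag/barcode prefix (the source of
# singleton tag clusters). A shared, strand-specific hotspot set models
# sequence-specific errors: the same template gives the same hotspots in
# both replicates, including a strong reverse-strand hotspot at position 57.
# Three low-frequency true variants are planted.
#
# FASTQ (both replicates interleaved into one R1/R2 pair, as sequenced on
# one lane) goes to scratch/library/; truth tables and a summary go to
# results/.

suppressPackageStartupMessages(library(ampliconec))

n_molecules <- 8000L
seed <- 20160212L

hotspots <- rbind(
  data.frame(position = c(12L, 31L, 48L, 66L), strand = "forward",
             rate = c(4e-3, 2e-3, 6e-3, 3e-3)),
  data.frame(position = c(22L, 40L, 57L, 74L), strand = "reverse",
             rate = c(8e-3, 5e-3, 0.08, 6e-3))
)
tpl <- protein_g_template()
mutate1 <- function(pos, to) { v <- tpl; substr(v, pos, pos) <- to; v }
variants <- data.frame(
  sequence = c(mutate1(20L, "A"), mutate1(44L, "G"), mutate1(70L, "T")),
  frequency = c(0.005, 0.002, 0.001)
)

libs <- lapply(1:2, function(r) {
  cfg <- sim_config(
    n_molecules,
    barcode = c("ACA", "GTG")[r],
    hotspots = hotspots,
    planted_variants = variants,
    seed = seed + r
  )
  simulate_library(cfg)
})

dir.create("scratch/library", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

# one lane: concatenate the replicates; the 3-bp barcode demultiplexes them
cat_fastq <- function(field, path, suffix) {
  ids <- c(paste0(libs[[1]]$fwd$read_id, "_rep1"),
           paste0(libs[[2]]$fwd$read_id, "_rep2"))
  seqs <- c(libs[[1]][[field]]$seq, libs[[2]][[field]]$seq)
  quals <- c(libs[[1]][[field]]$qual, libs[[2]][[field]]$qual)
  ampliconec:::write_fastq(ids, seqs, quals, path, suffix)
}
cat_fastq("fwd", "scratch/library/lane_R1.fastq", "/1")
cat_fastq("rev", "scratch/library/lane_R2.fastq", "/2")

for (r in 1:2) {
  write_library(libs[[r]], "scratch/library", paste0("rep", r))
}

summary_tbl <- do.call(rbind, lapply(1:2, function(r) {
  lib <- libs[[r]]
  data.frame(
    replicate = paste0("replicate", r),
    barcode = lib$config$barcode,
    molecules = nrow(lib$molecules),
    read_pairs = nrow(lib$fwd),
    injected_errors = nrow(lib$truth_errors),
    planted_variant_molecules = sum(lib$molecules$variant > 0)
  )
}))
write.table(summary_tbl, "results/simulation_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(summary_tbl, row.names = FALSE)
cat("\nFASTQ written to scratch/library/lane_R[12].fastq\n")
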