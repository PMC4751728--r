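#!/usr/bin/env Rscript
# Step 4: comparative statistics.
#
# From the profiles of step 3: tag cluster-size distributions (with the
# singleton excess that tag errors produce), Shapiro-Wilk normality of the
# raw per-position rates, paired Wilcoxon signed-rank comparisons between
# schemes, replicate-replicate and forward-reverse Pearson correlations,
# and a single JSON summary.

suppressPackageStartupMessages({
  library(ampliconec)
  library(dplyr)
  library(jsonlite)
})

if (!file.exists("scratch/profiles.rds")) {
  stop("run analysis/03_error_profiles.R first")
}
profiles <- readRDS("scratch/profiles.rds")

## tag cluster sizes per replicate (from the demultiplexed lane)
lane <- read_paired_fastq("scratch/library/lane_R1.fastq",
                          "scratch/library/lane_R2.fastq")
fx <- extract_tag_payload(lane$fwd, mate = "forward")
rx <- extract_tag_payload(lane$rev, mate = "reverse")
dm <- demultiplex(pair_records(fx$records, rx$records)$pairs)
cluster_rows <- list()
cluster_summary <- list()
for (rep_ in c("replicate1", "replicate2")) {
  tags <- dm$pairs$combined_tag[dm$pairs$replicate == rep_]
  cs <- cluster_size_distribution(tags)
  cluster_rows[[rep_]] <- transform(cs$histogram, replicate = rep_)
  cluster_summary[[rep_]] <- list(
    mean_nonsingleton = cs$mean_nonsingleton,
    n_singletons = cs$n_singletons,
    n_tags = sum(cs$histogram$n_tags)
  )
  cat(sprintf("%s: %d tags, %d singletons, non-singleton mean %.2f\n",
              rep_, sum(cs$histogram$n_tags), cs$n_singletons,
              cs$mean_nonsingleton))
}
write.table(bind_rows(cluster_rows), "results/cluster_sizes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## normality of raw per-position rates (replicate 1, forward, substitutions)
p1f <- profiles[["replicate1.s1.forward"]]
rates1 <- profile_table(p1f) %>%
  filter(coverage > 0, type %in% c("transition", "transversion"))
nc <- normality_check(rates1$rate)
cat(sprintf("\nShapiro-Wilk on raw per-position substitution rates: W = %.3f, p = %.2e\n",
            nc$statistic, nc$p_value))

## paired scheme comparisons (pooled strands per scheme, replicate 1)
pool <- function(s) {
  keys <- grep(paste0("^replicate1\\.", s, "\\."), names(profiles),
               value = TRUE)
  Reduce(`+`, profiles[keys])
}
pooled <- list(s1 = pool("s1"), s2 = pool("s2"),
               s3 = pool("s3"), s4 = pool("s4"))
contrasts <- list(
  c("s2", "s1"), c("s3", "s1"), c("s4", "s1"),
  c("s3", "s2"), c("s4", "s2"), c("s4", "s3")
)
cmp_rows <- lapply(contrasts, function(ct) {
  subs <- compare_schemes(pooled[[ct[1]]], pooled[[ct[2]]],
                          types = c("transition", "transversion"),
                          unit = "pooled")
  inds <- compare_schemes(pooled[[ct[1]]], pooled[[ct[2]]],
                          types = c("insertion", "deletion"),
                          unit = "pooled")
  data.frame(contrast = paste(ct[1], "vs", ct[2]),
             class = c("substitution", "indel"),
             n_pairs = c(subs$n_pairs, inds$n_pairs),
             p_value = c(subs$p_value, inds$p_value),
             direction = c(subs$direction, inds$direction))
})
cmp <- bind_rows(cmp_rows)
write.table(format(cmp, digits = 3), "results/scheme_comparisons.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nscheme comparisons (replicate 1, pooled position x type pairs):\n")
print(cmp, row.names = FALSE, digits = 3)

## correlations: replicate reproducibility and strand disagreement
cor_rows <- list(
  data.frame(contrast = "replicate1 vs replicate2 (raw forward)",
             correlation_report(profiles[["replicate1.s1.forward"]],
                                profiles[["replicate2.s1.forward"]],
                                fit = TRUE)),
  data.frame(contrast = "replicate1 vs replicate2 (raw reverse)",
             correlation_report(profiles[["replicate1.s1.reverse"]],
                                profiles[["replicate2.s1.reverse"]],
                                fit = TRUE)),
  data.frame(contrast = "forward vs reverse (raw, replicate1)",
             correlation_report(profiles[["replicate1.s1.forward"]],
                                profiles[["replicate1.s1.reverse"]])),
  data.frame(contrast = "forward vs reverse (tag consensus, replicate1)",
             correlation_report(profiles[["replicate1.s3.forward"]],
                                profiles[["replicate1.s3.reverse"]]))
)
cors <- bind_rows(cor_rows)
write.table(format(cors, digits = 3), "results/correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\ncorrelations (Pearson r by error type):\n")
print(cors[, c("contrast", "type", "r")], row.names = FALSE, digits = 2)

## JSON summary
summary_json <- list(
  cluster_sizes = cluster_summary,
  shapiro_wilk_raw_substitution = list(W = nc$statistic, p = nc$p_value),
  scheme_comparisons = cmp,
  correlations = cors[, c("contrast", "type", "r")],
  note = paste("Raw p-values; no multiple-testing correction is applied,",
               "matching the benchmark's reporting.")
)
write_json(summary_json, "results/benchmark_summary.json",
           auto_unbox = TRUE, digits = 6, dataframe = "rows")
cat("\nwritten: results/cluster_sizes.tsv, results/scheme_comparisons.tsv,",
    "results/correlations.tsv, results/benchmark_summary.json\n")
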