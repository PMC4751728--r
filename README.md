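# ampliconec

Benchmarking read-pairing and tag-clustering error correction for
amplicon-based deep sequencing, as a fully simulated, ground-truthed
workflow.

Illumina amplicon sequencing carries a per-nucleotide error rate around
0.1–1 %, which masks rare true variants (viral quasispecies, tumor
subclones). Two library-design remedies trade coverage for accuracy:

* **Read-pairing consensus** — keep a mate pair only if the forward read is
  the exact reverse complement of the reverse read. Independent errors at
  per-nt rate *e* survive at roughly *e*²/3.
* **Tag-clustering consensus** (Primer ID / UMI) — label each template
  molecule with 16 random nucleotides (8 per primer; tag space 4¹⁶ ≈ 4×10⁹),
  group reads by tag, discard groups of fewer than 3 reads, and keep a group
  only if all members are identical. An erroneous consensus needs the same
  error in all *k* members: probability ≤ (*e*/3)^(k−1)·*e* per position.

This package rebuilds the benchmark around a clonal 88-bp protein G amplicon
(54.5 % GC): a synthetic-library generator with recorded ground truth
(strand-asymmetric substitutions, single-base indels, tag-region errors,
hotspots, planted variants, error-linked Phred scores), the four analysis
schemes (raw / pairing / tag clustering / combined, plus a Phred ≥ 30
pre-filter), per-position error profiling from local alignments
(+1/−1 match/mismatch, −1/−0.5 gap open/extend; transitions, transversions,
insertions, deletions), and the comparative statistics (coverage and fold
cost, tag cluster-size distributions, paired Wilcoxon signed-rank tests,
Shapiro–Wilk checks, replicate/strand Pearson correlations).

## Worked example

```r
library(ampliconec)

cfg   <- sim_config(n_molecules = 2000, seed = 42)   # study-condition defaults
lib   <- simulate_library(cfg)                       # FASTQ-ready reads + truth tables
pairs <- as_read_pairs(lib)                          # trim, tag, pair, demultiplex
res   <- run_schemes(pairs, min_group_size = 3)      # schemes 1-4

coverage_report(data.frame(
  scheme   = c("raw", "read-pairing", "tag-clustering (fwd)", "combined"),
  raw      = c(2 * nrow(pairs), 2 * nrow(pairs), nrow(pairs), 2 * nrow(pairs)),
  retained = c(2 * nrow(pairs), nrow(res$s2$consensus),
               sum(res$s3$consensus$strand == "forward"),
               nrow(res$s4$consensus))))
#>                scheme   raw retained retention fold_cost
#>                   raw 14306    14306    1.0000      1.00
#>          read-pairing 14306     4812    0.3364      2.97
#>  tag-clustering (fwd)  7153      864    0.1208      8.28
#>              combined 14306      827    0.0578     17.30
```

Retention is the fraction of raw reads surviving a scheme; its reciprocal is
the per-nucleotide sequencing-cost fold increase — here ~3-fold for
read-pairing, ~8-fold for tag clustering on the forward stream, ~17-fold for
the combination, the coverage price paid for sensitivity.

```r
pr <- profile_consensus(res$s1, protein_g_template())   # raw-read error profile
profile_summary(pr$forward + pr$reverse)
#>   type         n_positions median_rate mean_rate
#> 1 deletion              88   0.0000699 0.0000826
#> 2 insertion             88   0.0000699 0.000104
#> 3 transition            88   0.000699  0.000671
#> 4 transversion          88   0.00133   0.00130

cluster_size_distribution(pairs$combined_tag)
#> <cluster_size_distribution> 2208 tags over 7153 reads; 468 singletons;
#>   mean size 3.84 excluding singletons

tag_error_probability(1e-3, 16)   # why singleton tags are so common
#> 0.0159
```

Raw per-position substitution rates sit near 10⁻³ per nt (reverse reads 3×
noisier than forward), indels an order of magnitude lower; the singleton-tag
excess follows from the ~1.6 % chance of an error somewhere in a 16-nt tag.

The full workflow — two barcoded replicates on one simulated lane,
demultiplexing, all schemes ± quality filtering, profiles, and the
statistical report — is scripted in `analysis/01_simulate_library.R` through
`analysis/04_benchmark_report.R` (run in order from the repository root;
tables land in `results/`, large intermediates in `scratch/`).

## Package layout

| where | what |
|---|---|
| `R/simulate.R`, `R/sim-config.R` | synthetic tagged libraries + truth tables |
| `R/fastq.R` | paired FASTQ I/O, demultiplexing, tag/payload extraction |
| `R/consensus.R` | schemes 1–4, quality filter, retention accounting |
| `R/align.R`, `R/profile.R` | local alignment, error classification, profiles |
| `R/stats.R` | coverage/fold-cost, cluster sizes, Wilcoxon/Shapiro/Pearson |
| `vignettes/error-correction-benchmark.Rmd` | models, assumptions, estimator caveats |
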