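# Comparative reporting: coverage retention and fold cost, tag cluster-size
# distribution, paired nonparametric scheme comparisons, normality checks,
# and replicate/strand correlations. The statistical machinery is base R
# (wilcox.test, shapiro.test, cor, lm); no multiple-testing correction is
# applied, matching the raw p-values the benchmark reports.

#' Coverage retention and sequencing-cost report
#'
#' For each stratum, the fraction of raw reads surviving a scheme and the
#' per-nucleotide sequencing-cost fold increase `1 / retention` (reported as
#' `Inf` at zero retention). For example, retentions of 0.42, 0.12 and 0.06
#' cost ~2.4-, ~8.3- and ~17-fold more sequencing per usable nucleotide.
#'
#' @param strata Data frame with a `raw` and a `retained` count column plus
#'   any label columns (e.g. `scheme`, `strand`, `replicate`).
#' @return The input tibble with `retention` and `fold_cost` columns added.
#' @export
coverage_report <- function(strata) {
  strata <- as_tibble(strata)
  stopifnot(all(c("raw", "retained") %in% names(strata)))
  if (any(strata$retained < 0 | strata$raw < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (any(strata$retained > strata$raw)) {
    stop("accounting error: retained exceeds raw reads", call. = FALSE)
  }
  strata %>%
    mutate(retention = ifelse(raw > 0, retained / raw, NA_real_),
           fold_cost = ifelse(retention > 0, 1 / retention, Inf))
}

#' Tag cluster-size distribution
#'
#' Histogram of reads per unique tag, the singleton count, and the mean
#' cluster size excluding singletons. Singleton tags are dominated by
#' sequencing errors inside the 16-nt tag region (see
#' [tag_error_probability()]), so the benchmark disregards them when
#' summarizing the distribution.
#'
#' @param tags Character vector of tag keys, one element per read.
#' @return A `cluster_size_distribution`: list with `histogram` (tibble
#'   `size`, `n_tags`), `n_singletons`, `mean_nonsingleton`, `total_reads`.
#' @export
cluster_size_distribution <- function(tags) {
  stopifnot(is.character(tags))
  sizes <- table(tags)
  histogram <- as_tibble(table(size = as.integer(sizes)),
                         .name_repair = "minimal")
  names(histogram) <- c("size", "n_tags")
  histogram$size <- as.integer(histogram$size)
  histogram$n_tags <- as.integer(histogram$n_tags)
  nonsingle <- sizes[sizes > 1L]
  structure(list(
    histogram = histogram,
    n_singletons = sum(sizes == 1L),
    mean_nonsingleton = if (length(nonsingle)) mean(nonsingle) else NA_real_,
    total_reads = length(tags)
  ), class = "cluster_size_distribution")
}

#' @export
print.cluster_size_distribution <- function(x, ...) {
  cat("<cluster_size_distribution>", sum(x$histogram$n_tags), "tags over",
      x$total_reads, "reads;", x$n_singletons, "singletons; mean size",
      sprintf("%.2f", x$mean_nonsingleton), "excluding singletons\n")
  invisible(x)
}

# Paired per-position rate vectors shared by two profiles, one pair per
# position x type with nonzero coverage in both.
paired_rates <- function(profile_a, profile_b, types) {
  stopifnot(inherits(profile_a, "error_profile"),
            inherits(profile_b, "error_profile"),
            nrow(profile_a$counts) == nrow(profile_b$counts),
            all(types %in% colnames(profile_a$counts)),
            all(types %in% colnames(profile_b$counts)))
  ok <- profile_a$coverage > 0 & profile_b$coverage > 0
  a <- sweep(profile_a$counts[ok, types, drop = FALSE], 1L,
             profile_a$coverage[ok], "/")
  b <- sweep(profile_b$counts[ok, types, drop = FALSE], 1L,
             profile_b$coverage[ok], "/")
  list(a = a, b = b)
}

wilcox_pair <- function(x, y) {
  d <- x - y
  nz <- d != 0
  if (!any(nz)) {
    return(list(n_pairs = 0L, statistic = NA_real_, p_value = NA_real_,
                direction = "none",
                note = "all pairs zero-difference; test undefined"))
  }
  wt <- suppressWarnings(wilcox.test(x[nz], y[nz], paired = TRUE,
                                     exact = FALSE, correct = TRUE))
  list(n_pairs = sum(nz), statistic = unname(wt$statistic),
       p_value = wt$p.value,
       direction = if (median(d[nz]) < 0) "A < B"
         else if (median(d[nz]) > 0) "B < A" else "none",
       note = NA_character_)
}

#' Paired comparison of two error profiles
#'
#' Two-sided Wilcoxon signed-rank test on paired per-position error rates.
#' The default pairing unit is per-position rates within one error type
#' (one test per type); `unit = "pooled"` instead pairs all position x type
#' rates of the selected types in a single test. Zero-difference pairs are
#' dropped (standard signed-rank convention); if every pair is
#' zero-difference the test is reported as undefined.
#'
#' @param profile_a,profile_b `error_profile`s over the same reference.
#' @param types Error types to compare (default all four).
#' @param unit `"by_type"` (default) or `"pooled"`.
#' @return Tibble with `type` (or `"pooled"`), `n_pairs`, `statistic`
#'   (signed-rank V), `p_value`, `direction` (`"A < B"` means profile A has
#'   the lower rates), `note`.
#' @export
compare_schemes <- function(profile_a, profile_b, types = ERROR_TYPES,
                            unit = c("by_type", "pooled")) {
  unit <- match.arg(unit)
  pr <- paired_rates(profile_a, profile_b, types)
  if (unit == "pooled") {
    res <- wilcox_pair(as.vector(pr$a), as.vector(pr$b))
    return(as_tibble(c(list(type = "pooled"), res)))
  }
  bind_rows(lapply(types, function(tp) {
    as_tibble(c(list(type = tp), wilcox_pair(pr$a[, tp], pr$b[, tp])))
  }))
}

#' Shapiro-Wilk normality check of a rate vector
#'
#' The benchmark's per-position error rates are far from normal (peak near
#' 1e-4 with a heavy tail to 1e-2), which motivates the nonparametric
#' scheme comparisons; this reproduces that check.
#'
#' @param rates Numeric vector (at least 3 values).
#' @return List with `statistic` (W), `p_value`, `n`, `note` (degenerate
#'   constant vectors are reported as such, with `NA` statistics).
#' @export
normality_check <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < 3L) {
    stop("need at least 3 values for the Shapiro-Wilk test", call. = FALSE)
  }
  if (length(unique(rates)) == 1L) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                n = length(rates), note = "degenerate: constant vector"))
  }
  # shapiro.test caps at 5000 values; thin deterministically if needed
  if (length(rates) > 5000L) {
    rates <- rates[unique(round(seq(1L, length(rates), length.out = 5000L)))]
  }
  sw <- shapiro.test(rates)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       n = length(rates), note = NA_character_)
}

#' Correlation between two error profiles
#'
#' Pearson correlation of per-position rates for each error type, the
#' replicate-vs-replicate / forward-vs-reverse reproducibility measure.
#' Optionally adds an ordinary least-squares fit of profile Y's rates on
#' profile X's. Zero variance in either vector makes r undefined (`NA`,
#' noted).
#'
#' @param profile_x,profile_y `error_profile`s over the same reference.
#' @param types Error types (default all four).
#' @param fit If `TRUE`, add OLS `slope` and `intercept`.
#' @return Tibble with `type`, `n`, `r`, optionally `slope`/`intercept`,
#'   `note`.
#' @export
correlation_report <- function(profile_x, profile_y, types = ERROR_TYPES,
                               fit = FALSE) {
  pr <- paired_rates(profile_x, profile_y, types)
  bind_rows(lapply(types, function(tp) {
    x <- pr$a[, tp]; y <- pr$b[, tp]
    degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
    row <- tibble(
      type = tp, n = length(x),
      r = if (degenerate) NA_real_ else cor(x, y),
      note = if (degenerate) "zero variance; r undefined" else NA_character_
    )
    if (fit) {
      if (degenerate) {
        row$slope <- NA_real_; row$intercept <- NA_real_
      } else {
        cf <- coef(lm(y ~ x))
        row$slope <- unname(cf[2]); row$intercept <- unname(cf[1])
      }
    }
    row
  }))
}
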