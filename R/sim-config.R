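#' Copies-per-tag models
#'
#' `copies_fixed(c)` sequences exactly `c` read pairs from every tagged
#' molecule; it is used for the exact ideal-retention identities.
#' `copies_poisson(lambda)` draws a zero-truncated Poisson count per molecule
#' (a molecule that is never sequenced is simply never observed, so the
#' truncation at >= 1 is the natural observable model). The default
#' `lambda = 3.5` is calibrated so that, under the default error rates, the
#' realized non-singleton tag-cluster size mean is ~3.8, between the 3.5 and
#' 4.1 observed in the two technical replicates of the benchmark experiment.
#'
#' @param c Positive integer, read pairs per molecule.
#' @param lambda Positive Poisson mean (before zero-truncation).
#' @return A copies-model object used by [sim_config()].
#' @export
copies_fixed <- function(c) {
  stopifnot(length(c) == 1L, is.finite(c), c >= 1, c == as.integer(c))
  structure(list(kind = "fixed", c = as.integer(c)), class = "copies_model")
}

#' @rdname copies_fixed
#' @export
copies_poisson <- function(lambda = 3.5) {
  stopifnot(length(lambda) == 1L, is.finite(lambda), lambda > 0)
  structure(list(kind = "poisson", lambda = lambda), class = "copies_model")
}

# Draw n copy counts from a copies model (zero-truncated for poisson).
draw_copies <- function(model, n) {
  switch(model$kind,
    fixed = rep.int(model$c, n),
    poisson = {
      p0 <- dpois(0, model$lambda)
      qpois(runif(n, p0, 1), model$lambda)
    },
    stop("unknown copies model: ", model$kind)
  )
}

#' Quality model for simulated base calls
#'
#' Bases read correctly receive a fixed high Phred score; erroneous bases
#' (substituted or inserted) receive a Phred score drawn uniformly from
#' `error_range`. This couples quality to error status, so that the Phred < 30
#' quality filter is informative (most, but not all, erroneous bases fall
#' below the threshold, since the error range includes 30 itself).
#'
#' @param correct Phred score of correctly read bases (default 37).
#' @param error_range Integer range `c(lo, hi)` for erroneous bases
#'   (default `c(2, 30)`).
#' @return A quality-model object used by [sim_config()].
#' @export
quality_model <- function(correct = 37L, error_range = c(2L, 30L)) {
  stopifnot(
    length(correct) == 1L, correct >= 0, correct <= 60,
    length(error_range) == 2L, error_range[1] <= error_range[2],
    error_range[1] >= 0, error_range[2] <= 60
  )
  structure(list(correct = as.integer(correct),
                 error_range = as.integer(error_range)),
            class = "quality_model")
}

#' Configuration of a synthetic clonal tagged amplicon library
#'
#' Fully specifies the generative model: a clonal 88-bp template, tagged
#' molecules carrying 16 random nucleotides (8 per primer, split 4+4 around a
#' 3-bp replicate barcode), a copies-per-tag model, strand-specific
#' substitution rates (the reverse read is noisier on the Illumina platform;
#' the default is a 3x asymmetry), per-nt single-base indel rates, optional
#' position/strand hotspot overrides, optional planted true variants, and a
#' quality model.
#'
#' @param n_molecules Number of tagged template molecules.
#' @param template DNA string (default the 88-bp protein G amplicon).
#' @param copies A [copies_fixed()]/[copies_poisson()] model
#'   (default `copies_poisson(3.5)`).
#' @param sub_rate_fwd,sub_rate_rev Per-nt substitution probability on the
#'   forward/reverse read; a scalar, or a vector of length `nchar(template)`
#'   giving per-position rates in reference coordinates. Defaults 1e-3 and
#'   3e-3 (the ~3x reverse-strand excess seen on HiSeq data).
#' @param ins_rate,del_rate Per-nt single-base insertion/deletion
#'   probabilities on the payload (defaults 1e-4; roughly 10-fold below the
#'   substitution rates, as observed for Illumina).
#' @param hotspots Optional data frame with columns `position` (1-based
#'   reference coordinate), `strand` (`"forward"`/`"reverse"`) and `rate`,
#'   overriding the substitution rate at those payload positions.
#' @param planted_variants Optional data frame with columns `sequence`
#'   (same length as `template`) and `frequency`; frequencies must sum to
#'   < 1. Planted variants model true template heterogeneity (including
#'   PCR-phase errors, which are shared by all copies of a molecule and
#'   therefore uncorrectable by consensus).
#' @param quality A [quality_model()].
#' @param tag_len_per_primer Random nucleotides per primer (default 8).
#' @param barcode 3-nt replicate barcode (default `"ACA"`, replicate 1;
#'   `"GTG"` is replicate 2).
#' @param tag_errors Logical; if `TRUE` (default) substitution errors are
#'   also drawn over the 12-nt read prefix at the strand rate, which is what
#'   produces singleton tag clusters. Disable for oracle checks that need
#'   intact tags.
#' @param seed Integer RNG seed; identical seed and config give
#'   byte-identical libraries.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_molecules,
                       template = protein_g_template(),
                       copies = copies_poisson(3.5),
                       sub_rate_fwd = 1e-3,
                       sub_rate_rev = 3e-3,
                       ins_rate = 1e-4,
                       del_rate = 1e-4,
                       hotspots = NULL,
                       planted_variants = NULL,
                       quality = quality_model(),
                       tag_len_per_primer = 8L,
                       barcode = "ACA",
                       tag_errors = TRUE,
                       seed = 1L) {
  chk_rate <- function(x, field, len) {
    if (!is.numeric(x) || !(length(x) %in% c(1L, len)) ||
        anyNA(x) || any(x < 0) || any(x > 1)) {
      stop("invalid `", field, "`: rates must be in [0, 1], scalar or length ",
           len, call. = FALSE)
    }
  }
  stopifnot(length(n_molecules) == 1L, n_molecules >= 1,
            n_molecules == as.integer(n_molecules))
  if (!is.character(template) || length(template) != 1L ||
      !grepl("^[ACGT]+$", template)) {
    stop("invalid `template`: must contain only A/C/G/T", call. = FALSE)
  }
  L <- nchar(template)
  if (!inherits(copies, "copies_model")) {
    stop("invalid `copies`: use copies_fixed() or copies_poisson()",
         call. = FALSE)
  }
  chk_rate(sub_rate_fwd, "sub_rate_fwd", L)
  chk_rate(sub_rate_rev, "sub_rate_rev", L)
  chk_rate(ins_rate, "ins_rate", 1L)
  chk_rate(del_rate, "del_rate", 1L)
  if (!is.null(hotspots)) {
    hotspots <- as.data.frame(hotspots)
    if (!all(c("position", "strand", "rate") %in% names(hotspots)) ||
        any(hotspots$position < 1) || any(hotspots$position > L) ||
        !all(hotspots$strand %in% c("forward", "reverse")) ||
        any(hotspots$rate < 0) || any(hotspots$rate > 1)) {
      stop("invalid `hotspots`: need columns position (1..", L,
           "), strand (forward/reverse), rate in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(planted_variants)) {
    planted_variants <- as.data.frame(planted_variants)
    if (!all(c("sequence", "frequency") %in% names(planted_variants)) ||
        !all(grepl("^[ACGT]+$", planted_variants$sequence)) ||
        !all(nchar(planted_variants$sequence) == L) ||
        any(planted_variants$frequency <= 0) ||
        sum(planted_variants$frequency) >= 1) {
      stop("invalid `planted_variants`: sequences must be A/C/G/T of length ",
           L, " and frequencies must sum to < 1", call. = FALSE)
    }
  }
  if (!inherits(quality, "quality_model")) {
    stop("invalid `quality`: use quality_model()", call. = FALSE)
  }
  stopifnot(length(tag_len_per_primer) == 1L, tag_len_per_primer >= 2,
            tag_len_per_primer %% 2 == 0)
  if (!is.character(barcode) || length(barcode) != 1L ||
      !grepl("^[ACGT]{3}$", barcode)) {
    stop("invalid `barcode`: must be a 3-nt A/C/G/T string", call. = FALSE)
  }
  stopifnot(length(seed) == 1L, is.finite(seed))
  structure(list(
    n_molecules = as.integer(n_molecules),
    template = template,
    copies = copies,
    sub_rate_fwd = sub_rate_fwd,
    sub_rate_rev = sub_rate_rev,
    ins_rate = ins_rate,
    del_rate = del_rate,
    hotspots = hotspots,
    planted_variants = planted_variants,
    quality = quality,
    tag_len_per_primer = as.integer(tag_len_per_primer),
    barcode = barcode,
    tag_errors = isTRUE(tag_errors),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  molecules:  ", x$n_molecules, "\n")
  cat("  template:   ", nchar(x$template), "nt, GC",
      sprintf("%.1f%%", 100 * gc_content(x$template)), "\n")
  cat("  copies:     ", if (x$copies$kind == "fixed")
        paste0("fixed(", x$copies$c, ")")
      else paste0("zero-truncated poisson(", x$copies$lambda, ")"), "\n")
  cat("  sub rates:  fwd", paste(signif(unique(x$sub_rate_fwd), 3), collapse = "/"),
      " rev", paste(signif(unique(x$sub_rate_rev), 3), collapse = "/"), "\n")
  cat("  indel rates: ins", x$ins_rate, " del", x$del_rate, "\n")
  cat("  barcode:    ", x$barcode, " tag:", 2 * x$tag_len_per_primer,
      "random nt\n")
  cat("  variants:   ",
      if (is.null(x$planted_variants)) 0 else nrow(x$planted_variants), "\n")
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}
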