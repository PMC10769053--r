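#' Validation parameters
#'
#' Bundles every tunable constant of the validation pipeline. The defaults are
#' the method's operating point: a read must span `flank_len` bp beyond both
#' SV breakpoints to count as a candidate; only alignments with
#' MAPQ >= `mapq_min` are considered; CIGAR indels shorter than
#' `min_cigar_indel` bp are treated as sequencing noise; candidate SVs in
#' regions whose coverage exceeds `coverage_multiplier` times the genome-wide
#' average (estimated from `n_coverage_samples` random positions) are set
#' aside; split-read distance deviations must exceed
#' `split_diff_threshold` bp in magnitude before they are read as an SV
#' signal; a support fraction at or above `hom_threshold` is called
#' homozygous, below `false_threshold` false, heterozygous in between; and a
#' false call is re-issued with a corrected length when more than
#' `alt_support_fraction` of the screened reads agree on an alternative
#' indel of at least `min_alt_sv_len` bp.
#'
#' @param flank_len bp of reference a candidate read must cover on each side
#'   of the SV (default 1000).
#' @param mapq_min minimum mapping quality of a read's best segment
#'   (default 20).
#' @param min_cigar_indel minimum CIGAR I/D operation length, bp, counted as
#'   SV evidence (default 30).
#' @param coverage_multiplier high-coverage filter multiplier (default 5).
#' @param n_coverage_samples reference positions sampled for the coverage
#'   estimate (default 1000).
#' @param split_diff_threshold bp gate on the split-read distance difference
#'   (default 200).
#' @param hom_threshold support-rate lower bound for a homozygous call
#'   (default 0.8).
#' @param false_threshold support-rate upper bound (exclusive) for a false
#'   call (default 0.1).
#' @param alt_support_fraction fraction of screened reads that must agree on
#'   an alternative SV before a corrected length is emitted (default 0.1,
#'   strict inequality).
#' @param inv_fwd_noise_min minimum forward-reference noise fraction for an
#'   inversion-supporting read (default 0.3).
#' @param inv_rev_noise_max maximum reverse-complement noise fraction for an
#'   inversion-supporting read (default 0.2).
#' @param min_alt_sv_len minimum |implied length|, bp, for the corrected-SV
#'   cluster (default 50, the conventional SV size floor).
#' @param ins_cov_flank half-width, bp, of the window used to measure
#'   coverage at an insertion breakpoint (default 500).
#' @param rng_seed seed for the coverage-sampling RNG.
#' @return a list of class `longsv_params`.
#' @export
validation_params <- function(flank_len = 1000L,
                              mapq_min = 20L,
                              min_cigar_indel = 30L,
                              coverage_multiplier = 5,
                              n_coverage_samples = 1000L,
                              split_diff_threshold = 200L,
                              hom_threshold = 0.8,
                              false_threshold = 0.1,
                              alt_support_fraction = 0.1,
                              inv_fwd_noise_min = 0.3,
                              inv_rev_noise_max = 0.2,
                              min_alt_sv_len = 50L,
                              ins_cov_flank = 500L,
                              rng_seed = 1L) {
  p <- list(
    flank_len = as.integer(flank_len),
    mapq_min = as.integer(mapq_min),
    min_cigar_indel = as.integer(min_cigar_indel),
    coverage_multiplier = as.numeric(coverage_multiplier),
    n_coverage_samples = as.integer(n_coverage_samples),
    split_diff_threshold = as.integer(split_diff_threshold),
    hom_threshold = as.numeric(hom_threshold),
    false_threshold = as.numeric(false_threshold),
    alt_support_fraction = as.numeric(alt_support_fraction),
    inv_fwd_noise_min = as.numeric(inv_fwd_noise_min),
    inv_rev_noise_max = as.numeric(inv_rev_noise_max),
    min_alt_sv_len = as.integer(min_alt_sv_len),
    ins_cov_flank = as.integer(ins_cov_flank),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    p$flank_len > 0L, p$min_cigar_indel > 0L, p$split_diff_threshold > 0L,
    p$min_alt_sv_len > 0L, p$ins_cov_flank > 0L,
    p$coverage_multiplier > 0, p$n_coverage_samples >= 1L,
    p$mapq_min >= 0L,
    p$false_threshold >= 0, p$false_threshold < p$hom_threshold,
    p$hom_threshold <= 1,
    p$alt_support_fraction >= 0, p$alt_support_fraction <= 1,
    p$inv_fwd_noise_min >= 0, p$inv_rev_noise_max >= 0
  )
  class(p) <- "longsv_params"
  p
}

#' @export
print.longsv_params <- function(x, ...) {
  cat("longsv validation parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Labels of the validation outcome; a closed set used across modules.
LABEL_HOM <- "HOMOZYGOUS"
LABEL_HET <- "HETEROZYGOUS"
LABEL_FALSE <- "FALSE"
LABEL_FILTERED <- "FILTERED_HIGH_COVERAGE"
LABEL_NO_READS <- "NO_READS"

SV_TYPES <- c("DEL", "INS", "INV")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
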