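# Step 1 of the pipeline: genome-wide average coverage from randomly sampled
# reference positions, and the high-coverage SV filter derived from it.

#' Per-base coverage of a BAM as an RleList
#'
#' Coverage counts primary and supplementary alignment records whose
#' reference span contains a position; secondary and unmapped records are
#' excluded. Computed once and reused by the estimator and the filter.
#'
#' @param bam path to an indexed BAM or a `BamFile`.
#' @return named `RleList`, one run-length vector per contig, with the
#'   contig lengths from the BAM header.
#' @export
bam_coverage <- function(bam) {
  bf <- as_bamfile(bam)
  targets <- Rsamtools::scanBamHeader(bf)$targets
  if (length(targets) == 0L) stop("BAM header lists no contigs")
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    what = c("rname", "pos", "cigar")
  )
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  if (length(res$pos) == 0L) {
    return(IRanges::RleList(lapply(targets, function(l)
      S4Vectors::Rle(0L, l)), compress = TRUE))
  }
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  gr <- GenomicRanges::GRanges(
    res$rname, IRanges::IRanges(res$pos, width = w))
  GenomeInfoDb::seqlengths(gr) <- targets[GenomeInfoDb::seqlevels(gr)]
  GenomicRanges::coverage(gr)
}

#' Estimate genome-wide average coverage from random positions
#'
#' Draws `n_samples` positions uniformly over the concatenated genome
#' (contigs weighted by length), reads the alignment coverage at each, and
#' returns their unweighted arithmetic mean:
#' `average = (1/n) * sum(coverage_i)`.
#'
#' @param bam path to an indexed BAM or a `BamFile`.
#' @param n_samples number of positions to draw (default 1000).
#' @param rng_seed RNG seed; identical inputs and seed give an identical
#'   model.
#' @param cov optional precomputed [bam_coverage()] result.
#' @return a `longsv_coverage` list: `average_coverage`, `samples`
#'   (data.frame of chrom, position, coverage), `n_samples`, `rng_seed`.
#' @export
estimate_average_coverage <- function(bam, n_samples = 1000L, rng_seed = 1L,
                                      cov = NULL) {
  stopifnot(n_samples >= 1L)
  if (is.null(cov)) cov <- bam_coverage(bam)
  lens <- vapply(cov, length, 0L)
  lens <- lens[lens > 0L]
  if (length(lens) == 0L) stop("reference contig list is empty")
  model <- with_seed(rng_seed, {
    chroms <- sample(names(lens), n_samples, replace = TRUE,
                     prob = as.numeric(lens))
    pos <- vapply(chroms, function(ch) sample.int(lens[[ch]], 1L), 0L)
    covs <- vapply(seq_len(n_samples), function(i) {
      as.integer(cov[[chroms[i]]][pos[i]])
    }, 0L)
    list(
      average_coverage = mean(covs),
      samples = data.frame(chrom = chroms, position = pos - 1L,
                           coverage = covs, stringsAsFactors = FALSE,
                           row.names = NULL),
      n_samples = as.integer(n_samples),
      rng_seed = as.integer(rng_seed)
    )
  })
  if (model$average_coverage == 0) {
    warning("no aligned reads found; average coverage is 0")
  }
  class(model) <- "longsv_coverage"
  model
}

#' @export
print.longsv_coverage <- function(x, ...) {
  cat(sprintf("longsv coverage model: average %.3f from %d sampled positions (seed %d)\n",
              x$average_coverage, x$n_samples, x$rng_seed))
  invisible(x)
}

#' Mean per-base coverage over a region
#'
#' @param bam path to an indexed BAM or a `BamFile`; ignored when `cov` is
#'   given.
#' @param chrom contig name.
#' @param start,end 0-based half-open region.
#' @param cov optional precomputed [bam_coverage()] result.
#' @return mean coverage over `[start, end)`; 0 for a region on a contig
#'   with no reads.
#' @export
region_mean_coverage <- function(bam, chrom, start, end, cov = NULL) {
  stopifnot(start < end)
  if (is.null(cov)) cov <- bam_coverage(bam)
  if (!chrom %in% names(cov)) return(0)
  v <- cov[[chrom]]
  from <- max(start + 1L, 1L)
  to <- min(end, length(v))
  if (from > to) return(0)
  mean(as.numeric(v[from:to]))
}

#' Filter SVs in abnormally high-coverage regions
#'
#' An SV is set aside when the mean coverage over its span (for insertions,
#' over `start +/- ins_cov_flank`) is strictly greater than
#' `coverage_multiplier` times the estimated genome-wide average. Filtered
#' SVs are reported with label `FILTERED_HIGH_COVERAGE`; kept and filtered
#' records partition the input.
#'
#' @param svs SV table.
#' @param coverage_model result of [estimate_average_coverage()].
#' @param bam path to an indexed BAM; ignored when `cov` is given.
#' @param params [validation_params()].
#' @param cov optional precomputed [bam_coverage()] result.
#' @return list with `kept` (SV table subset) and `filtered` (results
#'   data.frame rows for the removed SVs, possibly empty).
#' @export
filter_high_coverage <- function(svs, coverage_model, bam,
                                 params = validation_params(), cov = NULL) {
  if (is.null(cov)) cov <- bam_coverage(bam)
  threshold <- params$coverage_multiplier * coverage_model$average_coverage
  regcov <- vapply(seq_len(nrow(svs)), function(i) {
    if (svs$sv_type[i] == "INS") {
      region_mean_coverage(bam, svs$chrom[i],
                           max(svs$start[i] - params$ins_cov_flank, 0L),
                           svs$start[i] + params$ins_cov_flank, cov = cov)
    } else {
      region_mean_coverage(bam, svs$chrom[i], svs$start[i], svs$end[i],
                           cov = cov)
    }
  }, 0)
  drop <- regcov > threshold & coverage_model$average_coverage > 0
  filtered <- empty_results()
  if (any(drop)) {
    filtered <- result_rows(svs[drop, , drop = FALSE], label = LABEL_FILTERED)
  }
  list(kept = svs[!drop, , drop = FALSE], filtered = filtered,
       region_coverage = regcov)
}
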