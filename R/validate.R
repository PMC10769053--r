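# Step 3 of the pipeline: aggregate per-read evidence into a support rate,
# assign the genotype label, and emit a corrected SV when the listed call is
# false but the locus carries a different variant.

empty_results <- function() {
  data.frame(
    id = character(), chrom = character(), start = integer(),
    end = integer(), sv_type = character(), length = integer(),
    total_reads = integer(), support_reads = integer(),
    support_rate = numeric(), label = character(),
    corrected_length = integer(), corrected_type = character(),
    corrected_support_fraction = numeric(), stringsAsFactors = FALSE
  )
}

result_rows <- function(svs, total_reads = 0L, support_reads = 0L,
                        support_rate = NA_real_, label,
                        corrected_length = NA_integer_,
                        corrected_type = NA_character_,
                        corrected_support_fraction = NA_real_) {
  data.frame(
    id = svs$id, chrom = svs$chrom, start = svs$start, end = svs$end,
    sv_type = svs$sv_type, length = svs$length,
    total_reads = as.integer(total_reads),
    support_reads = as.integer(support_reads),
    support_rate = as.numeric(support_rate),
    label = label,
    corrected_length = as.integer(corrected_length),
    corrected_type = as.character(corrected_type),
    corrected_support_fraction = as.numeric(corrected_support_fraction),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tally per-read evidence into a support rate
#'
#' @param evidences list of support-evidence lists for all screened reads at
#'   one SV.
#' @return list `(support_reads, total_reads, support_rate)`;
#'   `support_rate` is `NA` when no read was screened in.
#' @export
tally_support <- function(evidences) {
  total <- length(evidences)
  supp <- sum(vapply(evidences, `[[`, logical(1), "supports"))
  list(support_reads = as.integer(supp), total_reads = as.integer(total),
       support_rate = if (total > 0L) supp / total else NA_real_)
}

#' Genotype label from the support rate
#'
#' `HOMOZYGOUS` for rates in `[hom_threshold, 1]`, `HETEROZYGOUS` in
#' `[false_threshold, hom_threshold)`, `FALSE` in `[0, false_threshold)`.
#' Boundary rates are assigned to the upper class (closed lower bounds).
#'
#' @param support_rate fraction in `[0, 1]`.
#' @param params [validation_params()].
#' @return one of `"HOMOZYGOUS"`, `"HETEROZYGOUS"`, `"FALSE"`.
#' @export
classify <- function(support_rate, params = validation_params()) {
  if (is.na(support_rate) || support_rate < 0 || support_rate > 1) {
    stop("support_rate must be in [0, 1]")
  }
  if (support_rate >= params$hom_threshold) LABEL_HOM
  else if (support_rate >= params$false_threshold) LABEL_HET
  else LABEL_FALSE
}

#' Corrected SV from the alternative-support cluster
#'
#' When a candidate is labelled false but the locus still carries indel
#' evidence, the non-supporting reads whose implied length has magnitude
#' >= `min_alt_sv_len` are pooled; if they agree in sign and make up more
#' than `alt_support_fraction` of the screened reads, the mean of their
#' |implied lengths| (rounded) is reported as the corrected SV, typed DEL or
#' INS by the shared sign.
#'
#' @param evidences list of support-evidence lists (all screened reads).
#' @param sv one-row SV table (the false candidate).
#' @param params [validation_params()].
#' @return list `(length, type, fraction)` or `NULL`.
#' @export
corrected_sv <- function(evidences, sv, params = validation_params()) {
  total <- length(evidences)
  if (total == 0L) return(NULL)
  alt <- Filter(function(e) {
    !e$supports && e$kind == "indel" &&
      abs(e$implied_length) >= params$min_alt_sv_len
  }, evidences)
  if (length(alt) == 0L) return(NULL)
  lens <- vapply(alt, `[[`, integer(1), "implied_length")
  if (length(unique(sign(lens))) != 1L) return(NULL)
  fraction <- length(lens) / total
  if (fraction <= params$alt_support_fraction) return(NULL)
  list(length = as.integer(round(mean(abs(lens)))),
       type = if (lens[1] < 0L) "DEL" else "INS",
       fraction = fraction)
}

#' Validate a list of candidate SVs against a BAM
#'
#' Runs the full three-step pipeline: (1) estimate average coverage from
#' random reference positions and set aside SVs in regions above
#' `coverage_multiplier` times the average; (2) per remaining SV, screen the
#' reads over the flanked window and collect per-read support evidence from
#' the CIGAR and split channels; (3) compute the support rate, assign
#' HOMOZYGOUS / HETEROZYGOUS / FALSE, and attach a corrected length when a
#' false candidate's locus supports a different indel. Output order matches
#' input order; a fixed `rng_seed` in `params` makes the run deterministic.
#'
#' @param svs SV table from [read_sv_bed()] or [sv_table()].
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param reference contig sequences (named character vector,
#'   `DNAStringSet`, or FASTA path); required when `svs` contains INV
#'   records.
#' @param params [validation_params()].
#' @return results data.frame (one row per input SV) with the coverage
#'   model attached as attribute `"coverage_model"`.
#' @export
validate_all <- function(svs, bam, reference = NULL,
                         params = validation_params()) {
  if (any(svs$sv_type == "INV") && is.null(reference)) {
    stop("INV records present: a reference sequence (--ref) is required")
  }
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  orig_id <- svs$id
  svs$id <- make.unique(svs$id)  # ids key the output ordering internally
  bf <- as_bamfile(bam)
  cov <- bam_coverage(bf)
  model <- estimate_average_coverage(bf, params$n_coverage_samples,
                                     params$rng_seed, cov = cov)
  flt <- filter_high_coverage(svs, model, bf, params, cov = cov)

  res_list <- lapply(seq_len(nrow(flt$kept)), function(i) {
    sv <- flt$kept[i, , drop = FALSE]
    tryCatch({
      win_lo <- max(sv$start - params$flank_len, 0L)
      win_hi <- sv$end + params$flank_len
      segs <- fetch_segments(bf, sv$chrom, win_lo, win_hi)
      segs <- screen_reads(segs, sv, params)
      groups <- split(segs, segs$read_id)
      evid <- lapply(groups, evidence_for_read, sv = sv, params = params,
                     reference = reference)
      tl <- tally_support(evid)
      if (tl$total_reads == 0L) {
        return(result_rows(sv, 0L, 0L, NA_real_, LABEL_NO_READS))
      }
      label <- classify(tl$support_rate, params)
      corr <- if (label == LABEL_FALSE) corrected_sv(evid, sv, params)
              else NULL
      result_rows(sv, tl$total_reads, tl$support_reads, tl$support_rate,
                  label,
                  corrected_length = if (is.null(corr)) NA_integer_
                                     else corr$length,
                  corrected_type = if (is.null(corr)) NA_character_
                                   else corr$type,
                  corrected_support_fraction = if (is.null(corr)) NA_real_
                                               else corr$fraction)
    }, error = function(e) {
      warning("SV ", sv$id, ": ", conditionMessage(e),
              "; reporting NO_READS", call. = FALSE)
      result_rows(sv, 0L, 0L, NA_real_, LABEL_NO_READS)
    })
  })
  out <- do.call(rbind, c(list(empty_results()), res_list,
                          list(flt$filtered)))
  out <- out[match(svs$id, out$id), , drop = FALSE]
  out$id <- orig_id
  rownames(out) <- NULL
  attr(out, "coverage_model") <- model
  out
}
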