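# Scoring a validation run against a truth set: greedy one-to-one matching,
# recall/precision/F1, optional repeat-region stratification.

#' Do a call and a truth record match?
#'
#' Match requires the same SV type, breakpoint distance (max of |start
#' difference| and |end difference|) at most `tolerance_bp`, and a length
#' ratio `min(lenA, lenB) / max(lenA, lenB)` of at least `length_ratio_min`.
#'
#' @param call,truth one-row SV tables (or result rows with the SV
#'   columns).
#' @param tolerance_bp breakpoint tolerance, bp (default 1000).
#' @param length_ratio_min minimum length ratio (default 0.5).
#' @return logical flag.
#' @export
match_sv <- function(call, truth, tolerance_bp = 1000L,
                     length_ratio_min = 0.5) {
  if (call$sv_type != truth$sv_type || call$chrom != truth$chrom) {
    return(FALSE)
  }
  bp_dist <- max(abs(call$start - truth$start), abs(call$end - truth$end))
  ratio <- min(call$length, truth$length) / max(call$length, truth$length)
  bp_dist <= tolerance_bp && ratio >= length_ratio_min
}

# Greedy one-to-one assignment of calls to truth records, nearest
# breakpoint first. Returns an integer vector over truth rows: the matched
# call row index or NA.
greedy_match <- function(calls, truth, tolerance_bp = 1000L,
                         length_ratio_min = 0.5) {
  assignment <- rep(NA_integer_, nrow(truth))
  if (nrow(calls) == 0L || nrow(truth) == 0L) return(assignment)
  cand <- list()
  for (ti in seq_len(nrow(truth))) {
    for (ci in seq_len(nrow(calls))) {
      if (match_sv(calls[ci, ], truth[ti, ], tolerance_bp,
                   length_ratio_min)) {
        d <- max(abs(calls$start[ci] - truth$start[ti]),
                 abs(calls$end[ci] - truth$end[ti]))
        cand[[length(cand) + 1L]] <- c(ti, ci, d)
      }
    }
  }
  if (!length(cand)) return(assignment)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  used_call <- logical(nrow(calls))
  for (k in seq_len(nrow(cand))) {
    ti <- cand[k, 1]; ci <- cand[k, 2]
    if (is.na(assignment[ti]) && !used_call[ci]) {
      assignment[ti] <- ci
      used_call[ci] <- TRUE
    }
  }
  assignment
}

metric_block <- function(tp, fp, fn) {
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (!is.na(fp) && tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(true_positives = tp, false_positives = fp, false_negatives = fn,
       recall = recall, precision = precision, f1 = f1)
}

#' Score a validation run against a truth set
#'
#' A truth SV counts as found when it matches a validated call labelled
#' HOMOZYGOUS or HETEROZYGOUS; recall is `found / n_truth`. A false-list
#' record counts as correctly rejected iff its label is FALSE; the others
#' contribute false positives. Precision is `TP / (TP + FP)` and F1 the
#' harmonic mean. With a repeat BED the report is additionally stratified
#' into repeat-overlapping and normal truth SVs.
#'
#' @param validated_true results data.frame for the truth list (from
#'   [validate_all()] or [read_results()]).
#' @param validated_false optional results data.frame for a false-SV list.
#' @param truth truth SV table.
#' @param repeat_bed optional data.frame `chrom, start, end` of repeat
#'   regions.
#' @param tolerance_bp,length_ratio_min matching thresholds (see
#'   [match_sv()]).
#' @return a `longsv_metrics` list: counts, `recall`, `precision`, `f1`,
#'   and optionally `strata`.
#' @export
score_run <- function(validated_true, validated_false = NULL, truth,
                      repeat_bed = NULL, tolerance_bp = 1000L,
                      length_ratio_min = 0.5) {
  if (nrow(truth) == 0L) stop("empty truth set")
  found_calls <- validated_true[validated_true$label %in%
                                  c(LABEL_HOM, LABEL_HET), , drop = FALSE]
  assignment <- greedy_match(found_calls, truth, tolerance_bp,
                             length_ratio_min)
  found <- !is.na(assignment)
  tp <- sum(found)
  fn <- sum(!found)
  fp <- if (is.null(validated_false)) 0L
        else sum(validated_false$label != LABEL_FALSE)
  out <- metric_block(tp, fp, fn)
  out$n_truth <- nrow(truth)
  if (!is.null(repeat_bed) && nrow(repeat_bed)) {
    in_rep <- vapply(seq_len(nrow(truth)), function(i) {
      any(repeat_bed$chrom == truth$chrom[i] &
            repeat_bed$start < truth$end[i] &
            truth$start[i] < repeat_bed$end)
    }, logical(1))
    out$strata <- list(
      repeat_region = metric_block(sum(found & in_rep), NA_integer_,
                                   sum(!found & in_rep)),
      normal_region = metric_block(sum(found & !in_rep), NA_integer_,
                                   sum(!found & !in_rep))
    )
  }
  class(out) <- "longsv_metrics"
  out
}

#' @export
print.longsv_metrics <- function(x, ...) {
  cat(sprintf("longsv metrics: TP %d  FP %s  FN %d  recall %.4f  precision %s  F1 %s\n",
              x$true_positives, format(x$false_positives),
              x$false_negatives, x$recall,
              ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
              ifelse(is.na(x$f1), "NA", sprintf("%.4f", x$f1))))
  invisible(x)
}
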