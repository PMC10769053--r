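# Step 2 of the pipeline: decide, per screened read, whether its alignment
# evidence (CIGAR indels or split segments) is consistent with the candidate
# SV's type and length.

#' Length tolerance for accepting a read's implied SV length
#'
#' `distance_support(L) = 0.2 * L + 2000 / L` bp. The linear term tolerates
#' proportional breakpoint slop on long SVs; the reciprocal term gives short
#' SVs the absolute slack long-read noise demands. The function is minimized
#' at L = 100 where both terms equal 20.
#'
#' @param sv_length candidate SV length in bp, positive.
#' @return tolerance in bp (vectorized).
#' @export
distance_support <- function(sv_length) {
  if (any(sv_length <= 0)) stop("sv_length must be positive")
  0.2 * sv_length + 2000 / sv_length
}

#' Screen candidate reads at an SV
#'
#' A read is retained iff (a) its best segment has MAPQ >= `mapq_min` and
#' (b) the union of its segments' reference spans covers both flank points
#' `start - flank_len` and `end + flank_len - 1` (i.e. the read traverses
#' the whole flanked region, possibly via split segments). Retained reads
#' are the denominator of the support rate.
#'
#' @param segments data.frame from [fetch_segments()] over the flanked
#'   window.
#' @param sv one-row SV table.
#' @param params [validation_params()].
#' @return the retained rows of `segments` (same columns).
#' @export
screen_reads <- function(segments, sv, params = validation_params()) {
  if (nrow(segments) == 0L) return(segments)
  p1 <- max(sv$start - params$flank_len, 0L)
  p2 <- sv$end + params$flank_len - 1L
  covers <- function(df, p) any(df$ref_start <= p & p < df$ref_end)
  keep <- vapply(split(seq_len(nrow(segments)), segments$read_id),
                 function(idx) {
    df <- segments[idx, , drop = FALSE]
    max(df$mapq) >= params$mapq_min && covers(df, p1) && covers(df, p2)
  }, logical(1))
  keep_ids <- names(keep)[keep]
  out <- segments[segments$read_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Net CIGAR indel length inside a window
#'
#' Walks the segment's CIGAR and sums `+len` for each insertion and `-len`
#' for each deletion of length >= `min_op` whose reference anchor lies in
#' `[window_start, window_end)`. Summing nets the several CIGAR operations a
#' single SV is often fragmented into inside repeat regions, so the read is
#' judged on its total implied SV length.
#'
#' @param segment one row of a segments data.frame (uses `cigar`,
#'   `ref_start`).
#' @param window_start,window_end 0-based half-open window.
#' @param min_op minimum operation length counted (default 30).
#' @return signed bp (insertion-positive, deletion-negative).
#' @export
net_indel_in_window <- function(segment, window_start, window_end,
                                min_op = 30L) {
  ops <- cigar_ops(segment$cigar)
  if (any(!ops$op %in% c("M", "=", "X", "I", "D", "S", "H", "N", "P"))) {
    stop("malformed CIGAR: ", segment$cigar)
  }
  refpos <- segment$ref_start
  net <- 0L
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op == "D") {
      if (len >= min_op && refpos >= window_start && refpos < window_end) {
        net <- net - len
      }
      refpos <- refpos + len
    } else if (op == "I") {
      anchor <- refpos - 1L  # reference base immediately left of the insertion
      if (len >= min_op && anchor >= window_start && anchor < window_end) {
        net <- net + len
      }
    } else if (op %in% c("M", "=", "X", "N")) {
      refpos <- refpos + len
    }
  }
  as.integer(net)
}

support_evidence <- function(read_id, supports, implied_length, channel,
                             kind = "indel") {
  list(read_id = read_id, supports = supports,
       implied_length = as.integer(implied_length), channel = channel,
       kind = kind)
}

no_evidence <- function(read_id) {
  support_evidence(read_id, FALSE, 0L, "none", "none")
}

#' CIGAR-channel support for a deletion or insertion
#'
#' Computes the net indel length over the flanked window
#' `(start - flank_len, end + flank_len)` on the read's longest segment. The
#' read supports the candidate iff the net's sign matches the SV type
#' (negative for DEL, positive for INS) and
#' `| |net| - length | <= distance_support(length)`.
#'
#' @param group segments of one read (data.frame rows).
#' @param sv one-row SV table with `sv_type` DEL or INS.
#' @param params [validation_params()].
#' @return a support-evidence list (`read_id`, `supports`,
#'   `implied_length`, `channel`).
#' @export
cigar_supports_indel <- function(group, sv, params = validation_params()) {
  stopifnot(sv$sv_type %in% c("DEL", "INS"))
  main <- group[which.max(group$ref_end - group$ref_start), , drop = FALSE]
  net <- net_indel_in_window(main,
                             sv$start - params$flank_len,
                             sv$end + params$flank_len,
                             params$min_cigar_indel)
  if (net == 0L) return(no_evidence(main$read_id))
  sign_ok <- (sv$sv_type == "DEL" && net < 0L) ||
             (sv$sv_type == "INS" && net > 0L)
  ok <- sign_ok && abs(abs(net) - sv$length) <= distance_support(sv$length)
  support_evidence(main$read_id, ok, net, "cigar")
}

#' Split-read distance difference between two segments of one read
#'
#' For two same-chromosome, same-strand segments ordered by forward-read
#' query position: `read_distance - ref_distance`, where
#' `ref_distance = ref_start(b) - ref_end(a)` and
#' `read_distance = query_start(b) - query_end(a)`. Positive values are
#' insertion-like (extra read sequence), negative deletion-like (missing
#' reference). Returns `NA` when the pair is on different chromosomes or
#' strands.
#'
#' @param seg_a,seg_b one-row segment data.frames.
#' @return signed bp or `NA`.
#' @export
split_difference <- function(seg_a, seg_b) {
  if (seg_a$chrom != seg_b$chrom || seg_a$strand != seg_b$strand) {
    return(NA_integer_)
  }
  if (seg_a$query_start > seg_b$query_start) {
    tmp <- seg_a; seg_a <- seg_b; seg_b <- tmp
  }
  # a reverse-strand read walks the reference right-to-left in query
  # order, so the genomic gap between consecutive segments flips
  ref_distance <- if (seg_a$strand == "+") seg_b$ref_start - seg_a$ref_end
                  else seg_a$ref_start - seg_b$ref_end
  read_distance <- seg_b$query_start - seg_a$query_end
  as.integer(read_distance - ref_distance)
}

#' Split-read support for a deletion or insertion
#'
#' Applies the distance-difference rule: a difference above
#' `+split_diff_threshold` signals an insertion, below the negative
#' threshold a deletion; the read supports the candidate iff the sign
#' matches and `| |difference| - length | <= distance_support(length)`.
#'
#' @param group segments of one read; the two largest same-chromosome,
#'   same-strand segments are used.
#' @inheritParams cigar_supports_indel
#' @return a support-evidence list.
#' @export
split_supports_indel <- function(group, sv, params = validation_params()) {
  stopifnot(sv$sv_type %in% c("DEL", "INS"))
  read_id <- group$read_id[1]
  g <- group[group$chrom == sv$chrom, , drop = FALSE]
  if (nrow(g) < 2L) return(no_evidence(read_id))
  # dominant strand pair: the two longest segments on one strand
  g <- g[order(g$query_end - g$query_start, decreasing = TRUE), , drop = FALSE]
  strands <- unique(g$strand)
  best <- NULL
  for (s in strands) {
    gs <- g[g$strand == s, , drop = FALSE]
    if (nrow(gs) >= 2L) { best <- gs[1:2, , drop = FALSE]; break }
  }
  if (is.null(best)) return(no_evidence(read_id))
  d <- split_difference(best[1, , drop = FALSE], best[2, , drop = FALSE])
  if (is.na(d) || abs(d) <= params$split_diff_threshold) {
    return(no_evidence(read_id))
  }
  sign_ok <- (sv$sv_type == "DEL" && d < 0L) || (sv$sv_type == "INS" && d > 0L)
  ok <- sign_ok && abs(abs(d) - sv$length) <= distance_support(sv$length)
  support_evidence(read_id, ok, d, "split")
}

#' Forward and reverse-complement noise of a read across an inversion
#'
#' Projects the read sequence onto the candidate interval `[start, end)` via
#' the CIGAR of its spanning segment and measures two edit distances:
#' `noise1` against the forward reference segment and `noise2` against its
#' reverse complement. A read carrying the inversion is far from the forward
#' reference but close to its reverse complement.
#'
#' @param group segments of one read; the segment spanning `[start, end)` is
#'   used.
#' @param sv one-row SV table with `sv_type` INV.
#' @param reference named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @return list `(noise1, noise2)`, or `NULL` when no segment spans the
#'   interval or the read sequence is unavailable.
#' @export
inv_noise_counts <- function(group, sv, reference) {
  stopifnot(sv$sv_type == "INV")
  ref_seq <- contig_sequence(reference, sv$chrom)
  if (is.null(ref_seq)) stop("reference contig '", sv$chrom, "' not found")
  span <- group[group$ref_start <= sv$start & group$ref_end >= sv$end, ,
                drop = FALSE]
  span <- span[!is.na(span$seq) & span$seq != "", , drop = FALSE]
  if (nrow(span) == 0L) return(NULL)
  seg <- span[which.max(span$ref_end - span$ref_start), , drop = FALSE]
  off <- query_offset_at_ref(seg$cigar, seg$ref_start, c(sv$start, sv$end))
  if (anyNA(off) || off[2] <= off[1]) return(NULL)
  read_sub <- substr(seg$seq, off[1] + 1L, off[2])
  ref_sub <- substr(ref_seq, sv$start + 1L, sv$end)
  list(
    noise1 = edit_distance(read_sub, ref_sub),
    noise2 = edit_distance(read_sub, revcomp(ref_sub))
  )
}

#' Inversion support from noise counts
#'
#' The read supports the inversion iff `noise1 / length >=
#' inv_fwd_noise_min` (the read is unlike the forward reference) and
#' `noise2 / length <= inv_rev_noise_max` (it matches the reverse
#' complement).
#'
#' @param noise1,noise2 edit distances from [inv_noise_counts()].
#' @param inv_length candidate inversion length, bp.
#' @param params [validation_params()].
#' @return logical flag.
#' @export
cigar_supports_inv <- function(noise1, noise2, inv_length,
                               params = validation_params()) {
  stopifnot(inv_length > 0)
  noise1 / inv_length >= params$inv_fwd_noise_min &&
    noise2 / inv_length <= params$inv_rev_noise_max
}

#' Split-read support for an inversion
#'
#' Three-segment geometry: segments on one chromosome with strand pattern
#' (s, -s, s) in query order and the middle segment overlapping
#' `[start, end)`; the implied span is `ref_start(third) - ref_end(first)`.
#' Two-segment geometry (inversions too large for any read to traverse):
#' opposite strands; at the left breakpoint the implied span is
#' `|ref_end(a) - ref_end(b)|`, at the right breakpoint
#' `|ref_start(a) - ref_start(b)|`. In all cases the read supports the
#' candidate iff `|span - length| <= distance_support(length)`.
#'
#' @inheritParams inv_noise_counts
#' @param params [validation_params()].
#' @return a support-evidence list (`kind == "inv"`).
#' @export
split_supports_inv <- function(group, sv, params = validation_params()) {
  stopifnot(sv$sv_type == "INV")
  read_id <- group$read_id[1]
  g <- group[group$chrom == sv$chrom, , drop = FALSE]
  g <- g[order(g$query_start), , drop = FALSE]
  if (nrow(g) < 2L || length(unique(g$strand)) < 2L) {
    return(no_evidence(read_id))
  }
  tol <- distance_support(sv$length)
  if (nrow(g) >= 3L) {
    # scan consecutive triples for the (s, -s, s) pattern
    for (i in seq_len(nrow(g) - 2L)) {
      t3 <- g[i:(i + 2L), , drop = FALSE]
      if (t3$strand[1] == t3$strand[3] && t3$strand[2] != t3$strand[1] &&
          t3$ref_start[2] < sv$end && t3$ref_end[2] > sv$start) {
        # outer segments in genomic order (a reverse-sequenced read walks
        # the locus right-to-left in query order)
        outer <- t3[c(1L, 3L), , drop = FALSE]
        outer <- outer[order(outer$ref_start), , drop = FALSE]
        span <- outer$ref_start[2] - outer$ref_end[1]
        ok <- abs(span - sv$length) <= tol
        return(support_evidence(read_id, ok, span, "split", "inv"))
      }
    }
  }
  if (nrow(g) == 2L && g$strand[1] != g$strand[2]) {
    covers_left <- any(g$ref_start < sv$start)
    covers_right <- any(g$ref_end > sv$end)
    spans <- c(
      if (covers_left) abs(g$ref_end[2] - g$ref_end[1]),
      if (covers_right) abs(g$ref_start[2] - g$ref_start[1])
    )
    if (length(spans)) {
      span <- spans[which.min(abs(spans - sv$length))]
      ok <- abs(span - sv$length) <= tol
      return(support_evidence(read_id, ok, span, "split", "inv"))
    }
  }
  no_evidence(read_id)
}

#' Decide whether one read supports a candidate SV
#'
#' Dispatcher over the evidence channels. For DEL/INS the CIGAR channel is
#' tried first, then the split channel; for INV the noise (CIGAR) channel is
#' used when the read has a single segment spanning the interval, otherwise
#' the split geometry. The first supporting channel wins; otherwise the
#' non-supporting evidence with the largest implied length is returned.
#'
#' @param group segments of one screened read.
#' @param sv one-row SV table.
#' @param params [validation_params()].
#' @param reference contig sequences; required for INV candidates whose
#'   reads span the interval in one segment.
#' @return a support-evidence list.
#' @export
evidence_for_read <- function(group, sv, params = validation_params(),
                              reference = NULL) {
  if (sv$sv_type %in% c("DEL", "INS")) {
    e1 <- cigar_supports_indel(group, sv, params)
    if (e1$supports) return(e1)
    e2 <- if (nrow(group) >= 2L) split_supports_indel(group, sv, params)
          else no_evidence(group$read_id[1])
    if (e2$supports) return(e2)
    if (abs(e2$implied_length) > abs(e1$implied_length)) e2 else e1
  } else {
    # single-alignment reads carry the inversion as forced-through mismatch
    # (noise channel); multi-segment reads carry it as strand-discordant
    # split geometry, where the aligned middle matches the forward
    # reference and the noise criteria are uninformative
    spanning <- nrow(group) == 1L &&
      any(group$ref_start <= sv$start & group$ref_end >= sv$end)
    if (spanning) {
      if (is.null(reference)) {
        stop("a reference sequence is required to evaluate INV candidates")
      }
      nc <- inv_noise_counts(group, sv, reference)
      if (!is.null(nc) &&
          cigar_supports_inv(nc$noise1, nc$noise2, sv$length, params)) {
        return(support_evidence(group$read_id[1], TRUE, sv$end - sv$start,
                                "cigar", "inv"))
      }
      no_evidence(group$read_id[1])
    } else {
      split_supports_inv(group, sv, params)
    }
  }
}

# --- sequence helpers -------------------------------------------------------

contig_sequence <- function(reference, chrom) {
  if (is.null(reference)) return(NULL)
  if (inherits(reference, "DNAStringSet") || inherits(reference, "XStringSet")) {
    if (!chrom %in% names(reference)) return(NULL)
    return(as.character(reference[[chrom]]))
  }
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && !chrom %in% names(reference)) {
    fa <- Biostrings::readDNAStringSet(reference)
    names(fa) <- sub("\\s.*$", "", names(fa))
    if (!chrom %in% names(fa)) return(NULL)
    return(as.character(fa[[chrom]]))
  }
  if (!chrom %in% names(reference)) return(NULL)
  unname(reference[[chrom]])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Levenshtein edit distance (unit costs) between two sequences.
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b)[1, 1])
}
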