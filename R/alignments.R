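# Alignment segments: one row per (read, alignment record), with query
# coordinates normalized to the forward orientation of the read so that a
# read's primary and supplementary segments share one query axis.

# Parse one CIGAR string into an ops data.frame (op, len).
cigar_ops <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# Full query length including hard clips; per-CIGAR vectorized.
cigar_full_query_length <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  mapply(function(o, l) sum(l[o %in% c("M", "I", "S", "H", "=", "X")]),
         ops, lens, USE.NAMES = FALSE)
}

# Leading/trailing clip lengths (S and H combined) of each CIGAR.
cigar_clips <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  lead <- mapply(function(o, l) {
    i <- 1L; tot <- 0L
    while (i <= length(o) && o[i] %in% c("S", "H")) { tot <- tot + l[i]; i <- i + 1L }
    tot
  }, ops, lens, USE.NAMES = FALSE)
  trail <- mapply(function(o, l) {
    i <- length(o); tot <- 0L
    while (i >= 1L && o[i] %in% c("S", "H")) { tot <- tot + l[i]; i <- i - 1L }
    tot
  }, ops, lens, USE.NAMES = FALSE)
  list(lead = lead, trail = trail)
}

#' Fetch alignment segments overlapping a window
#'
#' Returns every primary and supplementary alignment record overlapping
#' `[window_start, window_end)` on `chrom`, one row per record, with query
#' coordinates expressed on the forward orientation of the read. Secondary
#' and unmapped records are excluded. Rows of the same read share a
#' `read_id`, so `split(seg, seg$read_id)` yields read groups.
#'
#' @param bam path to a coordinate-sorted, indexed BAM (or a
#'   `Rsamtools::BamFile`).
#' @param chrom contig name.
#' @param window_start,window_end 0-based half-open window.
#' @return data.frame with columns `read_id, chrom, ref_start, ref_end,
#'   query_start, query_end, strand, mapq, cigar, is_supplementary, seq`
#'   (`seq` is the stored, aligned-orientation sequence, `NA` if absent).
#' @export
fetch_segments <- function(bam, chrom, window_start, window_end) {
  stopifnot(window_start < window_end)
  bf <- as_bamfile(bam)
  hdr <- Rsamtools::scanBamHeader(bf)
  targets <- hdr$targets
  if (!chrom %in% names(targets)) {
    warning("contig '", chrom, "' absent from BAM header")
    return(empty_segments())
  }
  which <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(window_start + 1L, window_end))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    what = c("qname", "flag", "pos", "mapq", "cigar", "strand", "seq"),
    which = which
  )
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) return(empty_segments())

  cig <- res$cigar
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  full_len <- cigar_full_query_length(cig)
  clips <- cigar_clips(cig)
  strand <- as.character(res$strand)
  qs <- ifelse(strand == "+", clips$lead, clips$trail)
  qe <- ifelse(strand == "+", full_len - clips$trail, full_len - clips$lead)

  seg <- data.frame(
    read_id = res$qname,
    chrom = chrom,
    ref_start = res$pos - 1L,
    ref_end = res$pos - 1L + ref_w,
    query_start = as.integer(qs),
    query_end = as.integer(qe),
    strand = strand,
    mapq = res$mapq,
    cigar = cig,
    is_supplementary = bitwAnd(res$flag, 2048L) > 0L,
    seq = as.character(res$seq),
    stringsAsFactors = FALSE
  )
  seg <- seg[!duplicated(seg[, c("read_id", "chrom", "ref_start", "cigar")]), ]
  seg <- seg[order(seg$read_id, seg$query_start, seg$ref_start), ]
  rownames(seg) <- NULL
  seg
}

empty_segments <- function() {
  data.frame(read_id = character(), chrom = character(),
             ref_start = integer(), ref_end = integer(),
             query_start = integer(), query_end = integer(),
             strand = character(), mapq = integer(), cigar = character(),
             is_supplementary = logical(), seq = character(),
             stringsAsFactors = FALSE)
}

as_bamfile <- function(bam) {
  if (inherits(bam, "BamFile")) return(bam)
  idx <- paste0(bam, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam)
  if (!file.exists(idx) && !file.exists(idx2)) {
    stop("BAM index not found for '", bam,
         "'; create one with Rsamtools::indexBam() or `samtools index`")
  }
  Rsamtools::BamFile(bam)
}

# Map reference positions to query offsets along one alignment record.
# `targets` are 0-based reference positions; returns 0-based offsets into the
# stored (aligned-orientation) sequence, NA when the record does not reach a
# target. A position inside a deletion maps to the query offset at its right
# edge.
query_offset_at_ref <- function(cigar, ref_start, targets) {
  ops <- cigar_ops(cigar)
  refpos <- ref_start
  qpos <- 0L
  out <- rep(NA_integer_, length(targets))
  ord <- order(targets)
  ti <- 1L
  tg <- targets[ord]
  while (ti <= length(tg) && tg[ti] < ref_start) ti <- ti + 1L  # unreachable
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    consumes_ref <- op %in% c("M", "D", "N", "=", "X")
    consumes_q <- op %in% c("M", "I", "S", "=", "X")
    if (consumes_ref) {
      while (ti <= length(tg) && tg[ti] < refpos + len) {
        if (tg[ti] >= refpos) {
          out[ord[ti]] <- if (op == "D" || op == "N") qpos
                          else qpos + (tg[ti] - refpos)
          ti <- ti + 1L
        } else break
      }
      refpos <- refpos + len
    }
    if (consumes_q) qpos <- qpos + len
    if (ti > length(tg)) break
  }
  # a target exactly at ref_end maps to the end of the aligned query
  at_end <- is.na(out) & targets == refpos
  out[at_end] <- qpos
  out
}
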