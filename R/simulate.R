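# Synthetic-data generator: a repeat-bearing reference, implanted hom/het
# DEL/INS/INV, and noisy long reads emitted directly as ground-truth SAM
# alignment records (no aligner involved), so every CIGAR op and split
# segment is known to be correct by construction.

#' Simulation configuration
#'
#' Defaults describe the package's reference study conditions: a 200 kb
#' single-contig genome with 30% tandem-repeat content, 20 homozygous and
#' 20 heterozygous SVs cycling through DEL/INS/INV with lengths 200-1000 bp,
#' and ~15 kb reads at 30-fold total depth. `error_rate` is the per-base
#' probability of a sequencing error, split 60/20/20 between mismatches and
#' short (1-3 bp) insertions/deletions; 0 gives noise-free reads.
#' Deletions at least `del_split_min` bp are emitted as split (primary +
#' supplementary) alignments rather than one D op; inversions longer than
#' `inv_split_min` bp are emitted as strand-discordant three-segment split
#' reads, shorter ones as a single forced-through match segment whose
#' sequence is the reverse complement of the reference. `frag_mode`
#' fragments each implanted indel's CIGAR op into two ops separated by a
#' `frag_gap` bp spacer, imitating the multi-op signatures aligners produce
#' in repeat regions.
#'
#' @param genome_length contig length, bp.
#' @param repeat_fraction fraction of the genome inside tandem-repeat
#'   blocks.
#' @param repeat_unit_len tandem-repeat unit length, bp.
#' @param n_hom,n_het implanted SV counts by zygosity.
#' @param sv_types SV types, cycled over the implants.
#' @param sv_length_range inclusive bp range of implanted SV lengths.
#' @param read_length_mean,read_length_sd read-length distribution, bp.
#' @param depth total fold-coverage (both haplotypes combined).
#' @param error_rate per-base error probability in `[0, 0.25]`.
#' @param del_split_min,inv_split_min split-alignment emission thresholds,
#'   bp.
#' @param frag_mode,frag_gap CIGAR fragmentation toggle and spacer, bp.
#' @param mapq mapping quality written on every record.
#' @param chrom contig name.
#' @param rng_seed master seed; every downstream draw derives from it.
#' @return a list of class `longsv_simconfig`.
#' @export
sim_config <- function(genome_length = 200000L,
                       repeat_fraction = 0.3,
                       repeat_unit_len = 24L,
                       n_hom = 20L,
                       n_het = 20L,
                       sv_types = c("DEL", "INS", "INV"),
                       sv_length_range = c(200L, 1000L),
                       read_length_mean = 15000L,
                       read_length_sd = 1500L,
                       depth = 30,
                       error_rate = 0,
                       del_split_min = 2500L,
                       inv_split_min = 400L,
                       frag_mode = FALSE,
                       frag_gap = 20L,
                       mapq = 60L,
                       chrom = "chr1",
                       rng_seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              repeat_fraction = repeat_fraction,
              repeat_unit_len = as.integer(repeat_unit_len),
              n_hom = as.integer(n_hom), n_het = as.integer(n_het),
              sv_types = match.arg(sv_types, SV_TYPES, several.ok = TRUE),
              sv_length_range = as.integer(sv_length_range),
              read_length_mean = as.integer(read_length_mean),
              read_length_sd = as.integer(read_length_sd),
              depth = depth, error_rate = error_rate,
              del_split_min = as.integer(del_split_min),
              inv_split_min = as.integer(inv_split_min),
              frag_mode = isTRUE(frag_mode), frag_gap = as.integer(frag_gap),
              mapq = as.integer(mapq), chrom = chrom,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$genome_length >= 10000L,
            cfg$repeat_fraction >= 0, cfg$repeat_fraction < 1,
            cfg$depth > 0, cfg$error_rate >= 0, cfg$error_rate <= 0.25,
            all(cfg$sv_length_range >= 50L),
            diff(cfg$sv_length_range) >= 0L)
  class(cfg) <- "longsv_simconfig"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference with tandem-repeat blocks
#'
#' Background sequence is i.i.d. ACGT; tandem-repeat blocks (a random unit
#' repeated to block length) are interspersed until `repeat_fraction` of the
#' genome is repetitive. Deterministic per seed.
#'
#' @param config [sim_config()].
#' @return list with `sequence` (character scalar) and `repeats`
#'   (data.frame `chrom, start, end`, 0-based half-open).
#' @export
generate_reference <- function(config = sim_config()) {
  with_seed(config$rng_seed, {
    L <- config$genome_length
    target <- round(config$repeat_fraction * L)
    repeats <- data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
    seq <- random_dna(L)
    if (target > 0) {
      block_len <- 2000L
      n_blocks <- ceiling(target / block_len)
      slot <- L %/% n_blocks
      placed <- 0L
      rows <- list()
      for (b in seq_len(n_blocks)) {
        this_len <- min(block_len, target - placed)
        if (this_len < config$repeat_unit_len) break
        lo <- (b - 1L) * slot
        start <- lo + sample.int(max(slot - this_len, 1L), 1L) - 1L
        unit <- random_dna(config$repeat_unit_len)
        block <- strtrim(paste(rep(unit, ceiling(this_len /
                   config$repeat_unit_len)), collapse = ""), this_len)
        substr(seq, start + 1L, start + this_len) <- block
        rows[[b]] <- data.frame(chrom = config$chrom, start = start,
                                end = start + this_len,
                                stringsAsFactors = FALSE)
        placed <- placed + this_len
      }
      repeats <- do.call(rbind, rows)
    }
    list(sequence = seq, repeats = repeats)
  })
}

#' Implant hom/het SVs into two haplotypes
#'
#' Chooses non-overlapping loci (3 kb minimum separation, 6 kb contig
#' margins), draws lengths uniformly from `sv_length_range`, and applies
#' homozygous SVs to both haplotypes and heterozygous ones to a random
#' single haplotype. Haplotypes are represented as block maps
#' (match / insertion / inversion blocks on the reference frame) from which
#' both the haplotype sequence and ground-truth alignments derive.
#'
#' @param reference result of [generate_reference()] (or a character
#'   scalar).
#' @param config [sim_config()].
#' @return list with `truth` (SV table plus `zygosity`, `hap`, `ins_seq`)
#'   and `haps` (two block data.frames).
#' @export
implant_svs <- function(reference, config = sim_config()) {
  ref <- if (is.list(reference)) reference$sequence else reference
  with_seed(config$rng_seed + 1L, {
    n <- config$n_hom + config$n_het
    margin <- 6000L
    gap_min <- 3000L
    types <- rep_len(config$sv_types, n)
    lens <- sample(seq(config$sv_length_range[1], config$sv_length_range[2]),
                   n, replace = TRUE)
    zyg <- sample(rep(c("HOM", "HET"), c(config$n_hom, config$n_het)))
    span <- ifelse(types == "INS", 1L, lens)
    free <- config$genome_length - 2L * margin - sum(span) -
      (n - 1L) * gap_min
    if (free < 0) {
      stop("infeasible SV packing: shorten or reduce the implanted SVs")
    }
    extra <- diff(c(0, sort(stats::runif(n, 0, free))))
    starts <- margin + cumsum(extra) +
      c(0, cumsum(span[-n] + gap_min))
    starts <- as.integer(round(starts))
    ends <- as.integer(ifelse(types == "INS", starts + 1L, starts + lens))
    hap <- ifelse(zyg == "HOM", 0L, sample(1:2, n, replace = TRUE))
    ins_seq <- ifelse(types == "INS",
                      vapply(lens, random_dna, ""), NA_character_)
    truth <- sv_table(config$chrom, starts, ends, types, lens,
                      id = sprintf("sv%02d_%s_%s", seq_len(n), tolower(types),
                                   tolower(zyg)))
    truth$zygosity <- zyg
    truth$hap <- hap
    truth$ins_seq <- ins_seq
    haps <- lapply(1:2, function(h) {
      on_hap <- truth[truth$hap == 0L | truth$hap == h, , drop = FALSE]
      build_blocks(ref, on_hap, config$genome_length)
    })
    list(truth = truth, haps = haps)
  })
}

# Block map of one haplotype: rows (kind, ref_start, ref_end, hap_start,
# hap_end, ins_seq) with kind M (collinear), I (insertion, ref width 0) or
# V (inversion, reverse-complement of the reference span).
build_blocks <- function(ref, svs, genome_length) {
  svs <- svs[order(svs$start), , drop = FALSE]
  rows <- list()
  cur_ref <- 0L
  hap_pos <- 0L
  add <- function(kind, rs, re, hlen, ins = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, ref_start = rs, ref_end = re,
      hap_start = hap_pos, hap_end = hap_pos + hlen,
      ins_seq = ins, stringsAsFactors = FALSE)
    hap_pos <<- hap_pos + as.integer(hlen)
  }
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    if (sv$start > cur_ref) {
      m_end <- if (sv$sv_type == "INS") sv$start + 1L else sv$start
      add("M", cur_ref, m_end, m_end - cur_ref)
      cur_ref <- m_end
    }
    if (sv$sv_type == "DEL") {
      cur_ref <- sv$end
    } else if (sv$sv_type == "INS") {
      add("I", cur_ref, cur_ref, sv$length, sv$ins_seq)
    } else {  # INV
      add("V", sv$start, sv$end, sv$end - sv$start)
      cur_ref <- sv$end
    }
  }
  if (cur_ref < genome_length) {
    add("M", cur_ref, genome_length, genome_length - cur_ref)
  }
  do.call(rbind, rows)
}

# Haplotype sequence from its block map.
hap_sequence <- function(ref, blocks) {
  pieces <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    switch(b$kind,
      M = substr(ref, b$ref_start + 1L, b$ref_end),
      I = b$ins_seq,
      V = revcomp(substr(ref, b$ref_start + 1L, b$ref_end)))
  }, "")
  paste(pieces, collapse = "")
}

#' Simulate long reads as ground-truth SAM alignment records
#'
#' Draws reads from the two haplotypes at the configured depth and length,
#' and emits each read's alignment to the reference computed from its known
#' haplotype origin: implanted indels become I/D CIGAR operations, long
#' deletions become primary + supplementary segment pairs, inversions become
#' either a forced-through match segment (short INV) or strand-discordant
#' split segments (long INV). Sequencing errors are injected into both the
#' sequence and the CIGAR. Records carry SA tags and are returned
#' coordinate-sorted.
#'
#' @param reference result of [generate_reference()] (or character scalar).
#' @param haps block maps from [implant_svs()].
#' @param config [sim_config()].
#' @return data.frame of SAM fields (`qname, flag, rname, pos, mapq, cigar,
#'   seq, tags`), coordinate-sorted.
#' @export
simulate_alignments <- function(reference, haps, config = sim_config()) {
  ref <- if (is.list(reference)) reference$sequence else reference
  with_seed(config$rng_seed + 2L, {
    recs <- list()
    for (h in 1:2) {
      blocks <- haps[[h]]
      block_seqs <- vapply(seq_len(nrow(blocks)), function(i) {
        b <- blocks[i, ]
        switch(b$kind,
          M = substr(ref, b$ref_start + 1L, b$ref_end),
          I = b$ins_seq,
          V = revcomp(substr(ref, b$ref_start + 1L, b$ref_end)))
      }, "")
      hap_len <- blocks$hap_end[nrow(blocks)]
      n_reads <- max(1L, round((config$depth / 2) * hap_len /
                                 config$read_length_mean))
      for (j in seq_len(n_reads)) {
        rl <- round(stats::rnorm(1, config$read_length_mean,
                                 config$read_length_sd))
        rl <- as.integer(min(max(rl, config$read_length_mean %/% 2),
                             hap_len))
        a <- sample.int(hap_len - rl + 1L, 1L) - 1L
        sigma <- sample(c("+", "-"), 1L)
        qname <- sprintf("read_h%d_%05d", h, j)
        recs[[length(recs) + 1L]] <-
          emit_read(qname, a, rl, sigma, blocks, block_seqs, config)
      }
    }
    recs <- do.call(rbind, recs)
    recs <- recs[order(recs$rname, recs$pos, recs$qname), , drop = FALSE]
    rownames(recs) <- NULL
    recs
  })
}

# Build the SAM records of one read from its haplotype interval [a, a+rl).
emit_read <- function(qname, a, rl, sigma, blocks, block_seqs, config) {
  b_hit <- which(blocks$hap_end > a & blocks$hap_start < a + rl)
  pieces <- lapply(b_hit, function(i) {
    b <- blocks[i, ]
    h1 <- max(a, b$hap_start); h2 <- min(a + rl, b$hap_end)
    o1 <- h1 - b$hap_start; o2 <- h2 - b$hap_start
    seqp <- substr(block_seqs[i], o1 + 1L, o2)
    if (b$kind == "M") {
      list(type = "M", ref_s = b$ref_start + o1, ref_e = b$ref_start + o2,
           seq = seqp)
    } else if (b$kind == "I") {
      list(type = "I", ref_s = b$ref_start, ref_e = b$ref_start, seq = seqp)
    } else {
      inv_len <- b$ref_end - b$ref_start
      if (inv_len <= config$inv_split_min) {
        # forced-through: collinear coordinates, reverse-complement sequence
        list(type = "M", ref_s = b$ref_start + o1, ref_e = b$ref_start + o2,
             seq = seqp)
      } else {
        list(type = "V", ref_s = b$ref_end - o2, ref_e = b$ref_end - o1,
             seq = seqp)
      }
    }
  })

  # assemble segments: lists of ops (per-column codes) + sequence, plus the
  # q offsets of each chunk on the built (haplotype-orientation) read
  segs <- list()
  chunks <- list()   # ordered: list(kind = "clip"/"seg", seq, seg_index)
  cur <- NULL
  pending_ins <- NULL
  close_cur <- function() {
    if (!is.null(cur)) {
      segs[[length(segs) + 1L]] <<- cur
      chunks[[length(chunks) + 1L]] <<- list(kind = "seg",
                                             seg_index = length(segs))
      cur <<- NULL
    }
  }
  drop_pending <- function() {
    if (!is.null(pending_ins)) {
      chunks[[length(chunks) + 1L]] <<- list(kind = "clip",
                                             seq = pending_ins)
      pending_ins <<- NULL
    }
  }
  for (p in pieces) {
    if (p$type == "I") {
      if (is.null(cur)) {
        drop_pending()
        pending_ins <- p$seq
      } else {
        pending_ins <- if (is.null(pending_ins)) p$seq
                       else paste0(pending_ins, p$seq)
      }
      next
    }
    if (p$type == "V") {
      drop_pending(); close_cur()
      cur <- list(orient = "R", ref_start = p$ref_s, ref_end = p$ref_e,
                  cols = rep("M", nchar(p$seq)), seq = p$seq)
      close_cur()
      next
    }
    # collinear M piece
    if (is.null(cur) || cur$orient == "R") {
      close_cur(); drop_pending()
      cur <- list(orient = "F", ref_start = p$ref_s, ref_end = p$ref_e,
                  cols = rep("M", nchar(p$seq)), seq = p$seq)
    } else {
      gap <- p$ref_s - cur$ref_end
      if (gap >= config$del_split_min || gap < 0L) {
        close_cur(); drop_pending()
        cur <- list(orient = "F", ref_start = p$ref_s, ref_end = p$ref_e,
                    cols = rep("M", nchar(p$seq)), seq = p$seq)
      } else {
        if (gap > 0L) cur$cols <- c(cur$cols, rep("D", gap))
        if (!is.null(pending_ins)) {
          cur$cols <- c(cur$cols, rep("I", nchar(pending_ins)))
          cur$seq <- paste0(cur$seq, pending_ins)
          pending_ins <- NULL
        }
        cur$cols <- c(cur$cols, rep("M", nchar(p$seq)))
        cur$seq <- paste0(cur$seq, p$seq)
        cur$ref_end <- p$ref_e
      }
    }
  }
  drop_pending(); close_cur()

  # CIGAR fragmentation (repeat-region style multi-op signatures)
  if (config$frag_mode) {
    segs <- lapply(segs, frag_segment, gap = config$frag_gap)
  }
  # sequencing errors
  if (config$error_rate > 0) {
    segs <- lapply(segs, noise_segment, rate = config$error_rate)
  }

  # rebuild read sequence and q offsets from the chunks
  qpos <- 0L
  read_built <- character(length(chunks))
  for (k in seq_along(chunks)) {
    ch <- chunks[[k]]
    if (ch$kind == "clip") {
      read_built[k] <- ch$seq
      qpos <- qpos + nchar(ch$seq)
    } else {
      s <- segs[[ch$seg_index]]
      segs[[ch$seg_index]]$q_start <- qpos
      segs[[ch$seg_index]]$q_end <- qpos + nchar(s$seq)
      read_built[k] <- s$seq
      qpos <- qpos + nchar(s$seq)
    }
  }
  read_built <- paste(read_built, collapse = "")
  L <- nchar(read_built)
  read_out <- if (sigma == "+") read_built else revcomp(read_built)

  # materialize SAM fields
  aligned_len <- vapply(segs, function(s)
    sum(s$cols != "D"), 0L)
  primary <- which.max(aligned_len)
  fields <- lapply(seq_along(segs), function(si) {
    s <- segs[[si]]
    strand <- if (sigma == "+") {
      if (s$orient == "F") "+" else "-"
    } else {
      if (s$orient == "F") "-" else "+"
    }
    q_out <- if (sigma == "+") c(s$q_start, s$q_end)
             else c(L - s$q_end, L - s$q_start)
    # ops in genome-forward order; for R-orientation segments the built
    # (haplotype) orientation is the reverse, so flip the column order
    cols <- if (s$orient == "R") rev(s$cols) else s$cols
    r <- rle(cols)
    lead <- if (strand == "+") q_out[1] else L - q_out[2]
    trail <- L - lead - sum(r$lengths[r$values != "D"])
    cig <- paste0(
      if (lead > 0L) paste0(lead, "S") else "",
      paste0(r$lengths, r$values, collapse = ""),
      if (trail > 0L) paste0(trail, "S") else "")
    list(strand = strand, pos = s$ref_start + 1L, cigar = cig,
         flag = (strand == "-") * 16L + (si != primary) * 2048L)
  })
  seqs <- vapply(fields, function(f)
    if (f$strand == "+") read_out else revcomp(read_out), "")
  sa <- vapply(seq_along(fields), function(si) {
    others <- setdiff(seq_along(fields), si)
    if (!length(others)) return("")
    paste0("SA:Z:", paste(vapply(others, function(o) {
      f <- fields[[o]]
      paste(config$chrom, f$pos, f$strand, f$cigar, config$mapq, 0,
            sep = ",")
    }, ""), collapse = ";"), ";")
  }, "")
  data.frame(
    qname = qname,
    flag = vapply(fields, `[[`, 0L, "flag"),
    rname = config$chrom,
    pos = vapply(fields, `[[`, 0L, "pos"),
    mapq = config$mapq,
    cigar = vapply(fields, `[[`, "", "cigar"),
    seq = seqs,
    tags = sa,
    stringsAsFactors = FALSE
  )
}

# Split each large D (or I) op into two ops >= 30 bp separated by a short
# matched spacer, leaving the read sequence and the net indel length
# unchanged: D(n)M(m) -> D(a)M(g)D(n-a)M(m-g), I likewise.
frag_segment <- function(s, gap) {
  r <- rle(s$cols)
  out_v <- character(0); out_l <- integer(0)
  k <- 1L
  while (k <= length(r$values)) {
    v <- r$values[k]; n <- r$lengths[k]
    if (v %in% c("D", "I") && n >= 60L + gap &&
        k < length(r$values) && r$values[k + 1L] == "M" &&
        r$lengths[k + 1L] > gap + 10L) {
      a <- n %/% 2L
      out_v <- c(out_v, v, "M", v, "M")
      out_l <- c(out_l, a, gap, n - a, r$lengths[k + 1L] - gap)
      k <- k + 2L
    } else {
      out_v <- c(out_v, v); out_l <- c(out_l, n)
      k <- k + 1L
    }
  }
  s$cols <- rep(out_v, out_l)
  s
}

# Inject per-base errors into one segment's columns and sequence.
noise_segment <- function(s, rate) {
  cols <- s$cols
  chars <- strsplit(s$seq, "")[[1]]
  qcols <- which(cols != "D")
  n_err <- stats::rbinom(1L, length(qcols), rate)
  if (n_err == 0L) return(s)
  at <- sort(sample(qcols, n_err))
  kind <- sample(c("mis", "ins", "del"), n_err, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  # process from the end so indices stay valid under insertion/deletion
  qidx <- cumsum(cols != "D")  # column -> query index
  for (e in rev(seq_len(n_err))) {
    col <- at[e]
    qi <- qidx[col]
    if (kind[e] == "mis") {
      chars[qi] <- sample(setdiff(c("A", "C", "G", "T"), chars[qi]), 1L)
    } else if (kind[e] == "del") {
      if (cols[col] == "M") cols[col] <- "D" else cols <- cols[-col]
      chars <- chars[-qi]
    } else {
      ilen <- sample(1:3, 1L)
      cols <- append(cols, rep("I", ilen), after = col)
      chars <- append(chars, sample(c("A", "C", "G", "T"), ilen,
                                    replace = TRUE), after = qi)
    }
  }
  s$cols <- cols
  s$seq <- paste(chars, collapse = "")
  s
}

#' Write alignment records as a SAM file
#'
#' @param records data.frame from [simulate_alignments()].
#' @param contigs named integer vector of contig lengths.
#' @param path output path.
#' @export
write_sam <- function(records, contigs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (nm in names(contigs)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, contigs[[nm]]), con)
  }
  if (nrow(records)) {
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                     records$qname, records$flag, records$rname,
                     records$pos, records$mapq, records$cigar, records$seq,
                     ifelse(nzchar(records$tags),
                            paste0("\t", records$tags), ""))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Convert a coordinate-sorted SAM to an indexed BAM
#'
#' @param sam_path input SAM.
#' @param bam_prefix output path without the `.bam` extension.
#' @return path to the indexed BAM.
#' @export
sam_to_bam <- function(sam_path, bam_prefix = sub("\\.sam$", "", sam_path)) {
  tmp <- Rsamtools::asBam(sam_path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  srt <- Rsamtools::sortBam(tmp, destination = bam_prefix)
  unlink(c(tmp, paste0(tmp, ".bai")))
  Rsamtools::indexBam(srt)
  srt
}

#' Generate a false-SV list by length multipliers
#'
#' Each DEL/INS truth record spawns one false record at the same locus
#' (midpoint fixed) whose length is the true length scaled by a multiplier
#' drawn uniformly from `multipliers`. With the default multiplier set every
#' false record's relative length error is at least 50% (minimum 60%, at
#' multiplier 0.4), which is what makes the list a stringent filtering
#' benchmark.
#'
#' @param truth_svs SV table (rows with `sv_type` INV are ignored: a
#'   length-scaled inversion centred on a real one is indistinguishable
#'   from a genuine sub-inversion).
#' @param rng_seed RNG seed.
#' @param multipliers multiplier set.
#' @return SV table with extra columns `multiplier`, `source_id`,
#'   `true_length`.
#' @export
make_false_svs <- function(truth_svs, rng_seed = 1L,
                           multipliers = c(0.1, 0.2, 0.3, 0.4, 2, 3, 4, 5)) {
  stopifnot(nrow(truth_svs) > 0)
  src <- truth_svs[truth_svs$sv_type %in% c("DEL", "INS"), , drop = FALSE]
  if (nrow(src) == 0L) stop("no DEL/INS records to derive false SVs from")
  with_seed(rng_seed, {
    m <- multipliers[sample.int(length(multipliers), nrow(src),
                                replace = TRUE)]
    new_len <- pmax(1L, as.integer(round(src$length * m)))
    mid <- (src$start + src$end) %/% 2L
    start <- ifelse(src$sv_type == "INS", src$start,
                    pmax(0L, mid - new_len %/% 2L))
    end <- ifelse(src$sv_type == "INS", src$start + 1L, start + new_len)
    out <- sv_table(src$chrom, start, end, src$sv_type, new_len,
                    id = paste0(src$id, "_false"))
    out$multiplier <- m
    out$source_id <- src$id
    out$true_length <- src$length
    out
  })
}

#' Write the full simulated fixture bundle
#'
#' Emits reference FASTA, coordinate-sorted SAM plus indexed BAM, truth
#' BED/TSV, repeat-region BED, and the false-SV BED into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param config [sim_config()].
#' @return named list of paths plus the in-memory `truth`, `false_svs`,
#'   `repeats`.
#' @export
simulate_bundle <- function(out_dir, config = sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(config)
  imp <- implant_svs(ref, config)
  recs <- simulate_alignments(ref, imp$haps, config)

  fasta <- file.path(out_dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(ref$sequence)
  names(dna) <- config$chrom
  Biostrings::writeXStringSet(dna, fasta, width = 80L)

  sam <- file.path(out_dir, "alignments.sam")
  contigs <- stats::setNames(config$genome_length, config$chrom)
  write_sam(recs, contigs, sam)
  bam <- sam_to_bam(sam)

  truth_bed <- file.path(out_dir, "truth.bed")
  write_sv_bed(imp$truth, truth_bed)
  truth_tsv <- file.path(out_dir, "truth.tsv")
  utils::write.table(imp$truth[, setdiff(names(imp$truth), "ins_seq")],
                     truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  repeat_bed <- file.path(out_dir, "repeats.bed")
  utils::write.table(ref$repeats, repeat_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  false_svs <- make_false_svs(imp$truth, config$rng_seed + 3L)
  false_bed <- file.path(out_dir, "false.bed")
  write_sv_bed(false_svs, false_bed)

  list(fasta = fasta, sam = sam, bam = bam, truth_bed = truth_bed,
       truth_tsv = truth_tsv, repeat_bed = repeat_bed,
       false_bed = false_bed, truth = imp$truth, false_svs = false_svs,
       repeats = ref$repeats, reference = ref$sequence)
}
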