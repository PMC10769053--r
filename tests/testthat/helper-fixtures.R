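# Programmatic SAM/BAM fixtures: tiny alignment files built in code.

sam_line <- function(qname, flag, rname, pos1, mapq, cigar, seq = "*",
                     tags = "") {
  paste(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0, seq, "*",
        if (nzchar(tags)) tags else NULL, sep = "\t")
}

# Write SAM lines (plus header) and convert to a sorted, indexed BAM.
fixture_bam <- function(lines, contigs = c(chr1 = 10000L)) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  writeLines(c(hdr, lines), sam)
  sam_to_bam(sam)
}

# n reads of `len`M starting at 1-based position 1 on each contig.
uniform_bam <- function(n, contigs = c(chr1 = 3000L)) {
  lines <- unlist(lapply(names(contigs), function(ch) {
    vapply(seq_len(n), function(i) {
      sam_line(sprintf("u_%s_%03d", ch, i), 0, ch, 1,
               60, paste0(contigs[[ch]], "M"))
    }, "")
  }))
  fixture_bam(lines, contigs)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A group data.frame in the fetch_segments layout, built by hand.
seg_row <- function(read_id, ref_start, ref_end, query_start, query_end,
                    strand = "+", mapq = 60L, cigar = NA_character_,
                    chrom = "chr1", seq = NA_character_,
                    is_supplementary = FALSE) {
  data.frame(read_id = read_id, chrom = chrom,
             ref_start = as.integer(ref_start),
             ref_end = as.integer(ref_end),
             query_start = as.integer(query_start),
             query_end = as.integer(query_end),
             strand = strand, mapq = as.integer(mapq), cigar = cigar,
             is_supplementary = is_supplementary, seq = seq,
             stringsAsFactors = FALSE)
}

# Mirror a read group onto the opposite sequencing strand: strand labels
# flip and forward-read query coordinates reflect about the read length.
flip_group <- function(group, read_len) {
  g <- group
  g$strand <- ifelse(group$strand == "+", "-", "+")
  g$query_start <- read_len - group$query_end
  g$query_end <- read_len - group$query_start
  g[order(g$query_start), , drop = FALSE]
}

# Independent brute-force oracle for the windowed net indel: walks the
# CIGAR string character by character (no shared code with the package).
oracle_net_indel <- function(cigar, ref_start, window_start, window_end,
                             min_op = 30L) {
  nums <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  refpos <- ref_start
  net <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] == "D") {
      if (nums[k] >= min_op && refpos >= window_start &&
          refpos < window_end) {
        net <- net - nums[k]
      }
      refpos <- refpos + nums[k]
    } else if (ops[k] == "I") {
      if (nums[k] >= min_op && (refpos - 1L) >= window_start &&
          (refpos - 1L) < window_end) {
        net <- net + nums[k]
      }
    } else if (ops[k] %in% c("M", "=", "X", "N")) {
      refpos <- refpos + nums[k]
    }
  }
  net
}

# Random valid CIGAR anchored by M runs.
random_cigar <- function() {
  n_ops <- sample(3:9, 1)
  ops <- character(n_ops)
  lens <- integer(n_ops)
  for (k in seq_len(n_ops)) {
    if (k %% 2 == 1) {
      ops[k] <- "M"; lens[k] <- sample(10:300, 1)
    } else {
      ops[k] <- sample(c("I", "D"), 1); lens[k] <- sample(1:400, 1)
    }
  }
  paste0(lens, ops, collapse = "")
}

# Shared end-to-end fixture (study conditions), computed once per test run.
.fixture_env <- new.env(parent = emptyenv())

study_fixture <- function(seed = 1L) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_env[[key]])) {
    dir <- tempfile("study")
    cfg <- sim_config(rng_seed = seed)
    bundle <- simulate_bundle(dir, cfg)
    ref <- stats::setNames(bundle$reference, cfg$chrom)
    params <- validation_params(rng_seed = seed)
    res_true <- validate_all(bundle$truth, bundle$bam, ref, params)
    res_false <- validate_all(bundle$false_svs, bundle$bam, ref, params)
    .fixture_env[[key]] <- list(cfg = cfg, bundle = bundle, ref = ref,
                                params = params, res_true = res_true,
                                res_false = res_false)
  }
  .fixture_env[[key]]
}
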