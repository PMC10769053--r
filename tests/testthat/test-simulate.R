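small_cfg <- function(...) {
  defaults <- list(genome_length = 60000L, n_hom = 3L, n_het = 3L,
                   sv_length_range = c(200L, 500L),
                   read_length_mean = 8000L, read_length_sd = 800L,
                   depth = 12, rng_seed = 5L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("reference generation is deterministic with repeat accounting", {
  cfg <- sim_config(genome_length = 100000L, repeat_fraction = 0.3,
                    rng_seed = 2L)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$sequence, r2$sequence)
  expect_equal(nchar(r1$sequence), 100000L)
  rep_bp <- sum(r1$repeats$end - r1$repeats$start)
  expect_lte(abs(rep_bp - 30000L), cfg$repeat_unit_len)
  # no repeats requested -> no repeat rows
  r0 <- generate_reference(sim_config(genome_length = 20000L,
                                      repeat_fraction = 0, rng_seed = 2L))
  expect_equal(nrow(r0$repeats), 0L)
})

test_that("implanted SVs change haplotype lengths by construction", {
  ref <- random_dna_str(100000)
  cfg <- sim_config(genome_length = 100000L, rng_seed = 3L)
  mk_truth <- function(type, start, len, zyg, hap) {
    tr <- sv_table("chr1", start,
                   if (type == "INS") start + 1L else start + len,
                   type, len, id = "x")
    tr$zygosity <- zyg; tr$hap <- hap
    tr$ins_seq <- if (type == "INS") random_dna_str(len) else NA
    tr
  }
  # HOM DEL 500: both haplotypes shorten
  blocks <- longsv:::build_blocks(ref, mk_truth("DEL", 40000L, 500L,
                                                "HOM", 0L), 100000L)
  expect_equal(blocks$hap_end[nrow(blocks)], 99500L)
  # HET INS 300 on hap 1 only
  tr <- mk_truth("INS", 40000L, 300L, "HET", 1L)
  b1 <- longsv:::build_blocks(ref, tr, 100000L)
  expect_equal(b1$hap_end[nrow(b1)], 100300L)
  # INV: haplotype segment is the reverse complement of the reference
  tr_inv <- mk_truth("INV", 40000L, 600L, "HOM", 0L)
  b_inv <- longsv:::build_blocks(ref, tr_inv, 100000L)
  hap <- longsv:::hap_sequence(ref, b_inv)
  expect_equal(nchar(hap), 100000L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ref, 40001, 40600))))
  expect_equal(substr(hap, 40001, 40600), rc)
})

test_that("emitted SAM is valid: CIGARs consume the stored sequences", {
  cfg <- small_cfg(error_rate = 0.08)
  ref <- generate_reference(cfg)
  imp <- implant_svs(ref, cfg)
  recs <- simulate_alignments(ref, imp$haps, cfg)
  expect_gt(nrow(recs), 30)
  # independent consumption check: query-consuming ops vs sequence length
  for (i in seq_len(nrow(recs))) {
    qlen <- sum(as.integer(regmatches(recs$cigar[i],
              gregexpr("[0-9]+(?=[MIS=X])", recs$cigar[i],
                       perl = TRUE))[[1]]))
    expect_equal(qlen, nchar(recs$seq[i]), info = recs$qname[i])
  }
  # and it survives samtools-compatible conversion + indexing
  sam <- tempfile(fileext = ".sam")
  write_sam(recs, c(chr1 = cfg$genome_length), sam)
  bam <- sam_to_bam(sam)
  expect_true(file.exists(paste0(bam, ".bai")))
  parsed <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(length(parsed$qname), nrow(recs))
})

test_that("same seed gives byte-identical bundles", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- small_cfg()
  b1 <- simulate_bundle(d1, cfg)
  b2 <- simulate_bundle(d2, cfg)
  expect_identical(readLines(b1$fasta), readLines(b2$fasta))
  expect_identical(readLines(b1$sam), readLines(b2$sam))
  expect_identical(readLines(b1$truth_bed), readLines(b2$truth_bed))
  expect_identical(readLines(b1$false_bed), readLines(b2$false_bed))
})

test_that("empirical depth tracks the configured depth", {
  cfg <- small_cfg(depth = 25)
  b <- simulate_bundle(tempfile(), cfg)
  # central window away from contig-end sampling shadow and SV loci
  mid <- cfg$genome_length %/% 2L
  near_sv <- any(abs(b$truth$start - mid) < 2000)
  win <- if (near_sv) mid + 4000L else mid
  obs <- region_mean_coverage(b$bam, cfg$chrom, win - 500L, win + 500L)
  expect_lt(abs(obs - 25) / 25, 0.15)
})

test_that("large deletions are emitted as split alignments", {
  ref <- random_dna_str(60000)
  cfg <- sim_config(genome_length = 60000L, rng_seed = 9L,
                    del_split_min = 2500L)
  tr <- sv_table("chr1", 30000L, 35000L, "DEL", id = "bigdel")
  tr$zygosity <- "HOM"; tr$hap <- 0L; tr$ins_seq <- NA
  blocks <- longsv:::build_blocks(ref, tr, 60000L)
  bs <- c(substr(ref, 1, 30000), substr(ref, 35001, 60000))
  set.seed(1)
  rec <- longsv:::emit_read("t", 25000L, 10000L, "+", blocks, bs, cfg)
  expect_equal(nrow(rec), 2L)
  expect_equal(sort(bitwAnd(rec$flag, 2048L)), c(0L, 2048L))
  gap <- max(rec$pos) - 1L -
    (min(rec$pos) - 1L + GenomicAlignments::cigarWidthAlongReferenceSpace(
      rec$cigar[which.min(rec$pos)]))
  expect_equal(gap, 5000L)
})

test_that("fragmentation mode splits an indel op without changing its net", {
  ref <- random_dna_str(40000)
  cfg <- sim_config(genome_length = 40000L, rng_seed = 9L,
                    frag_mode = TRUE, frag_gap = 20L)
  tr <- sv_table("chr1", 20000L, 20500L, "DEL", id = "d")
  tr$zygosity <- "HOM"; tr$hap <- 0L; tr$ins_seq <- NA
  blocks <- longsv:::build_blocks(ref, tr, 40000L)
  bs <- c(substr(ref, 1, 20000), substr(ref, 20501, 40000))
  set.seed(1)
  rec <- longsv:::emit_read("t", 15000L, 10000L, "+", blocks, bs, cfg)
  expect_equal(nrow(rec), 1L)
  d_ops <- as.integer(regmatches(rec$cigar,
             gregexpr("[0-9]+(?=D)", rec$cigar, perl = TRUE))[[1]])
  expect_equal(length(d_ops), 2L)
  expect_equal(sum(d_ops), 500L)
  seg <- seg_row("t", rec$pos - 1L, NA, 0, NA, cigar = rec$cigar)
  expect_equal(net_indel_in_window(seg, 19000, 21500), -500L)
})

test_that("false SVs follow the multiplier rule with >= 50% length error", {
  truth <- sv_table("chr1", seq(10000L, 49000L, by = 1000L),
                    seq(10000L, 49000L, by = 1000L) + 500L, "DEL")
  f2 <- make_false_svs(truth[1, ], rng_seed = 1L, multipliers = 2)
  expect_equal(f2$length, 1000L)
  f01 <- make_false_svs(truth[1, ], rng_seed = 1L, multipliers = 0.1)
  expect_equal(f01$length, 50L)
  fs <- make_false_svs(truth, rng_seed = 4L)
  expect_equal(nrow(fs), nrow(truth))
  rel_err <- abs(fs$length - fs$true_length) / fs$true_length
  expect_true(all(rel_err >= 0.5))
  expect_true(all(fs$multiplier %in% c(0.1, 0.2, 0.3, 0.4, 2, 3, 4, 5)))
  # INV records are not used as false-SV sources
  tr_inv <- sv_table("chr1", 1000L, 2000L, "INV")
  expect_error(make_false_svs(tr_inv), "DEL/INS")
})
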