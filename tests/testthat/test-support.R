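test_that("distance_support matches its closed form and is minimal at 100", {
  expect_equal(distance_support(50), 50)
  expect_equal(distance_support(100), 40)
  expect_equal(distance_support(2000), 401)
  expect_equal(distance_support(500), 104)
  grid <- seq(50, 5000)
  expect_equal(grid[which.min(distance_support(grid))], 100)
  expect_error(distance_support(0), "positive")
})

test_that("net_indel_in_window sums only large ops inside the window", {
  seg <- seg_row("r", 1000, NA, 0, NA, cigar = "100M500D100M")
  expect_equal(net_indel_in_window(seg, 0, 5000), -500L)
  seg <- seg_row("r", 1000, NA, 0, NA, cigar = "50M200I30M300I20M")
  expect_equal(net_indel_in_window(seg, 0, 5000), 500L)
  seg <- seg_row("r", 1000, NA, 0, NA, cigar = "100M20D100M")
  expect_equal(net_indel_in_window(seg, 0, 5000), 0L)
  # ops outside the window are ignored
  seg <- seg_row("r", 1000, NA, 0, NA, cigar = "100M500D100M")
  expect_equal(net_indel_in_window(seg, 0, 1050), 0L)
})

test_that("net_indel_in_window agrees with a brute-force CIGAR walk", {
  set.seed(101)
  for (i in 1:300) {
    cig <- random_cigar()
    ref_start <- sample(0:2000, 1)
    ws <- sample(0:1500, 1)
    we <- ws + sample(100:2000, 1)
    seg <- seg_row("r", ref_start, NA, 0, NA, cigar = cig)
    expect_equal(net_indel_in_window(seg, ws, we),
                 oracle_net_indel(cig, ref_start, ws, we),
                 info = paste(cig, ref_start, ws, we))
  }
})

test_that("CIGAR-channel indel support applies sign and tolerance rules", {
  sv <- sv_table("chr1", 10000L, 10500L, "DEL")  # distance_support = 104
  mk <- function(cigar) seg_row("r", 9000, 12000, 0, 3000, cigar = cigar)
  expect_true(cigar_supports_indel(mk("1100M480D1900M"), sv)$supports)
  expect_false(cigar_supports_indel(mk("1100M380D1900M"), sv)$supports)
  ins <- cigar_supports_indel(mk("1100M500I1900M"), sv)
  expect_false(ins$supports)  # an insertion cannot support a deletion
  expect_equal(ins$implied_length, 500L)
  expect_equal(ins$channel, "cigar")
})

test_that("split_difference is read minus reference distance", {
  a <- seg_row("r", 1000, 2000, 0, 1000)
  b <- seg_row("r", 3500, 4000, 1500, 2000)
  expect_equal(split_difference(a, b), -1000L)   # deletion-like
  b2 <- seg_row("r", 2010, 2500, 1310, 1800)
  expect_equal(split_difference(a, b2), 300L)    # insertion-like
  b3 <- seg_row("r", 2100, 2600, 1150, 1650)
  expect_equal(split_difference(a, b3), 50L)     # below the signal gate
  expect_true(is.na(split_difference(a, seg_row("r", 3500, 4000, 1500,
                                                2000, strand = "-"))))
})

test_that("split-read indel support respects the 200 bp gate", {
  sv_del <- sv_table("chr1", 10000L, 11000L, "DEL")
  grp <- rbind(seg_row("r", 5000, 10000, 0, 5000),
               seg_row("r", 11000, 15000, 5000, 9000))
  expect_true(split_supports_indel(grp, sv_del)$supports)
  sv_ins <- sv_table("chr1", 10000L, 10001L, "INS", length = 290L)
  grp_ins <- rbind(seg_row("r", 5000, 10000, 0, 5000),
                   seg_row("r", 10000, 14000, 5300, 9300))
  expect_true(split_supports_indel(grp_ins, sv_ins)$supports)
  # |difference| below the gate is never a signal
  grp_small <- rbind(seg_row("r", 5000, 10000, 0, 5000),
                     seg_row("r", 10150, 14000, 5000, 8850))
  expect_false(split_supports_indel(grp_small, sv_del)$supports)
})

test_that("the split gate never supports for |difference| <= 200", {
  sv <- sv_table("chr1", 10000L, 10180L, "DEL")  # length 180 < gate
  set.seed(7)
  for (i in 1:50) {
    d <- sample(-200:200, 1)
    grp <- rbind(seg_row("r", 5000, 10000, 0, 5000),
                 seg_row("r", 10000 + max(0, -d) + 10, 14000,
                         5000 + max(0, d) + 10, 9000))
    ev <- split_supports_indel(grp, sv)
    expect_false(ev$supports, info = paste("diff", d))
  }
})

test_that("inversion noise counts are edit distances to both orientations", {
  set.seed(33)
  ref <- strsplit(random_dna_str(3000), "")[[1]]
  ref_str <- paste(ref, collapse = "")
  reference <- c(chr1 = ref_str)
  sv <- sv_table("chr1", 1000L, 2000L, "INV")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  inv_seg <- rc(substr(ref_str, 1001, 2000))
  # read carrying an exact inversion
  read_seq <- paste0(substr(ref_str, 501, 1000), inv_seg,
                     substr(ref_str, 2001, 2500))
  grp <- seg_row("r", 500, 2500, 0, 2000, cigar = "2000M", seq = read_seq)
  nc <- inv_noise_counts(grp, sv, reference)
  expect_equal(nc$noise2, 0L)
  expect_gt(nc$noise1, 300)
  expect_true(cigar_supports_inv(nc$noise1, nc$noise2, sv$length))
  # read identical to the forward reference
  fwd <- seg_row("r", 500, 2500, 0, 2000, cigar = "2000M",
                 seq = substr(ref_str, 501, 2500))
  nc2 <- inv_noise_counts(fwd, sv, reference)
  expect_equal(nc2$noise1, 0L)
  expect_false(cigar_supports_inv(nc2$noise1, nc2$noise2, sv$length))
  # five substitutions in the inverted copy -> noise2 == 5
  mut <- strsplit(inv_seg, "")[[1]]
  at <- c(100, 300, 500, 700, 900)
  mut[at] <- vapply(mut[at], function(b) setdiff(c("A", "C", "G", "T"),
                                                 b)[1], "")
  read_mut <- paste0(substr(ref_str, 501, 1000), paste(mut, collapse = ""),
                     substr(ref_str, 2001, 2500))
  nc3 <- inv_noise_counts(seg_row("r", 500, 2500, 0, 2000,
                                  cigar = "2000M", seq = read_mut),
                          sv, reference)
  expect_equal(nc3$noise2, 5L)
})

test_that("the noise criteria gate on both fractions", {
  expect_true(cigar_supports_inv(350, 100, 1000))
  expect_false(cigar_supports_inv(200, 100, 1000))
  expect_false(cigar_supports_inv(400, 250, 1000))
  # boundaries are inclusive as printed
  expect_true(cigar_supports_inv(300, 200, 1000))
})

test_that("three-segment inversion split geometry", {
  sv <- sv_table("chr1", 100000L, 105000L, "INV")  # tolerance 1000.4
  grp <- rbind(
    seg_row("r", 95000, 100000, 0, 5000, strand = "+"),
    seg_row("r", 100010, 104990, 5000, 9980, strand = "-"),
    seg_row("r", 104990, 110000, 9980, 14990, strand = "+"))
  ev <- split_supports_inv(grp, sv)
  expect_true(ev$supports)
  expect_equal(ev$implied_length, 4990L)
  expect_equal(ev$channel, "split")
  # same-strand triples carry no inversion signal
  grp_same <- grp; grp_same$strand <- "+"
  expect_false(split_supports_inv(grp_same, sv)$supports)
})

test_that("two-segment breakpoint geometry covers very large inversions", {
  sv <- sv_table("chr1", 100000L, 150000L, "INV")  # tolerance 10000.04
  left <- rbind(
    seg_row("r", 90000, 100000, 0, 10000, strand = "+"),
    seg_row("r", 140020, 150020, 10000, 20000, strand = "-"))
  ev <- split_supports_inv(left, sv)
  expect_true(ev$supports)
  expect_lte(abs(ev$implied_length - 50000L), 20L)
  right <- rbind(
    seg_row("r", 100010, 110000, 0, 9990, strand = "-"),
    seg_row("r", 150010, 160000, 9990, 19980, strand = "+"))
  expect_true(split_supports_inv(right, sv)$supports)
})

test_that("screening enforces MAPQ and double-flank spanning", {
  sv <- sv_table("chr1", 10000L, 10500L, "DEL")
  segs <- rbind(
    seg_row("lowq", 8000, 13000, 0, 5000, mapq = 19L),
    seg_row("short", 8000, 10700, 0, 2700),           # ends 200 bp past end
    seg_row("span", 8500, 12000, 0, 3500),
    seg_row("split", 8500, 10000, 0, 1500),
    seg_row("split", 10500, 12200, 1500, 3200))
  kept <- screen_reads(segs, sv)
  expect_setequal(unique(kept$read_id), c("span", "split"))
  # raising mapq_min or flank_len never adds reads
  for (i in 1:10) {
    p1 <- validation_params(mapq_min = sample(0:60, 1),
                            flank_len = sample(500:2000, 1))
    p2 <- validation_params(mapq_min = p1$mapq_min + 10L,
                            flank_len = p1$flank_len + 500L)
    n1 <- length(unique(screen_reads(segs, sv, p1)$read_id))
    n2 <- length(unique(screen_reads(segs, sv, p2)$read_id))
    expect_lte(n2, n1)
  }
})

test_that("support verdicts are invariant to the sequencing strand", {
  sv_del <- sv_table("chr1", 10000L, 11000L, "DEL")
  grp <- rbind(seg_row("r", 5000, 10000, 0, 5000),
               seg_row("r", 11000, 15000, 5000, 9000))
  flipped <- flip_group(grp, 9000L)
  expect_equal(split_supports_indel(grp, sv_del)$supports,
               split_supports_indel(flipped, sv_del)$supports)
  sv_inv <- sv_table("chr1", 100000L, 105000L, "INV")
  grp3 <- rbind(
    seg_row("r", 95000, 100000, 0, 5000, strand = "+"),
    seg_row("r", 100010, 104990, 5000, 9980, strand = "-"),
    seg_row("r", 104990, 110000, 9980, 14990, strand = "+"))
  f3 <- flip_group(grp3, 14990L)
  expect_equal(split_supports_inv(grp3, sv_inv)$supports,
               split_supports_inv(f3, sv_inv)$supports)
  expect_equal(split_supports_inv(grp3, sv_inv)$implied_length,
               split_supports_inv(f3, sv_inv)$implied_length)
})

test_that("the evidence dispatcher prefers CIGAR, then split", {
  sv <- sv_table("chr1", 10000L, 10100L, "DEL")
  one <- seg_row("r1", 8900, 12000, 0, 3000, cigar = "1100M100D1900M")
  ev1 <- evidence_for_read(one, sv)
  expect_true(ev1$supports)
  expect_equal(ev1$channel, "cigar")
  sv_big <- sv_table("chr1", 10000L, 15000L, "DEL")
  two <- rbind(seg_row("r5", 5000, 10000, 0, 5000, cigar = "5000M4000S"),
               seg_row("r5", 15000, 19000, 5000, 9000,
                       cigar = "5000S4000M"))
  ev2 <- evidence_for_read(two, sv_big)
  expect_true(ev2$supports)
  expect_equal(ev2$channel, "split")
  none <- seg_row("r0", 8900, 12000, 0, 3100, cigar = "3100M")
  ev0 <- evidence_for_read(none, sv)
  expect_false(ev0$supports)
  expect_equal(ev0$channel, "none")
})
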