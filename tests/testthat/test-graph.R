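# Junction collection/filtering, coverage contigs, candidate exon
# generation.

test_that("junctions are tallied per distinct endpoint pair", {
  bl <- rbind(
    ## three reads spanning the same (110,160) gap
    do.call(rbind, lapply(1:3, function(i)
      data.frame(read = i, contig = "chr1", lib_strand = "+",
                 start = c(100L, 160L), end = c(110L, 170L)))),
    ## one read with a one-off acceptor
    data.frame(read = 4L, contig = "chr1", lib_strand = "+",
               start = c(100L, 161L), end = c(110L, 171L)))
  j <- collect_junctions(mk_aln(bl))
  expect_equal(nrow(j), 2L)
  expect_equal(j$count[j$acceptor_start == 160L], 3L)
  expect_equal(j$count[j$acceptor_start == 161L], 1L)

  ## no spliced reads -> empty
  expect_equal(nrow(collect_junctions(mk_aln(
    data.frame(contig = "chr1", lib_strand = "+", start = 0L, end = 50L)))), 0L)

  ## sub-min_intron gaps are alignment artifacts, not junctions
  short_gap <- data.frame(read = 1L, contig = "chr1", lib_strand = "+",
                          start = c(100L, 115L), end = c(110L, 130L))
  expect_equal(nrow(collect_junctions(mk_aln(short_gap), min_intron = 20L)), 0L)
})

test_that("junction filters: support, intron-length cap, endpoint plausibility", {
  j <- data.frame(
    contig = "chr1", strand = "+",
    donor_end =      c(110L, 110L, 500L, 1000L, 2000L,    3000L),
    acceptor_start = c(160L, 162L, 560L, 1001000L, 2000001L + 1000000L, 3100L),
    count =          c(10L,  1L,   2L,   5L,       5L,     1L))
  f <- filter_junctions(j, min_junction_reads = 2L, max_intron = 1000000L,
                        endpoint_window = 5L)
  ## (110,162) shares donor 110 within window 5 of the dominant (110,160)
  expect_false(any(f$acceptor_start == 162L))
  expect_true(any(f$acceptor_start == 160L))
  ## support boundary is inclusive
  expect_true(any(f$donor_end == 500L))
  ## intron of exactly 1,000,000 nt is retained; 1,000,001 is removed
  expect_true(any(f$donor_end == 1000L))
  expect_false(any(f$donor_end == 2000L))
  ## below min support
  expect_false(any(f$donor_end == 3000L))
})

test_that("endpoint plausibility keeps independent junctions outside the window", {
  j <- data.frame(contig = "chr1", strand = "+",
                  donor_end = c(110L, 110L),
                  acceptor_start = c(160L, 200L), count = c(10L, 2L))
  f <- filter_junctions(j, min_junction_reads = 1L, endpoint_window = 10L)
  expect_equal(nrow(f), 2L)  # 40 nt apart: both plausible
})

test_that("coverage contigs bridge gaps up to max_fill_gap", {
  bl <- data.frame(contig = "chr1", lib_strand = "+",
                   start = c(0L, 60L), end = c(50L, 100L))
  one <- build_coverage_contigs(mk_aln(bl), max_fill_gap = 20L)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(0L, 100L))
  two <- build_coverage_contigs(mk_aln(bl), max_fill_gap = 5L)
  expect_equal(nrow(two), 2L)
  expect_equal(two$start, c(0L, 60L))
  ## single read -> its own footprint
  single <- build_coverage_contigs(mk_aln(
    data.frame(contig = "chr1", lib_strand = "+", start = 7L, end = 57L)))
  expect_equal(c(single$start, single$end), c(7L, 57L))
})

test_that("exon candidates are cut at junction points and never straddle introns", {
  bl <- rbind(tile_blocks(0L, 100L), tile_blocks(200L, 300L),
              tile_blocks(0L, 300L, n = 2L))  # two intron-spanning reads
  aln <- mk_aln(bl)
  contigs <- data.frame(contig = "chr1", strand = "+", start = 0L, end = 300L)
  j <- data.frame(contig = "chr1", strand = "+", donor_end = 100L,
                  acceptor_start = 200L, count = 5L)
  ex <- make_candidate_exons(contigs, j, aln, min_exon_support = 1,
                             short_single_exon_support = 1L)
  sig <- paste(ex$start, ex$end)
  expect_setequal(sig, c("0 100", "200 300"))
  expect_true(ex$right_jb[ex$end == 100L])
  expect_false(ex$left_jb[ex$start == 0L])

  ## with intron-retention emission the full-span variant appears, flagged
  ir <- make_candidate_exons(contigs, j, aln, min_exon_support = 1,
                             short_single_exon_support = 1L,
                             emit_retained_introns = TRUE)
  full <- ir[ir$start == 0L & ir$end == 300L, ]
  expect_equal(nrow(full), 1L)
  expect_true(full$retained_intron)
  expect_false(any(ir$retained_intron[ir$end <= 100L]))
})

test_that("a contig without junctions yields exactly itself as the one exon", {
  aln <- mk_aln(tile_blocks(1000L, 2400L))
  contigs <- build_coverage_contigs(aln)
  ex <- make_candidate_exons(contigs, data.frame(
    contig = character(), strand = character(), donor_end = integer(),
    acceptor_start = integer(), count = integer()), aln)
  expect_equal(nrow(ex), 1L)
  expect_equal(c(ex$start, ex$end), c(1000L, 2400L))
})

test_that("short single-exon candidates need elevated read support", {
  ## 900 nt junction-less candidate with 2 supporting reads
  aln2 <- mk_aln(tile_blocks(0L, 900L, n = 2L))
  contigs <- data.frame(contig = "chr1", strand = "+", start = 0L, end = 900L)
  no_j <- data.frame(contig = character(), strand = character(),
                     donor_end = integer(), acceptor_start = integer(),
                     count = integer())
  dropped <- make_candidate_exons(contigs, no_j, aln2,
                                  min_exon_support = 1,
                                  short_single_exon_len = 1000L,
                                  short_single_exon_support = 4L)
  expect_equal(nrow(dropped), 0L)
  ## same support is enough once the candidate is >= 1000 nt
  aln3 <- mk_aln(tile_blocks(0L, 1100L, n = 2L))
  contigs3 <- data.frame(contig = "chr1", strand = "+", start = 0L,
                         end = 1100L)
  kept <- make_candidate_exons(contigs3, no_j, aln3, min_exon_support = 1,
                               short_single_exon_len = 1000L,
                               short_single_exon_support = 4L)
  expect_equal(nrow(kept), 1L)
})

test_that("exon set size is monotone in the support thresholds", {
  fxd <- fx_multirole()
  sizes <- vapply(c(0.5, 1, 2, 4), function(ms)
    nrow(make_candidate_exons(fxd$contigs, fxd$jx, fxd$aln,
                              min_exon_support = ms)), integer(1))
  expect_true(all(diff(sizes) <= 0L))
  jx_sizes <- vapply(c(1L, 2L, 5L, 10L), function(mj) {
    jf <- filter_junctions(collect_junctions(fxd$aln),
                           min_junction_reads = mj)
    nrow(jf)
  }, integer(1))
  expect_true(all(diff(jx_sizes) <= 0L))
})

test_that("no emitted exon overlaps a retained intron; ends are covered", {
  fxd <- fx_multirole()
  ex <- fxd$exons
  j <- fxd$jx
  for (i in seq_len(nrow(ex))) {
    same <- j$contig == ex$contig[i] & j$strand == ex$strand[i]
    bad <- same & j$donor_end < ex$end[i] & j$acceptor_start > ex$start[i]
    expect_false(any(bad & !ex$retained_intron[i]))
  }
  ## depth > 0 at both terminal bases of every exon
  bl <- fxd$aln$blocks
  for (i in seq_len(nrow(ex))) {
    for (p in c(ex$start[i], ex$end[i] - 1L)) {
      expect_true(any(bl$contig == ex$contig[i] &
                      bl$lib_strand == ex$strand[i] &
                      bl$start <= p & bl$end > p))
    }
  }
})
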