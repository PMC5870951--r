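# Greedy chaining: endpoint scoring, exon selection, branching, and the
# stringency-modulated transcript filter.

mk_exons <- function(start, end, X, strand = "+") {
  data.frame(exon_id = sprintf("e%d", seq_along(start)), contig = "chr1",
             strand = strand, start = as.integer(start),
             end = as.integer(end), length = as.integer(end - start),
             n_reads = 1L, X = X, left_jb = FALSE, right_jb = FALSE,
             retained_intron = FALSE, stringsAsFactors = FALSE)
}

mk_jx <- function(donor, acceptor, count, strand = "+") {
  data.frame(contig = "chr1", strand = strand,
             donor_end = as.integer(donor),
             acceptor_start = as.integer(acceptor),
             count = as.integer(count), stringsAsFactors = FALSE)
}

test_that("endpoint scores normalize support and apply the distance weight", {
  sc <- endpoint_scores(c(8L, 2L), c(100, 100))
  expect_equal(sc$norm, c(0.8, 0.2))
  expect_equal(which.max(sc$score), 1L)

  expect_equal(endpoint_scores(5L, 1000)$norm, 1)   # single endpoint

  ## equal support: the distance weight decides (inverse favors proximal)
  tie <- endpoint_scores(c(5L, 5L), c(100, 5000), "inverse")
  expect_gt(tie$score[1], tie$score[2])
  lin <- endpoint_scores(c(5L, 5L), c(100, 5000), "linear")
  expect_gt(lin$score[2], lin$score[1])  # printed-formula mode is distal
  none <- endpoint_scores(c(5L, 5L), c(100, 5000), "none")
  expect_equal(none$score[1], none$score[2])
})

test_that("a linear three-exon gene assembles into exactly one transcript", {
  ex <- mk_exons(c(0, 200, 400), c(100, 300, 500), X = c(5, 4, 3))
  jx <- mk_jx(c(100, 300), c(200, 400), c(3, 3))
  tx <- assemble_transcripts(ex, jx)
  expect_equal(nrow(tx$transcripts), 1L)
  expect_equal(tx$transcripts$n_exons, 3L)
  expect_equal(tx$exons$start, c(0L, 200L, 400L))
  expect_equal(tx$transcripts$mean_x, 4)
})

test_that("the next exon at an endpoint is the X argmax, ties to the longer exon", {
  ex <- rbind(mk_exons(c(0, 200, 200), c(100, 300, 500), X = c(5, 1.2, 3)))
  jx <- mk_jx(100, 200, 4)
  tx <- assemble_transcripts(ex, jx)
  expect_equal(nrow(tx$transcripts), 1L)
  expect_equal(max(tx$exons$end), 500L)   # X = 3 beats 1.2

  tie <- rbind(mk_exons(c(0, 200, 200), c(100, 700, 400), X = c(5, 2, 2)))
  tx2 <- assemble_transcripts(tie, jx)
  expect_equal(max(tx2$exons$end), 700L)  # tie on X -> longer exon
})

test_that("branching emits minor isoforms only above the cutoff", {
  ## skipped-exon locus: 1->2->3 and 1->3 with support split 70/30
  ex <- mk_exons(c(0, 200, 400), c(100, 300, 500), X = c(5, 4, 3))
  jx <- rbind(mk_jx(100, 200, 7),   # into exon 2 (dominant)
              mk_jx(100, 400, 3),   # skip to exon 3
              mk_jx(300, 400, 7))
  cfg_lo <- maps_config(branch_cutoff = 0.2)
  both <- assemble_transcripts(ex, jx, cfg_lo)
  expect_equal(nrow(both$transcripts), 2L)
  expect_setequal(both$transcripts$n_exons, c(3L, 2L))

  cfg_hi <- maps_config(branch_cutoff = 0.5)
  one <- assemble_transcripts(ex, jx, cfg_hi)
  expect_equal(nrow(one$transcripts), 1L)
  expect_equal(one$transcripts$n_exons, 3L)  # only the 70% path
})

test_that("max_per_seed caps the chains from one seed", {
  ## two-level branching: 2 x 2 = 4 possible chains
  ex <- mk_exons(c(0, 200, 300, 600, 700), c(100, 250, 350, 650, 750),
                 X = c(5, 4, 4, 3, 3))
  jx <- rbind(mk_jx(100, c(200, 300), c(5, 5)),
              mk_jx(250, c(600, 700), c(5, 5)),
              mk_jx(350, c(600, 700), c(5, 5)))
  all4 <- assemble_transcripts(ex, jx, maps_config(branch_cutoff = 0,
                                                   max_per_seed = 16L))
  expect_equal(nrow(all4$transcripts), 4L)
  capped <- assemble_transcripts(ex, jx, maps_config(branch_cutoff = 0,
                                                     max_per_seed = 2L))
  expect_equal(nrow(capped$transcripts), 2L)
  greedy <- assemble_transcripts(ex, jx, maps_config(max_per_seed = 1L))
  expect_equal(nrow(greedy$transcripts), 1L)
})

test_that("assembly is deterministic and respects junction connectivity", {
  fxd <- fx_multirole()
  a1 <- assemble_transcripts(fxd$exons, fxd$jx)
  a2 <- assemble_transcripts(fxd$exons, fxd$jx)
  expect_identical(a1, a2)
  ## every consecutive exon pair in every transcript is a retained junction
  for (tid in a1$transcripts$transcript_id) {
    e <- a1$exons[a1$exons$transcript_id == tid, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2L) next
    for (k in seq_len(nrow(e) - 1L)) {
      expect_true(any(fxd$jx$contig == e$contig[1] &
                      fxd$jx$strand == e$strand[1] &
                      fxd$jx$donor_end == e$end[k] &
                      fxd$jx$acceptor_start == e$start[k + 1L]))
      expect_lte(e$start[k + 1L] - e$end[k], 1000000L)
    }
  }
})

test_that("stringency 0 keeps everything; stringency 1 can empty the set", {
  ex <- mk_exons(c(0, 200), c(100, 300), X = c(5, 3))
  jx <- mk_jx(100, 200, 3)
  tx <- assemble_transcripts(ex, jx)
  s0 <- filter_transcripts(tx, 0, expression_threshold_base = 100)
  expect_equal(nrow(s0$transcripts), nrow(tx$transcripts))
  s1 <- filter_transcripts(tx, 1, expression_threshold_base = 100)
  expect_equal(nrow(s1$transcripts), 0L)
})

test_that("similar transcripts need proportionally strong expression", {
  ## identical junction chains, expressions 10 and 2, stringency 0.3:
  ## 2 < 10 * 0.3 so the weaker one is dropped
  ex <- data.frame(
    transcript_id = rep(c("A", "B"), each = 2),
    contig = "chr1", strand = "+",
    start = c(0L, 200L, 10L, 200L), end = c(100L, 300L, 100L, 280L),
    x = c(10, 10, 2, 2))
  tx <- maps_transcripts(ex)
  out <- filter_transcripts(tx, 0.3, expression_threshold_base = 0)
  expect_equal(out$transcripts$transcript_id, "A")
  ## at stringency 0.1 the weaker one survives (2 >= 10 * 0.1)
  out2 <- filter_transcripts(tx, 0.1, expression_threshold_base = 0)
  expect_setequal(out2$transcripts$transcript_id, c("A", "B"))
  ## single-exon transcripts have no internal structure: never "similar"
  ex3 <- rbind(ex, data.frame(transcript_id = "C", contig = "chr1",
                              strand = "+", start = 40L, end = 90L, x = 1))
  out3 <- filter_transcripts(maps_transcripts(ex3), 0.3,
                             expression_threshold_base = 0)
  expect_true("C" %in% out3$transcripts$transcript_id)
})

test_that("transcriptome size shrinks monotonically with stringency", {
  fxd <- fx_multirole()
  base <- median(fxd$exons$X)
  sizes <- t(vapply(seq(0, 1, by = 0.1), function(s) {
    f <- filter_transcripts(fxd$asm, s, expression_threshold_base = base)
    c(n = nrow(f$transcripts),
      nt = sum(f$exons$end - f$exons$start))
  }, c(n = 0, nt = 0)))
  expect_true(all(diff(sizes[, "n"]) <= 0))
  expect_true(all(diff(sizes[, "nt"]) <= 0))
  expect_equal(sizes[1, "n"], nrow(fxd$asm$transcripts),
               ignore_attr = TRUE)
})
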