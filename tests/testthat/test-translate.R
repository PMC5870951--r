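# Transcript sequence construction, three-frame ORF extraction, and
# genomic ORF extension.

one_tx <- function(start, end, strand = "+", contig = "chr1", id = "t1") {
  maps_transcripts(data.frame(transcript_id = id, contig = contig,
                              strand = strand, start = as.integer(start),
                              end = as.integer(end)))
}

test_that("transcript sequences concatenate exons and honor strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGTTCCCTT"))
  tx <- one_tx(c(0, 7), c(3, 10))
  expect_equal(transcript_sequence(tx, "t1", genome), "ATGCTT")
  txm <- one_tx(c(0, 7), c(3, 10), strand = "-")
  expect_equal(transcript_sequence(txm, "t1", genome), "AAGCAT")

  ## a called SNP flows into the transcript sequence
  bl <- data.frame(contig = "chr1", lib_strand = "+", start = 1L, end = 2L,
                   bases = rep("A", 8))
  cons <- build_consensus(mk_aln(bl))
  expect_equal(transcript_sequence(tx, "t1", genome, cons), "AAGCTT")
})

test_that("three-frame translation finds maximal stop-free stretches", {
  orfs <- three_frame_orfs("ATGGCC")
  expect_equal(orfs$aa[orfs$frame == 0], "MA")
  expect_equal(orfs$aa[orfs$frame == 1], "W")
  expect_equal(orfs$aa[orfs$frame == 2], "G")

  ## stops split stretches; empty stretches are not emitted
  expect_equal(nrow(three_frame_orfs("TAATAA")[
    three_frame_orfs("TAATAA")$frame == 0, ]), 0L)
  f0 <- three_frame_orfs("ATGTGAAAA")
  f0 <- f0[f0$frame == 0, ]
  expect_equal(f0$aa, c("M", "K"))
  expect_equal(f0$nt_start, c(0L, 6L))
  expect_false(f0$open5[2])
  expect_true(f0$open3[2])
  expect_true(f0$open5[1])

  ## codons containing N translate to X, which is not a stop
  nx <- three_frame_orfs("ATGNNNAAA")
  expect_equal(nx$aa[nx$frame == 0], "MXK")
})

test_that("three-frame extraction agrees with an independent translation oracle", {
  set.seed(500)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:90, 1),
                      replace = TRUE), collapse = "")
    got <- three_frame_orfs(s)
    for (f in 0:2) {
      n_cod <- (nchar(s) - f) %/% 3
      if (n_cod == 0) next
      aa <- vapply(seq_len(n_cod), function(k)
        seqinr::translate(strsplit(substr(s, f + 3 * k - 2, f + 3 * k),
                                   "")[[1]]), character(1))
      runs <- rle(aa != "*")
      starts <- cumsum(c(1, runs$lengths))[seq_along(runs$lengths)]
      want <- data.frame(
        aa = vapply(which(runs$values), function(j)
          paste(aa[starts[j]:(starts[j] + runs$lengths[j] - 1)],
                collapse = ""), character(1)))
      gotf <- got[got$frame == f, ]
      expect_equal(gotf$aa, want$aa)
    }
  }
})

test_that("3' extension walks the genome to the nearest in-frame stop", {
  ## transcript = ATG GCC, genome continues TTT TAA
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 9), "TAG", "ATGGCC", "TTTTAA", strrep("C", 12))))
  tx <- one_tx(12, 18)
  orfs <- build_orf_db(tx, genome, min_orf_aa = 1L)
  hit <- orfs[orfs$frame == 0 & orfs$aa == "MAF", ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$extended_3p)
  expect_equal(hit$ext3, 3L)
  expect_equal(hit$stop_codon, "TAA")
  expect_false(hit$trunc3)
  expect_equal(hit$spans[[1]], rbind(c(12, 21)), ignore_attr = TRUE)
})

test_that("a stop immediately flanking the transcript gives zero-length extension", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 9), "TAG", "ATGGCC", "TAA", strrep("C", 12))))
  tx <- one_tx(12, 18)
  orfs <- build_orf_db(tx, genome, min_orf_aa = 1L)
  hit <- orfs[orfs$frame == 0 & orfs$aa == "MA", ]
  expect_false(hit$extended_3p)
  expect_equal(hit$ext3, 0L)
  expect_equal(hit$stop_codon, "TAA")
})

test_that("5' extension recovers an upstream in-frame ATG beyond the transcript", {
  ## genome upstream of the transcript: TAG ATG AAA | transcript CCC TGA
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("G", 9), "TAGATGAAA", "CCCTGA", strrep("G", 9))))
  tx <- one_tx(18, 24)
  orfs <- build_orf_db(tx, genome, min_orf_aa = 1L)
  hit <- orfs[orfs$frame == 0 & orfs$extended_5p, ]
  expect_equal(hit$aa, "MKP")
  expect_equal(hit$ext5, 6L)  # stops one codon after the upstream TAG
  expect_false(hit$trunc5)
  st <- assign_start(hit)
  expect_equal(st$start_class, "AUG")
  expect_equal(st$start_codon_index, 0L)
})

test_that("extension on the minus strand mirrors the plus strand", {
  ## minus-strand transcript CAT GCC (revcomp GGCATG at 12..18),
  ## upstream genomic continuation carries TTT TAA in transcript frame
  plus_tx_seq <- "ATGGCC"; cont <- "TTTTAA"
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 12),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste0(plus_tx_seq, cont)))),
    "CTA", strrep("C", 9))))
  tx <- one_tx(18, 24, strand = "-")
  orfs <- build_orf_db(tx, genome, min_orf_aa = 1L)
  hit <- orfs[orfs$frame == 0 & orfs$aa == "MAF", ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$extended_3p)
  expect_equal(hit$spans[[1]], rbind(c(15, 24)), ignore_attr = TRUE)
})

test_that("the contig edge truncates extension and sets the boundary flag", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGGCCGGG"))
  tx <- one_tx(0, 9)
  orfs <- build_orf_db(tx, genome, min_orf_aa = 1L)
  f0 <- orfs[orfs$frame == 0, ]
  expect_true(f0$trunc3)
  expect_true(is.na(f0$stop_codon))
  expect_true(f0$trunc5)
})

test_that("every ORF record re-translates from its own genomic spans", {
  fxd <- fx_multirole()
  orfs <- fxd$orfs
  take <- seq_len(nrow(orfs))
  if (length(take) > 80) { set.seed(1); take <- sort(sample(take, 80)) }
  for (i in take) {
    sp <- orfs$spans[[i]]
    pieces <- vapply(seq_len(nrow(sp)), function(k) {
      s <- apply_consensus(fxd$sim$genome, fxd$cons, orfs$contig[i],
                           sp[k, 1], sp[k, 2])$seq
      if (orfs$strand[i] == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      else s
    }, character(1))
    nt <- paste(pieces, collapse = "")
    expect_identical(nt, orfs$nt[i])
    aa <- vapply(seq_len(nchar(nt) %/% 3), function(k)
      seqinr::translate(strsplit(substr(nt, 3 * k - 2, 3 * k), "")[[1]]),
      character(1))
    expect_identical(paste(aa, collapse = ""), orfs$aa[i])
  }
})

test_that("consensus and genome-only databases differ exactly at SNP peptides", {
  fxd <- fx_multirole()
  orfs_cons <- fxd$orfs
  orfs_ref <- build_orf_db(fxd$tx, fxd$sim$genome, cons = NULL)
  ## records with snp_count > 0 are exactly those whose aa changed
  changed <- orfs_cons[orfs_cons$snp_count > 0L, ]
  expect_gt(nrow(changed), 0L)
  expect_true(all(changed$aa != changed$aa_ref))
  same <- orfs_cons[orfs_cons$snp_count == 0L, ]
  expect_true(all(same$aa == same$aa_ref))
  ## the consensus-free database never contains a SNP-altered peptide
  expect_false(any(changed$aa %in% orfs_ref$aa))
})
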