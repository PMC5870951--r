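# Peptide filtering, mapping, start-codon assignment, smORF classification
# and SNP-mutant flagging.

test_that("annotated peptides are removed, with I/L equivalence", {
  prot <- Biostrings::AAStringSet(c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"))
  expect_equal(filter_annotated(c("TAYIAKQR"), prot), character(0))
  expect_equal(filter_annotated(c("TAYIAKQX"), prot), "TAYIAKQX")
  ## I<->L swapped peptide is indistinguishable by MS: removed
  expect_equal(filter_annotated(c("TAYLAKQR"), prot), character(0))
  expect_warning(out <- filter_annotated("PEP", Biostrings::AAStringSet()),
                 "empty")
  expect_equal(out, "PEP")
})

test_that("peptides map to every containing ORF with offsets", {
  db <- rbind(mk_orf(c("ATG", "AAA", "CCC", "GGG"), id = "o1"),
              mk_orf(c("TTT", "ATG", "AAA", "CCC"), id = "o2"),
              mk_orf(c("TTT", "TTC", "TTA", "CTG"), id = "o3"))
  hits <- map_peptide("MKP", db)
  expect_equal(hits$orf_id, c("o1", "o2"))
  expect_equal(hits$aa_offset, c(1L, 2L))
  expect_equal(nrow(map_peptide("WWW", db)), 0L)
  ## I/L equivalence in mapping
  expect_equal(map_peptide("FFI", db)$orf_id, "o3")
})

test_that("start assignment prefers ATG, then near-cognate in Kozak context", {
  ## rule 1: in-frame ATG
  aug <- assign_start(mk_orf(c("AAA", "ATG", "GCC", "AAA")))
  expect_equal(aug$start_class, "AUG")
  expect_equal(aug$start_codon_index, 1L)
  expect_equal(aug$orf_length_codons, 3L)

  ## rule 2: no ATG; CTG with A at -3 (last codon of context irrelevant)
  nc <- assign_start(mk_orf(c("CTG", "GCC", "AAA"), upstream_ctx = "ACC"))
  expect_equal(nc$start_class, "near-cognate-Kozak")
  expect_equal(nc$start_codon, "CTG")

  ## -3 pyrimidine and +4 not G: context fails, falls through
  bad_ctx <- assign_start(mk_orf(c("CTG", "ACC", "AAA"),
                                 upstream_ctx = "TCC"))
  expect_equal(bad_ctx$start_class, "stop-bounded")

  ## +4 G alone is enough in "either" mode but not with kozak_mode "both"
  p4 <- mk_orf(c("CTG", "GCC", "AAA"), upstream_ctx = "TCC")
  expect_equal(assign_start(p4)$start_class, "near-cognate-Kozak")
  expect_equal(assign_start(p4, kozak_mode = "both")$start_class,
               "stop-bounded")

  ## near-cognate context read across the previous codon inside the ORF
  mid <- assign_start(mk_orf(c("CCA", "ACG", "GCC", "AAA"),
                             upstream_ctx = "TTT"))
  expect_equal(mid$start_class, "near-cognate-Kozak")
  expect_equal(mid$start_codon, "ACG")
  expect_equal(mid$start_codon_index, 1L)
})

test_that("the 150-codon rule separates smORFs from longer ORFs", {
  safe <- mapsr:::.SAFE_CODONS[1]
  smorf <- assign_start(mk_orf(rep(safe, 149)))
  expect_equal(smorf$start_class, "stop-bounded")
  expect_true(smorf$is_smorf)
  expect_equal(smorf$orf_length_codons, 149L)
  long <- assign_start(mk_orf(rep(safe, 151)))
  expect_false(long$is_smorf)
  ## boundary: exactly 150 codons is not a smORF ("less than 150")
  expect_false(assign_start(mk_orf(rep(safe, 150)))$is_smorf)
  ## with an assigned start, the length from the start codon decides
  aug <- assign_start(mk_orf(c(rep(safe, 10), "ATG", rep(safe, 100))))
  expect_true(aug$is_smorf)
  expect_equal(aug$orf_length_codons, 101L)
})

test_that("start assignment is invariant to the peptide chosen within an ORF", {
  orf <- mk_orf(c("AAA", "ATG", "GCC", "AAA", "CCC", "GGG"))
  s1 <- assign_start(orf, peptide = "KPG")
  s2 <- assign_start(orf, peptide = "MA")
  expect_equal(s1$start_codon_index, s2$start_codon_index)
  expect_equal(s1$start_class, s2$start_class)
  ## but an ATG downstream of the peptide cannot be the start
  s3 <- assign_start(mk_orf(c("AAA", "CCC", "ATG", "GGG")), peptide = "KP")
  expect_equal(s3$start_class, "stop-bounded")
  expect_error(assign_start(orf, peptide = "WWW"), "not found")
})

test_that("SNP-mutant peptides are flagged via the reference translation", {
  orf <- mk_orf(c("ATG", "AAA", "CCC", "GGG"))
  orf$aa_ref <- "MKTG"  # reference had T where consensus has P
  prot <- Biostrings::AAStringSet(c(known = "AAAMKTGAAA"))
  expect_true(flag_snp_mutant("MKPG", orf, 1L, prot))
  ## mismatch not at a SNP-altered residue: ref version not in proteome
  expect_false(flag_snp_mutant("MKPG", orf, 1L,
                               Biostrings::AAStringSet(c(x = "WWWW"))))
  ## zero-mismatch peptides are not mutants
  orf2 <- mk_orf(c("ATG", "AAA"))
  expect_false(flag_snp_mutant("MK", orf2, 1L, prot))
})

test_that("the peptide report classifies annotated, mutant, novel and unmappable", {
  fxd <- fx_multirole()
  rep <- annotate_peptides(fxd$sim$peptides$peptide, fxd$orfs,
                           proteome = fxd$sim$ref_proteome)
  truth <- fxd$sim$peptides
  m <- merge(rep, truth, by = "peptide")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$status[m$origin == "annotated"] == "annotated"))
  expect_true(all(m$status[m$origin == "snp_mutant"] == "snp_mutant"))
  sm <- m[m$origin == "smorf", ]
  expect_true(all(sm$status == "novel"))
  expect_true(all(sm$is_smorf))
  expect_equal(sm$start_class, sm$expected_class)
})
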