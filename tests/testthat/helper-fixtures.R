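# Shared fixtures, memoized so each simulation is built once per test run.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# error-free multi-role simulation exercising every planted feature
fx_multirole <- function() fx("multirole", function() {
  cfg <- sim_config(seed = 7, n_genes = 14, error_rate = 0, n_snps = 4,
                    n_annotated_genes = 4, n_snp_mutant_genes = 2,
                    smorf_classes = c("AUG", "near-cognate", "stop-bounded"),
                    n_truncated_3p = 1, n_truncated_5p = 1,
                    frac_antisense = 0.25, n_multimapper_reads = 8)
  sim <- simulate_transcriptome(cfg)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(sim, sam)
  aln <- read_alignments(sam, sim$genome)
  cons <- build_consensus(aln)
  jx <- filter_junctions(collect_junctions(aln))
  contigs <- build_coverage_contigs(aln)
  exons <- make_candidate_exons(contigs, jx, aln)
  asm <- assemble_transcripts(exons, jx)
  tx <- filter_transcripts(asm, 0.3)
  orfs <- build_orf_db(tx, sim$genome, cons)
  list(cfg = cfg, sim = sim, sam = sam, aln = aln, cons = cons, jx = jx,
       contigs = contigs, exons = exons, asm = asm, tx = tx, orfs = orfs)
})

# construct a maps_alignments object directly from a block table
mk_aln <- function(blocks) {
  blocks <- data.table::as.data.table(blocks)
  if (is.null(blocks$read)) blocks$read <- seq_len(nrow(blocks))
  if (is.null(blocks$read_id)) blocks$read_id <- sprintf("r%d", blocks$read)
  if (is.null(blocks$contig)) blocks$contig <- "chr1"
  if (is.null(blocks$lib_strand)) blocks$lib_strand <- "+"
  if (is.null(blocks$bases))
    blocks$bases <- strrep("A", blocks$end - blocks$start)
  data.table::setkey(blocks, read)
  reads <- unique(blocks[, c("read", "read_id", "contig", "lib_strand")])
  reads$n_hits <- 1L
  structure(list(blocks = blocks, reads = reads,
                 n_alignments = nrow(reads), n_multimappers = 0L,
                 strand_mode = "firststrand"),
            class = "maps_alignments")
}

# n reads tiling [start, end) on one strand, enough for support thresholds
tile_blocks <- function(start, end, n = 6L, contig = "chr1", strand = "+") {
  data.frame(contig = contig, lib_strand = strand,
             start = rep(start, n), end = rep(end, n))
}

# random transcript sets for round-trip properties
random_transcripts <- function(n_tx = 5L) {
  rows <- lapply(seq_len(n_tx), function(i) {
    n_ex <- sample(1:5, 1)
    len <- sample(50:300, n_ex, replace = TRUE)
    gap <- sample(50:500, n_ex, replace = TRUE)
    start <- cumsum(gap) + cumsum(c(0L, len[-n_ex]))
    data.frame(transcript_id = sprintf("t%02d", i),
               contig = sample(c("chr1", "chr2"), 1),
               strand = sample(c("+", "-"), 1),
               start = start, end = start + len)
  })
  maps_transcripts(do.call(rbind, rows))
}

# build a minimal ORF record from codon strings
mk_orf <- function(codons, upstream_ctx = "TAA", stop_codon = "TGA",
                   aa_ref = NULL, id = "orf1") {
  nt <- paste(codons, collapse = "")
  aa <- mapsr:::.translate_str(nt)
  data.frame(orf_id = id, transcript_id = "t1", contig = "chr1",
             strand = "+", frame = 0L, aa = aa,
             aa_ref = if (is.null(aa_ref)) aa else aa_ref, nt = nt,
             upstream_ctx = upstream_ctx, stop_codon = stop_codon,
             stringsAsFactors = FALSE)
}

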