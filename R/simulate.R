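## Closed-loop fixture generator: a toy genome with designed genes, planted
## SNPs and small ORFs, and error-bearing spliced stranded reads in SAM --
## the test surface for every other stage.

.SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        paste0), c("A", "C", "G", "T"), paste0)),
  .STOPS)
## codons that are neither stop, ATG, nor near-cognate: a body built from
## these can contain no in-frame start candidate at all
.SAFE_CODONS <- setdiff(.SENSE_CODONS, c("ATG", .NEAR_COGNATE))

#' Simulation configuration
#'
#' Defaults describe a small but realistic stranded RNA-Seq experiment:
#' compact multi-exon genes, log-normally distributed expression with a
#' floor so every transcript is assemblable, and an Illumina-like error
#' rate. The seed fixes every downstream byte.
#'
#' @param seed integer random seed.
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer range; extra isoforms skip one internal
#'   exon.
#' @param exons_per_gene,exon_len,intron_len,intergenic integer ranges (nt).
#' @param read_len read length in nt (default 76).
#' @param coverage_target median transcript coverage (default 30x).
#' @param coverage_min coverage floor (default 10x).
#' @param expr_sdlog sd(log) of the log-normal expression draw
#'   (default 0.8).
#' @param error_rate per-base substitution error rate (default 0.002).
#' @param n_snps SNPs planted in exons of ordinary genes (reads carry the
#'   alternate base; the genome FASTA keeps the reference).
#' @param n_annotated_genes genes given a designed CDS whose (reference)
#'   protein goes into the reference proteome.
#' @param n_snp_mutant_genes how many annotated genes additionally carry a
#'   nonsynonymous SNP (must be <= n_annotated_genes).
#' @param smorf_classes character vector drawn from \code{"AUG"},
#'   \code{"near-cognate"}, \code{"stop-bounded"}; one novel smORF gene is
#'   planted per entry.
#' @param n_truncated_3p,n_truncated_5p planted ORFs whose transcript is
#'   cut mid-ORF at the 3' / 5' end (the genomic flank carries the
#'   remainder, for testing ORF extension).
#' @param frac_antisense fraction of ordinary genes that also get an
#'   antisense transcript.
#' @param n_multimapper_reads reads emitted twice with NH=2.
#' @return list of class \code{maps_sim_config}.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L,
                       isoforms_per_gene = c(1L, 3L),
                       exons_per_gene = c(1L, 6L),
                       exon_len = c(120L, 400L),
                       intron_len = c(80L, 800L),
                       intergenic = c(500L, 2000L),
                       read_len = 76L, coverage_target = 30,
                       coverage_min = 10, expr_sdlog = 0.8,
                       error_rate = 0.002, n_snps = 0L,
                       n_annotated_genes = 0L, n_snp_mutant_genes = 0L,
                       smorf_classes = character(0),
                       n_truncated_3p = 0L, n_truncated_5p = 0L,
                       frac_antisense = 0, n_multimapper_reads = 0L) {
  stopifnot(n_snp_mutant_genes <= n_annotated_genes,
            all(smorf_classes %in% c("AUG", "near-cognate", "stop-bounded")))
  cfg <- as.list(environment())
  class(cfg) <- "maps_sim_config"
  cfg
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
.rint <- function(rng) if (rng[1L] >= rng[2L]) rng[1L] else
  sample(seq.int(rng[1L], rng[2L]), 1L)

## genomic position of transcript position t (0-based), single set of exons
.tx_pos_to_genome <- function(exons, strand, t) {
  sp <- .tx_interval_spans(exons, strand, t, t + 1L)
  if (strand == "+") sp[1L, 1L] else sp[1L, 2L] - 1L
}

#' Simulate a genome, transcript set and truth tables
#'
#' Generates a single-contig genome with non-overlapping genes. Ordinary
#' genes carry random sequence; designated genes get a designed spliced
#' transcript sequence written back into their exons: annotated CDS genes
#' (reference proteins), SNP mutants of those, novel smORFs with a chosen
#' start-codon class, and ORFs truncated by the transcript boundary whose
#' continuation lives in the genomic flank. Every planted item is recorded
#' in a truth table, and a peptide is drawn from every planted protein so
#' the annotation stage can be exercised end to end.
#'
#' @param config a [sim_config()].
#' @return list of class \code{maps_sim}: \code{genome} (reference),
#'   \code{sample_genome} (with planted SNP alternates),
#'   \code{transcripts} (truth \code{maps_transcripts}),
#'   \code{expression} (per-transcript coverage), \code{snps},
#'   \code{smorfs}, \code{peptides} truth tables, \code{ref_proteome},
#'   and the config.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  set.seed(config$seed)
  n_special <- config$n_annotated_genes + length(config$smorf_classes) +
    config$n_truncated_3p + config$n_truncated_5p
  if (config$n_genes < n_special)
    stop("n_genes (", config$n_genes, ") smaller than the ", n_special,
         " designed genes requested; increase n_genes")
  roles <- c(rep("annotated", config$n_annotated_genes),
             config$smorf_classes,
             rep("trunc3", config$n_truncated_3p),
             rep("trunc5", config$n_truncated_5p),
             rep("plain", config$n_genes - n_special))
  roles[seq_len(config$n_annotated_genes)[
    seq_len(config$n_snp_mutant_genes)]] <- "snp_mutant"

  ## gene structures
  genes <- vector("list", config$n_genes)
  cursor <- .rint(config$intergenic)
  for (i in seq_len(config$n_genes)) {
    role <- roles[i]
    n_ex <- if (role %in% c("trunc3", "trunc5")) 1L else
      .rint(config$exons_per_gene)
    elen <- vapply(seq_len(n_ex), function(j) .rint(config$exon_len),
                   integer(1))
    ## designed genes need room for their planted CDS/smORF
    if (!role %in% c("plain", "trunc3", "trunc5") && sum(elen) < 520L)
      elen[n_ex] <- elen[n_ex] + 520L - sum(elen)
    ilen <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(j) .rint(config$intron_len),
             integer(1)) else integer(0)
    starts <- cursor + cumsum(c(0L, elen[-n_ex] + ilen))
    ends <- starts + elen
    genes[[i]] <- list(role = role, strand = sample(c("+", "-"), 1L),
                       starts = starts, ends = ends)
    cursor <- ends[n_ex] + .rint(config$intergenic)
  }
  glen <- cursor + .rint(config$intergenic)
  g <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

  write_back <- function(chars, exons, strand, T) {
    stopifnot(nchar(T) == sum(exons$end - exons$start))
    Tg <- if (strand == "-") .revcomp(T) else T
    off <- 0L
    for (k in seq_len(nrow(exons))) {
      w <- exons$end[k] - exons$start[k]
      chars[(exons$start[k] + 1L):exons$end[k]] <-
        strsplit(substr(Tg, off + 1L, off + w), "")[[1L]]
      off <- off + w
    }
    chars
  }

  smorfs <- list(); snps <- list(); peptides <- list()
  proteins <- character(0)
  tx_rows <- list(); expr <- list()
  tx_n <- 0L

  draw_peptide <- function(aa, center = NULL, width = 11L) {
    n <- nchar(aa)
    if (is.null(center)) center <- (n + 1L) %/% 2L
    s <- max(1L, min(center - width %/% 2L, n - width + 1L))
    substr(aa, s, min(n, s + width - 1L))
  }

  for (i in seq_len(config$n_genes)) {
    gn <- genes[[i]]
    exons <- data.frame(contig = "chr1", strand = gn$strand,
                        start = gn$starts, end = gn$ends)
    L <- sum(exons$end - exons$start)
    gene_id <- sprintf("g%03d", i)
    role <- gn$role

    if (role %in% c("annotated", "snp_mutant")) {
      utr5 <- 30L
      n_cod <- min((L - utr5 - 30L - 6L) %/% 3L, .rint(c(60L, 150L)))
      body <- paste(sample(.SENSE_CODONS, n_cod, replace = TRUE),
                    collapse = "")
      cds <- paste0("ATG", body, "TGA")
      T <- paste0(.rand_dna(utr5), cds,
                  .rand_dna(L - utr5 - nchar(cds)))
      g <- write_back(g, exons, gn$strand, T)
      aa <- .translate_str(paste0("ATG", body))
      proteins[gene_id] <- aa
      if (role == "snp_mutant") {
        ## nonsynonymous SNP in the middle of the CDS; avoid stop gains
        ## and I<->L swaps (isobaric, invisible to peptide matching)
        repeat {
          ci <- .rint(c(10L, n_cod - 10L))      # codon within body
          cod <- substr(body, 3L * ci - 2L, 3L * ci)
          bpos <- .rint(c(1L, 2L))
          alt_b <- sample(setdiff(c("A", "C", "G", "T"),
                                  substr(cod, bpos, bpos)), 1L)
          new_cod <- cod
          substr(new_cod, bpos, bpos) <- alt_b
          old_aa <- .translate_str(cod); new_aa <- .translate_str(new_cod)
          if (new_cod %in% .STOPS || new_aa == old_aa ||
              .il(new_aa) == .il(old_aa)) next
          break
        }
        t_pos <- utr5 + 3L + 3L * (ci - 1L) + (bpos - 1L)  # transcript nt
        gpos <- .tx_pos_to_genome(exons, gn$strand, t_pos)
        ref_b <- g[gpos + 1L]
        alt_g <- if (gn$strand == "-") .revcomp(alt_b) else alt_b
        snps[[length(snps) + 1L]] <- data.frame(
          contig = "chr1", pos = gpos, ref = ref_b, alt = alt_g,
          gene = gene_id, stringsAsFactors = FALSE)
        mut_aa <- aa
        substr(mut_aa, ci + 1L, ci + 1L) <- new_aa  # +1: ATG is residue 1
        peptides[[length(peptides) + 1L]] <- data.frame(
          peptide = draw_peptide(mut_aa, center = ci + 1L),
          origin = "snp_mutant", gene = gene_id,
          expected_class = NA_character_, stringsAsFactors = FALSE)
      } else {
        peptides[[length(peptides) + 1L]] <- data.frame(
          peptide = draw_peptide(aa), origin = "annotated", gene = gene_id,
          expected_class = NA_character_, stringsAsFactors = FALSE)
      }
    } else if (role %in% c("AUG", "near-cognate", "stop-bounded")) {
      utr5 <- 40L
      n_cod <- min(.rint(c(40L, 120L)), (L - utr5 - 19L) %/% 3L)
      start_codon <- switch(role, "AUG" = "ATG", "near-cognate" = "CTG",
                            "stop-bounded" = sample(.SAFE_CODONS, 1L))
      body_codons <- sample(.SAFE_CODONS, n_cod, replace = TRUE)
      ## a stop codon right before the start puts T at -3, so a planted
      ## near-cognate start owes its Kozak context to G at +4
      if (role == "near-cognate")
        body_codons[1L] <- sample(grep("^G", .SAFE_CODONS, value = TRUE), 1L)
      body <- paste(body_codons, collapse = "")
      core <- paste0("TAA", start_codon, body, "TGA")
      stopifnot(L >= utr5 + nchar(core) + 10L)
      T <- paste0(.rand_dna(utr5), core,
                  .rand_dna(L - utr5 - nchar(core)))
      g <- write_back(g, exons, gn$strand, T)
      orf_aa <- .translate_str(paste0(start_codon, body))
      cls <- switch(role, "AUG" = "AUG",
                    "near-cognate" = "near-cognate-Kozak",
                    "stop-bounded" = "stop-bounded")
      smorfs[[length(smorfs) + 1L]] <- data.frame(
        gene = gene_id, class = cls, start_codon = start_codon,
        n_codons = n_cod + 1L, aa = orf_aa, truncation = "none",
        true_stop_gpos = NA_integer_, stringsAsFactors = FALSE)
      peptides[[length(peptides) + 1L]] <- data.frame(
        peptide = draw_peptide(orf_aa), origin = "smorf", gene = gene_id,
        expected_class = cls, stringsAsFactors = FALSE)
    } else if (role %in% c("trunc3", "trunc5")) {
      n_cod <- .rint(c(40L, 100L))
      n_in <- n_cod %/% 2L          # codons inside the transcript
      n_out <- n_cod - n_in         # codons in the genomic flank
      body <- sample(.SAFE_CODONS, n_cod, replace = TRUE)
      aa_full <- .translate_str(paste0("ATG", paste(body, collapse = "")))
      if (role == "trunc3") {
        utr5 <- 40L
        inside <- paste0("TAA", "ATG",
                         paste(body[seq_len(n_in)], collapse = ""))
        outside <- paste0(paste(body[n_in + seq_len(n_out)], collapse = ""),
                          "TGA")
        exlen <- utr5 + nchar(inside)
        exons <- data.frame(contig = "chr1", strand = gn$strand,
                            start = gn$starts[1L],
                            end = gn$starts[1L] + exlen)
        T <- paste0(.rand_dna(utr5), inside)
        g <- write_back(g, exons, gn$strand, T)
        ## flank immediately downstream of the transcript 3' end
        fl <- nchar(outside)
        if (gn$strand == "+") {
          rng <- (exons$end + 1L):(exons$end + fl)
          g[rng] <- strsplit(outside, "")[[1L]]
          stop_gpos <- exons$end + fl - 3L
        } else {
          rng <- (exons$start - fl + 1L):exons$start
          g[rng] <- strsplit(.revcomp(outside), "")[[1L]]
          stop_gpos <- exons$start - fl
        }
      } else {
        utr3 <- 40L
        outside <- paste0("TAA", "ATG",
                          paste(body[seq_len(n_out)], collapse = ""))
        inside <- paste0(paste(body[n_out + seq_len(n_in)], collapse = ""),
                         "TGA")
        exlen <- nchar(inside) + utr3
        exons <- data.frame(contig = "chr1", strand = gn$strand,
                            start = gn$starts[1L],
                            end = gn$starts[1L] + exlen)
        T <- paste0(inside, .rand_dna(utr3))
        g <- write_back(g, exons, gn$strand, T)
        fl <- nchar(outside)
        if (gn$strand == "+") {
          rng <- (exons$start - fl + 1L):exons$start
          g[rng] <- strsplit(outside, "")[[1L]]
          stop_gpos <- exons$start - fl
        } else {
          rng <- (exons$end + 1L):(exons$end + fl)
          g[rng] <- strsplit(.revcomp(outside), "")[[1L]]
          stop_gpos <- exons$end + fl - 3L
        }
      }
      smorfs[[length(smorfs) + 1L]] <- data.frame(
        gene = gene_id, class = "AUG", start_codon = "ATG",
        n_codons = n_cod + 1L, aa = aa_full,
        truncation = if (role == "trunc3") "3p" else "5p",
        true_stop_gpos = as.integer(stop_gpos), stringsAsFactors = FALSE)
      pep_center <- if (role == "trunc3") max(2L, n_in %/% 2L) else
        1L + n_out + n_in %/% 2L
      peptides[[length(peptides) + 1L]] <- data.frame(
        peptide = draw_peptide(aa_full, center = pep_center),
        origin = "smorf", gene = gene_id, expected_class = "AUG",
        stringsAsFactors = FALSE)
    }

    ## isoforms
    n_ex <- nrow(exons)
    iso_structs <- list(seq_len(n_ex))
    if (role == "plain" && n_ex >= 3L) {
      ## one skipped internal exon per extra isoform caps what is possible
      n_iso <- min(.rint(config$isoforms_per_gene), n_ex - 1L)
      while (length(iso_structs) < n_iso) {
        drop <- .rint(c(2L, n_ex - 1L))
        cand <- setdiff(seq_len(n_ex), drop)
        if (!any(vapply(iso_structs, identical, logical(1), cand)))
          iso_structs[[length(iso_structs) + 1L]] <- cand
      }
    }
    for (iso in iso_structs) {
      tx_n <- tx_n + 1L
      tid <- sprintf("tx%04d", tx_n)
      tx_rows[[tx_n]] <- data.frame(
        transcript_id = tid, contig = "chr1", strand = gn$strand,
        start = exons$start[iso], end = exons$end[iso], gene = gene_id,
        stringsAsFactors = FALSE)
      expr[[tx_n]] <- data.frame(
        transcript_id = tid, gene = gene_id,
        coverage = max(config$coverage_min,
                       rlnorm(1L, log(config$coverage_target),
                              config$expr_sdlog)),
        stringsAsFactors = FALSE)
    }
    ## antisense companion transcript
    if (role == "plain" && runif(1L) < config$frac_antisense) {
      tx_n <- tx_n + 1L
      tid <- sprintf("tx%04d", tx_n)
      as_strand <- setdiff(c("+", "-"), gn$strand)
      tx_rows[[tx_n]] <- data.frame(
        transcript_id = tid, contig = "chr1", strand = as_strand,
        start = exons$start, end = exons$end, gene = gene_id,
        stringsAsFactors = FALSE)
      expr[[tx_n]] <- data.frame(
        transcript_id = tid, gene = gene_id,
        coverage = max(config$coverage_min,
                       rlnorm(1L, log(config$coverage_target),
                              config$expr_sdlog)),
        stringsAsFactors = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(setNames(paste(g, collapse = ""),
                                              "chr1"))
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), gene = character())
  ## generic SNPs in plain genes' exons
  plain_tx <- which(vapply(genes, function(x) x$role == "plain", logical(1)))
  if (config$n_snps > 0L && length(plain_tx)) {
    gchars <- g
    placed <- 0L; guard <- 0L
    while (placed < config$n_snps && guard < 1000L) {
      guard <- guard + 1L
      gi <- genes[[sample(plain_tx, 1L)]]
      k <- sample(length(gi$starts), 1L)
      pos <- .rint(c(gi$starts[k] + 5L, gi$ends[k] - 6L))
      if (pos %in% snps$pos) next
      ref_b <- gchars[pos + 1L]
      alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
      snps <- rbind(snps, data.frame(contig = "chr1", pos = pos,
                                     ref = ref_b, alt = alt_b,
                                     gene = NA_character_,
                                     stringsAsFactors = FALSE))
      placed <- placed + 1L
    }
  }
  sample_chars <- g
  if (nrow(snps)) sample_chars[snps$pos + 1L] <- snps$alt
  sample_genome <- Biostrings::DNAStringSet(
    setNames(paste(sample_chars, collapse = ""), "chr1"))

  ex_all <- do.call(rbind, tx_rows)
  tx <- maps_transcripts(ex_all[, c("transcript_id", "contig", "strand",
                                    "start", "end")], source = "truth")
  gene_of <- ex_all$gene[match(tx$transcripts$transcript_id,
                               ex_all$transcript_id)]
  tx$transcripts$gene <- gene_of

  structure(list(
    genome = genome, sample_genome = sample_genome, transcripts = tx,
    expression = do.call(rbind, expr),
    snps = snps,
    smorfs = if (length(smorfs)) do.call(rbind, smorfs) else
      data.frame(gene = character(), class = character(),
                 start_codon = character(), n_codons = integer(),
                 aa = character(), truncation = character(),
                 true_stop_gpos = integer()),
    peptides = if (length(peptides)) do.call(rbind, peptides) else
      data.frame(peptide = character(), origin = character(),
                 gene = character(), expected_class = character()),
    ref_proteome = Biostrings::AAStringSet(proteins),
    config = config), class = "maps_sim")
}

#' @export
print.maps_sim <- function(x, ...) {
  cat("maps_sim:", Biostrings::width(x$genome), "nt genome,",
      nrow(x$transcripts$transcripts), "transcripts,",
      nrow(x$snps), "SNPs,", nrow(x$smorfs), "planted ORFs\n")
  invisible(x)
}

#' Simulate stranded spliced reads and write them as SAM
#'
#' Single-end reads are drawn from each transcript in proportion to
#' coverage x length, spliced back to genomic coordinates with M/N CIGARs,
#' given substitution errors at the configured rate, and written under the
#' fr-firststrand convention (the read aligns antisense to its
#' transcript). Reads are taken from the sample genome, so every planted
#' SNP is present in all reads covering it.
#'
#' @param sim a \code{maps_sim} from [simulate_transcriptome()].
#' @param path output SAM path.
#' @param config optional override of \code{sim$config}.
#' @return the path, invisibly.
#' @export
simulate_reads <- function(sim, path, config = sim$config) {
  set.seed(config$seed + 1L)
  rl <- config$read_len
  tx <- sim$transcripts
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sim$genome),
                     Biostrings::width(sim$genome)))
  qual <- strrep("I", rl)
  n_read <- 0L
  multimap_left <- config$n_multimapper_reads
  recs <- list()
  for (ti in seq_len(nrow(tx$transcripts))) {
    tid <- tx$transcripts$transcript_id[ti]
    strand <- tx$transcripts$strand[ti]
    ex <- tx$exons[tx$exons$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    L <- sum(ex$end - ex$start)
    cov <- sim$expression$coverage[
      sim$expression$transcript_id == tid]
    this_rl <- min(rl, L)
    n <- ceiling(cov * L / this_rl)
    if (n <= 0L) next
    tseq <- {
      pieces <- vapply(seq_len(nrow(ex)), function(i)
        as.character(Biostrings::subseq(sim$sample_genome[[ex$contig[i]]],
                                        ex$start[i] + 1L, ex$end[i])),
        character(1))
      s <- paste(pieces, collapse = "")
      if (strand == "-") .revcomp(s) else s
    }
    starts <- sample.int(L - this_rl + 1L, n, replace = TRUE) - 1L
    for (p in starts) {
      n_read <- n_read + 1L
      rseq <- substr(tseq, p + 1L, p + this_rl)
      if (config$error_rate > 0) {
        hit <- which(runif(this_rl) < config$error_rate)
        if (length(hit)) {
          ch <- strsplit(rseq, "")[[1L]]
          for (h in hit)
            ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1L)
          rseq <- paste(ch, collapse = "")
        }
      }
      sp <- .tx_interval_spans(ex, strand, p, p + this_rl)
      sp <- sp[order(sp[, 1L]), , drop = FALSE]
      cig <- character(0)
      for (k in seq_len(nrow(sp))) {
        if (k > 1L) cig <- c(cig, sprintf("%dN", sp[k, 1L] - sp[k - 1L, 2L]))
        cig <- c(cig, sprintf("%dM", sp[k, 2L] - sp[k, 1L]))
      }
      cig <- paste(cig, collapse = "")
      seq_fwd <- if (strand == "-") .revcomp(rseq) else rseq
      flag <- if (strand == "+") 16L else 0L
      nh <- 1L
      dup <- multimap_left > 0L
      if (dup) { nh <- 2L; multimap_left <- multimap_left - 1L }
      recs[[length(recs) + 1L]] <- sprintf(
        "r%06d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
        n_read, flag, ex$contig[1L], sp[1L, 1L] + 1L, cig,
        seq_fwd, substr(qual, 1L, this_rl), nh)
      if (dup) {
        ## second placement a little upstream inside the same exon
        recs[[length(recs) + 1L]] <- sprintf(
          "r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
          n_read, flag, ex$contig[1L],
          max(1L, sp[1L, 1L] - 3L), this_rl, seq_fwd,
          substr(qual, 1L, this_rl), nh)
      }
    }
  }
  writeLines(c(lines, unlist(recs)), path)
  invisible(path)
}

#' Write the simulation truth bundle to a directory
#'
#' genome FASTA, truth GTF, reference proteome FASTA, peptide list, and
#' SNP/smORF truth TSVs, in the same dialects the pipeline reads.
#'
#' @param sim a \code{maps_sim}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_sim_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "truth.gtf"),
    proteome = file.path(dir, "ref_proteome.fa"),
    peptides = file.path(dir, "peptides.txt"),
    snps = file.path(dir, "truth_snps.tsv"),
    smorfs = file.path(dir, "truth_smorfs.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_gtf(sim$transcripts, paths["gtf"])
  Biostrings::writeXStringSet(sim$ref_proteome, paths["proteome"])
  writeLines(sim$peptides$peptide, paths["peptides"])
  write.table(sim$snps, paths["snps"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$smorfs, paths["smorfs"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
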