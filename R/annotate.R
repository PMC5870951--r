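## Microprotein identification downstream of the database search: remove
## annotated peptides, map survivors onto the ORF database, assign start
## codons, classify smORFs, and flag sample-specific mutants of annotated
## proteins.

#' Remove peptides annotated in a reference proteome
#'
#' A peptide occurring as an exact substring of any reference protein
#' (under I/L equivalence) is removed; everything else is kept as
#' potentially novel.
#'
#' @param peptides character vector of peptide sequences.
#' @param proteome [Biostrings::AAStringSet] or character vector of
#'   reference protein sequences.
#' @return the retained (non-annotated) peptides.
#' @export
filter_annotated <- function(peptides, proteome) {
  if (length(proteome) == 0L) {
    warning("empty reference proteome; all peptides pass")
    return(peptides)
  }
  hay <- .il(as.character(proteome))
  keep <- !vapply(.il(peptides), function(p) any(grepl(p, hay, fixed = TRUE)),
                  logical(1))
  peptides[keep]
}

#' Map a peptide onto the ORF database
#'
#' All ORFs whose amino-acid sequence contains the peptide (I/L-equivalent),
#' with the 1-based offset of the first occurrence.
#'
#' @param peptide one peptide sequence.
#' @param orf_db data.frame from [build_orf_db()].
#' @return data.frame of hits: orf_id, aa_offset; zero rows means the
#'   peptide is unmappable (derived from RNA absent from the database).
#' @export
map_peptide <- function(peptide, orf_db) {
  if (nrow(orf_db) == 0L)
    return(data.frame(orf_id = character(), aa_offset = integer()))
  off <- regexpr(.il(peptide), .il(orf_db$aa), fixed = TRUE)
  hit <- which(off > 0L)
  data.frame(orf_id = orf_db$orf_id[hit], aa_offset = as.integer(off[hit]),
             stringsAsFactors = FALSE)
}

#' Assign a start codon and smORF status to an ORF
#'
#' Within the stop-to-stop frame of an ORF record, in decreasing priority:
#' (1) the upstream-most in-frame ATG at or upstream of the detected
#' peptide gives start class \code{AUG}; (2) otherwise the upstream-most
#' in-frame near-cognate codon (one nucleotide substitution away from ATG)
#' in a favorable Kozak context gives \code{near-cognate-Kozak}; (3)
#' otherwise the ORF is \code{stop-bounded}. The Kozak test is the minimal
#' standard criterion: purine at -3 and/or G at +4 relative to the start
#' codon (\code{kozak_mode = "both"} requires both). The ORF is a smORF
#' when the length from the assigned start (classes 1-2) or the
#' stop-to-stop distance (class 3) is below \code{smorf_max_codons}.
#'
#' @param orf one-row ORF record (from [build_orf_db()]).
#' @param peptide optional peptide sequence; the start is constrained to
#'   lie at or upstream of it. NULL allows the whole ORF.
#' @param kozak_mode \code{"either"} (default) or \code{"both"}.
#' @param smorf_max_codons smORF length bound in codons (default 150;
#'   the bound is exclusive: 149 codons is a smORF, 150 is not).
#' @return data.frame row: start_class, start_codon, start_codon_index
#'   (0-based codon within the ORF), orf_length_codons, is_smorf.
#' @export
assign_start <- function(orf, peptide = NULL,
                         kozak_mode = c("either", "both"),
                         smorf_max_codons = 150L) {
  kozak_mode <- match.arg(kozak_mode)
  nt <- orf$nt
  n_codon <- nchar(nt) %/% 3L
  codons <- substring(nt, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  max_idx <- n_codon
  if (!is.null(peptide)) {
    off <- regexpr(.il(peptide), .il(orf$aa), fixed = TRUE)
    if (off < 1L) stop("peptide not found in ORF ", orf$orf_id)
    max_idx <- as.integer(off)          # codon of first peptide residue
  }
  res <- function(class, codon, idx) {
    len <- if (is.na(idx)) n_codon else n_codon - idx
    data.frame(start_class = class, start_codon = codon,
               start_codon_index = idx, orf_length_codons = len,
               is_smorf = len < smorf_max_codons, stringsAsFactors = FALSE)
  }
  atg <- which(codons[seq_len(max_idx)] == "ATG")
  if (length(atg)) return(res("AUG", "ATG", atg[1L] - 1L))
  nc <- which(codons[seq_len(max_idx)] %in% .NEAR_COGNATE)
  for (i in nc) {
    ## -3 relative to the codon start (= 3 nt upstream); +4 = base after it
    m3 <- if (i > 1L) substr(nt, 3L * (i - 1L) - 2L, 3L * (i - 1L) - 2L) else {
      ctx <- orf$upstream_ctx
      if (nchar(ctx) >= 3L) substr(ctx, nchar(ctx) - 2L, nchar(ctx) - 2L)
      else NA_character_
    }
    p4 <- if (i < n_codon) substr(nt, 3L * i + 1L, 3L * i + 1L) else
      substr(orf$stop_codon, 1L, 1L)
    ok3 <- !is.na(m3) && m3 %in% c("A", "G")
    ok4 <- !is.na(p4) && p4 == "G"
    if (switch(kozak_mode, either = ok3 || ok4, both = ok3 && ok4))
      return(res("near-cognate-Kozak", codons[i], i - 1L))
  }
  res("stop-bounded", NA_character_, NA_integer_)
}

#' Flag a peptide as a SNP mutant of an annotated protein
#'
#' A peptide whose only mismatches to a reference protein are explained by
#' called consensus substitutions is a sample-specific mutant of a known
#' protein, not a novel microprotein. Because the consensus and reference
#' translations of an ORF differ exactly at SNP-altered residues, the test
#' is: the reference-genome version of the peptide differs from the
#' detected peptide and occurs in the reference proteome.
#'
#' @param peptide the detected peptide.
#' @param orf the ORF record it maps to.
#' @param aa_offset 1-based offset of the peptide in \code{orf$aa}.
#' @param proteome reference proteome.
#' @return logical.
#' @export
flag_snp_mutant <- function(peptide, orf, aa_offset, proteome) {
  if (length(proteome) == 0L) return(FALSE)
  ref_pep <- substr(orf$aa_ref, aa_offset, aa_offset + nchar(peptide) - 1L)
  if (.il(ref_pep) == .il(peptide)) return(FALSE)
  if (grepl("*", ref_pep, fixed = TRUE)) return(FALSE)
  any(grepl(.il(ref_pep), .il(as.character(proteome)), fixed = TRUE))
}

#' Annotate detected peptides against the ORF database
#'
#' The full decision pipeline for one set of database-search peptides:
#' peptides matching the reference proteome are labelled annotated;
#' survivors are mapped onto the ORF database (unmappable peptides are kept
#' with a flag); peptides whose mismatches are explained by called SNPs in
#' the frame of a reference protein are labelled SNP mutants and excluded
#' from the novel list; the rest are assigned a start codon and smORF
#' status via [assign_start()]. When a peptide maps to several ORFs the
#' reported ORF is chosen deterministically, preferring class AUG, then
#' near-cognate, then the shortest ORF.
#'
#' @param peptides character vector.
#' @param orf_db data.frame from [build_orf_db()].
#' @param proteome optional reference proteome ([Biostrings::AAStringSet]
#'   or character); NULL skips the annotated-peptide and SNP-mutant steps.
#' @param kozak_mode,smorf_max_codons see [assign_start()].
#' @return data.frame, one row per input peptide: status
#'   (\code{annotated} / \code{unmappable} / \code{snp_mutant} /
#'   \code{novel}), the chosen ORF and its coordinates, start codon class,
#'   ORF length and smORF flag, and the number of database hits.
#' @export
annotate_peptides <- function(peptides, orf_db, proteome = NULL,
                              kozak_mode = "either",
                              smorf_max_codons = 150L) {
  peptides <- unique(toupper(peptides))
  novel <- if (is.null(proteome)) peptides else
    filter_annotated(peptides, proteome)
  rows <- lapply(peptides, function(p) {
    base <- data.frame(peptide = p, status = "annotated",
                       orf_id = NA_character_, transcript_id = NA_character_,
                       contig = NA_character_, strand = NA_character_,
                       start_class = NA_character_,
                       start_codon = NA_character_,
                       orf_length_codons = NA_integer_, is_smorf = NA,
                       n_hits = 0L, stringsAsFactors = FALSE)
    if (!p %in% novel) return(base)
    hits <- map_peptide(p, orf_db)
    if (nrow(hits) == 0L) { base$status <- "unmappable"; return(base) }
    base$n_hits <- nrow(hits)
    recs <- orf_db[match(hits$orf_id, orf_db$orf_id), , drop = FALSE]
    if (!is.null(proteome)) {
      snp <- vapply(seq_len(nrow(hits)), function(i)
        flag_snp_mutant(p, recs[i, ], hits$aa_offset[i], proteome),
        logical(1))
      if (any(snp)) {
        i <- which(snp)[1L]
        base$status <- "snp_mutant"
        base$orf_id <- recs$orf_id[i]
        base$transcript_id <- recs$transcript_id[i]
        base$contig <- recs$contig[i]; base$strand <- recs$strand[i]
        return(base)
      }
    }
    calls <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i)
      assign_start(recs[i, ], peptide = p, kozak_mode = kozak_mode,
                   smorf_max_codons = smorf_max_codons)))
    pri <- match(calls$start_class,
                 c("AUG", "near-cognate-Kozak", "stop-bounded"))
    i <- order(pri, calls$orf_length_codons, recs$orf_id)[1L]
    base$status <- "novel"
    base$orf_id <- recs$orf_id[i]
    base$transcript_id <- recs$transcript_id[i]
    base$contig <- recs$contig[i]; base$strand <- recs$strand[i]
    base$start_class <- calls$start_class[i]
    base$start_codon <- calls$start_codon[i]
    base$orf_length_codons <- calls$orf_length_codons[i]
    base$is_smorf <- calls$is_smorf[i]
    base
  })
  do.call(rbind, rows)
}

#' Read a reference proteome FASTA
#'
#' @param path protein FASTA.
#' @return [Biostrings::AAStringSet].
#' @export
read_proteome <- function(path) Biostrings::readAAStringSet(path)

#' Write the smORF/peptide annotation report as TSV
#'
#' @param report data.frame from [annotate_peptides()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_smorf_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
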