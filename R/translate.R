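## Stage 4: consensus-corrected transcript sequences, three-frame
## translation, and extension of open ORFs along the genome to the nearest
## in-frame stop codon.

## transcript interval [a,b) (0-based, 5'->3') to genomic half-open spans,
## in transcript order
.tx_interval_spans <- function(exons, strand, a, b) {
  lens <- exons$end - exons$start
  ord <- if (strand == "-") rev(seq_len(nrow(exons))) else
    seq_len(nrow(exons))
  offs <- cumsum(c(0L, lens[ord]))
  out <- list()
  for (k in seq_along(ord)) {
    s0 <- max(a, offs[k]); e0 <- min(b, offs[k + 1L])
    if (s0 >= e0) next
    ei <- ord[k]
    if (strand == "+")
      out[[length(out) + 1L]] <- c(exons$start[ei] + (s0 - offs[k]),
                                   exons$start[ei] + (e0 - offs[k]))
    else
      out[[length(out) + 1L]] <- c(exons$end[ei] - (e0 - offs[k]),
                                   exons$end[ei] - (s0 - offs[k]))
  }
  do.call(rbind, out)
}

## merge genomically adjacent spans (in transcript order)
.merge_spans <- function(spans, strand) {
  if (is.null(spans) || nrow(spans) < 2L) return(spans)
  out <- spans[1L, , drop = FALSE]
  for (i in 2L:nrow(spans)) {
    prev <- out[nrow(out), ]
    cur <- spans[i, ]
    joined <- if (strand == "+") prev[2L] == cur[1L] else prev[1L] == cur[2L]
    if (joined) {
      out[nrow(out), ] <- if (strand == "+") c(prev[1L], cur[2L]) else
        c(cur[1L], prev[2L])
    } else out <- rbind(out, cur)
  }
  rownames(out) <- NULL
  out
}

#' Consensus-corrected transcript sequence
#'
#' Concatenates the consensus-corrected exon slices of one transcript in
#' transcript order; minus-strand transcripts are reverse-complemented.
#'
#' @param tx a \code{maps_transcripts}.
#' @param transcript_id which transcript.
#' @param genome [Biostrings::DNAStringSet].
#' @param cons optional \code{maps_consensus}; NULL gives the reference
#'   sequence.
#' @return character sequence (5' to 3').
#' @export
transcript_sequence <- function(tx, transcript_id, genome, cons = NULL) {
  ex <- tx$exons[tx$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript: ", transcript_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  pieces <- vapply(seq_len(nrow(ex)), function(i)
    apply_consensus(genome, cons, ex$contig[i], ex$start[i], ex$end[i])$seq,
    character(1))
  s <- paste(pieces, collapse = "")
  if (ex$strand[1L] == "-") .revcomp(s) else s
}

#' Three-frame ORF extraction
#'
#' For each reading frame of the given (sense-strand) sequence, returns the
#' maximal stop-free amino-acid stretches with their nucleotide offsets.
#' Standard genetic code; stops are TAA, TAG, TGA; codons containing N
#' translate to X (not a stop). A stretch is flagged open at the 5' end
#' when no stop precedes it in its frame, and open at the 3' end when the
#' sequence ends before an in-frame stop.
#'
#' @param seq DNA character string over A,C,G,T,N.
#' @param min_aa minimum stretch length in amino acids (default 1).
#' @return data.frame: frame (0..2), aa, nt_start, nt_end (0-based
#'   half-open in \code{seq}), open5, open3.
#' @export
three_frame_orfs <- function(seq, min_aa = 1L) {
  seq <- toupper(seq)
  out <- list()
  for (f in 0:2) {
    aa_full <- .translate_str(substr(seq, f + 1L, nchar(seq)))
    n_codon <- nchar(aa_full)
    if (n_codon == 0L) next
    m <- gregexpr("[^*]+", aa_full)[[1L]]
    if (m[1L] == -1L) next
    st <- as.integer(m)
    le <- attr(m, "match.length")
    for (i in seq_along(st)) {
      if (le[i] < min_aa) next
      out[[length(out) + 1L]] <- data.frame(
        frame = f, aa = substr(aa_full, st[i], st[i] + le[i] - 1L),
        nt_start = f + 3L * (st[i] - 1L), nt_end = f + 3L * (st[i] + le[i] - 1L),
        open5 = st[i] == 1L, open3 = st[i] + le[i] - 1L == n_codon,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), aa = character(),
                      nt_start = integer(), nt_end = integer(),
                      open5 = logical(), open3 = logical()))
  do.call(rbind, out)
}

## precomputed per-transcript context: extended consensus/reference
## sequences (upstream flank + spliced transcript + downstream flank)
.tx_context <- function(exons, strand, genome, cons, max_ext) {
  contig <- exons$contig[1L]
  clen <- Biostrings::width(genome[contig])
  first_start <- min(exons$start); last_end <- max(exons$end)
  L <- sum(exons$end - exons$start)
  flank <- function(side) {
    ## side "5" = transcript-upstream, "3" = transcript-downstream
    if ((side == "5" && strand == "+") || (side == "3" && strand == "-")) {
      gs <- max(0L, first_start - max_ext); ge <- first_start
    } else {
      gs <- last_end; ge <- min(clen, last_end + max_ext)
    }
    ref <- apply_consensus(genome, NULL, contig, gs, ge)$seq
    con <- if (is.null(cons)) ref else
      apply_consensus(genome, cons, contig, gs, ge)$seq
    if (strand == "-") { ref <- .revcomp(ref); con <- .revcomp(con) }
    list(gs = gs, ge = ge, ref = ref, con = con,
         at_edge = (ge - gs) < max_ext)
  }
  f5 <- flank("5"); f3 <- flank("3")
  tx_con <- vapply(seq_len(nrow(exons)), function(i)
    apply_consensus(genome, cons, contig, exons$start[i],
                    exons$end[i])$seq, character(1))
  tx_ref <- vapply(seq_len(nrow(exons)), function(i)
    apply_consensus(genome, NULL, contig, exons$start[i],
                    exons$end[i])$seq, character(1))
  Scon <- paste(tx_con, collapse = ""); Sref <- paste(tx_ref, collapse = "")
  if (strand == "-") { Scon <- .revcomp(Scon); Sref <- .revcomp(Sref) }
  list(contig = contig, first_start = first_start, last_end = last_end,
       L = L, Scon = Scon,
       Econ = paste0(f5$con, Scon, f3$con),
       Eref = paste0(f5$ref, Sref, f3$ref),
       o = nchar(f5$con))
}

## core ORF record builder; `stretch` is one row of three_frame_orfs() on
## the consensus transcript sequence; `ctx` from .tx_context()
.orf_record <- function(stretch, ctx, exons, strand) {
  contig <- ctx$contig
  first_start <- ctx$first_start; last_end <- ctx$last_end
  L <- ctx$L; Econ <- ctx$Econ; Eref <- ctx$Eref; o <- ctx$o

  aE <- o + stretch$nt_start
  bE <- o + stretch$nt_end
  a0 <- aE; b0 <- bE
  trunc5 <- trunc3 <- FALSE
  stop_codon <- NA_character_
  if (stretch$open5) {
    repeat {
      cs <- aE - 3L
      if (cs < 0L) { trunc5 <- TRUE; break }
      codon <- substr(Econ, cs + 1L, cs + 3L)
      if (codon %in% .STOPS) break
      aE <- cs
    }
  }
  if (stretch$open3) {
    repeat {
      if (bE + 3L > nchar(Econ)) { trunc3 <- TRUE; break }
      codon <- substr(Econ, bE + 1L, bE + 3L)
      if (codon %in% .STOPS) { stop_codon <- codon; break }
      bE <- bE + 3L
    }
  } else {
    stop_codon <- substr(Econ, bE + 1L, bE + 3L)
  }
  nt <- substr(Econ, aE + 1L, bE)
  aa <- .translate_str(nt)
  aa_ref <- .translate_str(substr(Eref, aE + 1L, bE))

  ## genomic spans, in transcript order
  spans <- list()
  if (aE < o) {
    u <- o - aE
    spans[[1L]] <- if (strand == "+") c(first_start - u, first_start) else
      c(last_end, last_end + u)
  }
  ta <- max(0L, aE - o); tb <- min(L, bE - o)
  if (tb > ta)
    spans[[length(spans) + 1L]] <- .tx_interval_spans(exons, strand, ta, tb)
  if (bE > o + L) {
    v <- bE - (o + L)
    spans[[length(spans) + 1L]] <- if (strand == "+")
      c(last_end, last_end + v) else c(first_start - v, first_start)
  }
  spans <- .merge_spans(do.call(rbind, spans), strand)

  snp_pos <- which(strsplit(aa, "")[[1L]] != strsplit(aa_ref, "")[[1L]])
  list(contig = contig, strand = strand, frame = stretch$frame,
       aa = aa, aa_ref = aa_ref, nt = nt, n_aa = nchar(aa),
       ext5 = a0 - aE, ext3 = bE - b0,
       extended_5p = aE < a0, extended_3p = bE > b0,
       trunc5 = trunc5, trunc3 = trunc3,
       open5 = stretch$open5, open3 = stretch$open3,
       upstream_ctx = substr(Econ, max(1L, aE - 2L), aE),
       stop_codon = stop_codon,
       spans = spans,
       snp_count = length(snp_pos),
       snp_aa_pos = paste(snp_pos, collapse = ","))
}

#' Extend one ORF along the genome to the nearest in-frame stop
#'
#' For an ORF stretch that touches the transcript's 5' and/or 3' terminus
#' in its frame, walks the (consensus-corrected) genome outward from the
#' terminal exon -- no splicing is imputed beyond the transcript -- codon by
#' codon, up to \code{max_ext} nt or the nearest in-frame stop. The 5'
#' extension stops one codon downstream of the upstream in-frame stop.
#' Reaching the contig edge or the extension cap truncates the extension
#' and sets the corresponding boundary flag.
#'
#' @param stretch one row of [three_frame_orfs()] computed on the
#'   consensus-corrected transcript sequence.
#' @param tx a \code{maps_transcripts}.
#' @param transcript_id the transcript the stretch belongs to.
#' @param genome [Biostrings::DNAStringSet].
#' @param cons optional \code{maps_consensus}.
#' @param max_ext maximum extension per side in nt (default 10000).
#' @return one-row data.frame ORF record (see [build_orf_db()]).
#' @export
extend_orf <- function(stretch, tx, transcript_id, genome, cons = NULL,
                       max_ext = 10000L) {
  ex <- tx$exons[tx$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript: ", transcript_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  ctx <- .tx_context(ex, ex$strand[1L], genome, cons, max_ext)
  rec <- .orf_record(stretch, ctx, ex, ex$strand[1L])
  rec$transcript_id <- transcript_id
  rec$orf_id <- sprintf("%s.f%d.%d", transcript_id, rec$frame,
                        stretch$nt_start)
  .orf_rows(list(rec))
}

.orf_rows <- function(recs) {
  df <- data.frame(
    orf_id = vapply(recs, `[[`, character(1), "orf_id"),
    transcript_id = vapply(recs, `[[`, character(1), "transcript_id"),
    contig = vapply(recs, `[[`, character(1), "contig"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    frame = vapply(recs, `[[`, integer(1), "frame"),
    aa = vapply(recs, `[[`, character(1), "aa"),
    aa_ref = vapply(recs, `[[`, character(1), "aa_ref"),
    nt = vapply(recs, `[[`, character(1), "nt"),
    n_aa = vapply(recs, `[[`, integer(1), "n_aa"),
    ext5 = vapply(recs, function(r) as.integer(r$ext5), integer(1)),
    ext3 = vapply(recs, function(r) as.integer(r$ext3), integer(1)),
    extended_5p = vapply(recs, `[[`, logical(1), "extended_5p"),
    extended_3p = vapply(recs, `[[`, logical(1), "extended_3p"),
    trunc5 = vapply(recs, `[[`, logical(1), "trunc5"),
    trunc3 = vapply(recs, `[[`, logical(1), "trunc3"),
    open5 = vapply(recs, `[[`, logical(1), "open5"),
    open3 = vapply(recs, `[[`, logical(1), "open3"),
    upstream_ctx = vapply(recs, `[[`, character(1), "upstream_ctx"),
    stop_codon = vapply(recs, `[[`, character(1), "stop_codon"),
    snp_count = vapply(recs, `[[`, integer(1), "snp_count"),
    snp_aa_pos = vapply(recs, `[[`, character(1), "snp_aa_pos"),
    stringsAsFactors = FALSE)
  df$spans <- lapply(recs, `[[`, "spans")
  df
}

#' Build the translated ORF database for an assembled transcript set
#'
#' For every transcript: build the consensus-corrected sequence, translate
#' the three sense-strand frames, extract stop-free stretches, extend
#' stretches open at either terminus along the genome to the nearest
#' in-frame stop ([extend_orf()]), and record each ORF with its reference
#' (non-consensus) translation, genomic spans and provenance flags.
#' Stranded libraries make the sense strand known, so three frames suffice;
#' \code{six_frame} additionally translates the antisense sequence for
#' unstranded input.
#'
#' @param tx a \code{maps_transcripts}.
#' @param genome [Biostrings::DNAStringSet].
#' @param cons optional \code{maps_consensus} (NULL: reference-only
#'   database).
#' @param min_orf_aa minimum reported ORF length in amino acids
#'   (default 8, about the shortest useful tryptic peptide).
#' @param max_ext maximum extension per side in nt (default 10000).
#' @param six_frame also translate the antisense strand (default FALSE).
#' @return data.frame, one row per ORF record: sequences \code{aa},
#'   \code{aa_ref}, \code{nt}; extension fields \code{ext5}, \code{ext3},
#'   flags; \code{spans} (list of genomic half-open span matrices in
#'   transcript order); SNP-altered residue positions.
#' @export
build_orf_db <- function(tx, genome, cons = NULL, min_orf_aa = 8L,
                         max_ext = 10000L, six_frame = FALSE) {
  recs <- list()
  for (tid in tx$transcripts$transcript_id) {
    ex <- tx$exons[tx$exons$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    strands <- ex$strand[1L]
    if (six_frame) strands <- c(strands, setdiff(c("+", "-"), strands))
    for (str in strands) {
      exs <- ex; exs$strand <- str
      ctx <- .tx_context(exs, str, genome, cons, max_ext)
      stretches <- three_frame_orfs(ctx$Scon, min_aa = 1L)
      for (i in seq_len(nrow(stretches))) {
        rec <- .orf_record(stretches[i, ], ctx, exs, str)
        if (rec$n_aa < min_orf_aa) next
        rec$transcript_id <- tid
        rec$orf_id <- sprintf("%s%s.f%d.%d", tid,
                              if (str != ex$strand[1L]) ".as" else "",
                              rec$frame, stretches$nt_start[i])
        recs[[length(recs) + 1L]] <- rec
      }
    }
  }
  if (!length(recs)) {
    df <- .orf_rows(list())
    return(df)
  }
  .orf_rows(recs)
}

#' Write ORF metadata as TSV
#'
#' @param orfs ORF database from [build_orf_db()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_orf_tsv <- function(orfs, path) {
  df <- orfs
  df$spans <- vapply(df$spans, function(m)
    paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ","), character(1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
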