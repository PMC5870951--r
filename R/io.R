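## Readers/writers for the standard formats and the coordinate contract.
## Internal convention everywhere: 0-based half-open [start, end) intervals.

#' Read a genome FASTA
#'
#' @param path path to a (multi-)FASTA file of contigs.
#' @return a [Biostrings::DNAStringSet] named by the first whitespace-free
#'   token of each header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) stop("no sequences in genome FASTA: ", path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read spliced alignments from SAM/BAM
#'
#' Loads primary alignments and splits each one into its reference-consuming
#' blocks: M/=/X/D CIGAR segments, cut at N operations. Deletions are
#' absorbed into the surrounding block (the deleted reference positions are
#' padded with \code{N} in the block bases, so they contribute no consensus
#' counts); insertions and soft clips consume no reference and are dropped.
#' Multi-mapped reads (NH tag > 1, or any secondary record) are removed by
#' default, before they can contribute to coverage, junctions or consensus.
#'
#' The library strand of each read is inferred from the alignment strand
#' under the chosen stranded-library convention: for \code{fr-firststrand}
#' libraries the read aligns antisense to its transcript, so the inferred
#' transcript strand is the opposite of the alignment strand.
#'
#' @param path SAM or BAM file. SAM input is converted (sorted, indexed)
#'   via [Rsamtools::asBam] in a temporary location.
#' @param genome optional [Biostrings::DNAStringSet]; when supplied, an
#'   alignment contig absent from the genome is a fatal error.
#' @param drop_multimappers drop reads with NH > 1 (default \code{TRUE}).
#' @param strand_mode one of \code{"firststrand"} (default),
#'   \code{"secondstrand"}, \code{"unstranded"}.
#' @return an object of class \code{maps_alignments}: a list with
#'   \code{blocks} (one row per aligned block: \code{read}, \code{read_id},
#'   \code{contig}, \code{lib_strand}, \code{start}, \code{end},
#'   \code{bases}) and \code{reads} (one row per read), plus counters.
#' @export
read_alignments <- function(path, genome = NULL, drop_multimappers = TRUE,
                            strand_mode = c("firststrand", "secondstrand",
                                            "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  n_total <- length(aln)
  nh <- S4Vectors::mcols(aln)$NH
  nh[is.na(nh)] <- 1L
  n_multi <- sum(nh > 1L)
  if (drop_multimappers && n_multi > 0L) {
    aln <- aln[nh == 1L]
    nh <- nh[nh == 1L]
  }
  contigs <- as.character(GenomicAlignments::seqnames(aln))
  if (!is.null(genome)) {
    missing <- setdiff(unique(contigs), names(genome))
    if (length(missing))
      stop("alignment contig(s) absent from genome: ",
           paste(missing, collapse = ", "))
  }
  al_strand <- as.character(BiocGenerics::strand(aln))
  lib_strand <- switch(strand_mode,
    firststrand  = ifelse(al_strand == "+", "-", "+"),
    secondstrand = al_strand,
    unstranded   = rep("*", length(aln)))

  if (length(aln) == 0L) {
    empty_blocks <- data.table(read = integer(), read_id = character(),
                               contig = character(), lib_strand = character(),
                               start = integer(), end = integer(),
                               bases = character())
    empty_reads <- data.table(read = integer(), read_id = character(),
                              contig = character(), lib_strand = character(),
                              n_hits = integer())
    return(structure(list(blocks = empty_blocks, reads = empty_reads,
                          n_alignments = n_total, n_multimappers = n_multi,
                          strand_mode = strand_mode),
                     class = "maps_alignments"))
  }

  cig <- GenomicAlignments::cigar(aln)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  nop <- lengths(ops)
  qseq <- as.character(S4Vectors::mcols(aln)$seq)
  pos0 <- BiocGenerics::start(aln) - 1L

  dt <- data.table(read = rep(seq_along(aln), nop),
                   op = unlist(ops), len = unlist(lens))
  bad <- setdiff(unique(dt$op), c("M", "=", "X", "I", "D", "N", "S", "H", "P"))
  if (length(bad)) stop("malformed CIGAR operation(s): ",
                        paste(bad, collapse = ","))
  dt[, qend := cumsum(len * (op %chin% c("M", "=", "X", "I", "S"))), by = read]
  dt[, qstart := qend - len * (op %chin% c("M", "=", "X", "I", "S"))]
  dt[, rend := cumsum(len * (op %chin% c("M", "=", "X", "D", "N"))), by = read]
  dt[, rstart := rend - len * (op %chin% c("M", "=", "X", "D", "N"))]
  dt[, blk := cumsum(op == "N"), by = read]
  keep <- dt[op %chin% c("M", "=", "X", "D")]
  keep[, piece := ifelse(op == "D", strrep("N", len),
                         substr(qseq[read], qstart + 1L, qend))]
  blocks <- keep[, .(start = min(rstart), end = max(rend),
                     bases = paste(piece, collapse = "")),
                 by = .(read, blk)]
  blocks[, start := start + pos0[read]]
  blocks[, end := end + pos0[read]]
  stopifnot(all(nchar(blocks$bases) == blocks$end - blocks$start))
  blocks[, `:=`(read_id = S4Vectors::mcols(aln)$qname[read],
                contig = contigs[read], lib_strand = lib_strand[read])]
  blocks <- blocks[, .(read, read_id, contig, lib_strand, start, end, bases)]
  setkey(blocks, read)
  reads <- data.table(read = seq_along(aln),
                      read_id = S4Vectors::mcols(aln)$qname,
                      contig = contigs, lib_strand = lib_strand,
                      n_hits = as.integer(nh))
  structure(list(blocks = blocks, reads = reads,
                 n_alignments = n_total, n_multimappers = n_multi,
                 strand_mode = strand_mode),
            class = "maps_alignments")
}

#' @export
print.maps_alignments <- function(x, ...) {
  cat("maps_alignments:", nrow(x$reads), "reads,", nrow(x$blocks), "blocks",
      sprintf("(%d multimappers in input, strand mode %s)\n",
              x$n_multimappers, x$strand_mode))
  invisible(x)
}

#' Construct a transcript set
#'
#' @param exons data.frame with columns \code{transcript_id}, \code{contig},
#'   \code{strand}, \code{start}, \code{end} (0-based half-open), optionally
#'   \code{x} (length-normalized read count of each exon).
#' @param mean_x optional named vector of per-transcript mean exon expression.
#' @param source source tag used when writing GTF.
#' @return an object of class \code{maps_transcripts}: list with
#'   \code{transcripts} and \code{exons} data.frames.
#' @export
maps_transcripts <- function(exons, mean_x = NULL, source = "MAPS") {
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  need <- c("transcript_id", "contig", "strand", "start", "end")
  if (!all(need %in% names(exons)))
    stop("exon table needs columns: ", paste(need, collapse = ", "))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons)) {
    if (any(exons$end <= exons$start)) stop("exon with end <= start")
    exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in by_tx) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (length(idx) > 1L && any(s[-1L] < e[-length(e)]))
        stop("overlapping exons within transcript ",
             exons$transcript_id[idx[1L]])
      if (length(unique(exons$strand[idx])) != 1L ||
          length(unique(exons$contig[idx])) != 1L)
        stop("inconsistent contig/strand within transcript ",
             exons$transcript_id[idx[1L]])
    }
    exons$exon_rank <- unlist(lapply(by_tx, seq_along))[
      order(unlist(by_tx))]
  } else {
    exons$exon_rank <- integer()
  }
  tx_ids <- unique(exons$transcript_id)
  tx <- data.frame(
    transcript_id = tx_ids,
    contig = exons$contig[match(tx_ids, exons$transcript_id)],
    strand = exons$strand[match(tx_ids, exons$transcript_id)],
    n_exons = as.integer(table(exons$transcript_id)[tx_ids]),
    stringsAsFactors = FALSE)
  tx$mean_x <- if (nrow(tx) == 0L) numeric() else
    if (!is.null(mean_x)) unname(mean_x[tx$transcript_id]) else
    if ("x" %in% names(exons))
      vapply(tx_ids, function(i) mean(exons$x[exons$transcript_id == i]),
             numeric(1)) else NA_real_
  structure(list(transcripts = tx, exons = exons, source = source),
            class = "maps_transcripts")
}

#' @export
print.maps_transcripts <- function(x, ...) {
  cat("maps_transcripts:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Write transcripts as GTF
#'
#' Emits one \code{exon} feature line per exon, 1-based inclusive, exons in
#' ascending genomic order within each transcript. Volatile comment lines
#' (date stamps) are stripped so identical inputs give byte-identical files.
#'
#' @param tx a \code{maps_transcripts} object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gtf <- function(tx, path) {
  stopifnot(inherits(tx, "maps_transcripts"))
  ex <- tx$exons
  if (nrow(ex) == 0L) {
    writeLines(c("##gff-version 2", "## 0 transcripts"), path)
    return(invisible(path))
  }
  ord_tx <- tx$transcripts[order(tx$transcripts$contig,
                                 vapply(tx$transcripts$transcript_id,
                                        function(i) min(ex$start[ex$transcript_id == i]),
                                        integer(1)),
                                 tx$transcripts$transcript_id), ]
  ex <- ex[order(match(ex$transcript_id, ord_tx$transcript_id), ex$start), ]
  gr <- GenomicRanges::GRanges(
    ex$contig, IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand,
    source = factor(rep(tx$source %||% "MAPS", nrow(ex))),
    type = factor(rep("exon", nrow(ex))),
    gene_id = ex$transcript_id, transcript_id = ex$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  lines <- readLines(path)
  lines <- lines[!grepl("^##(date|source-version)", lines)]
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a GTF into a transcript set
#'
#' Keeps \code{exon} features and groups them by \code{transcript_id};
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path GTF file.
#' @return a \code{maps_transcripts} object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L)
    return(maps_transcripts(data.frame(transcript_id = character(),
                                       contig = character(),
                                       strand = character(),
                                       start = integer(), end = integer())))
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "exon"]
  src <- unique(as.character(S4Vectors::mcols(gr)$source))
  ex <- data.frame(
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE)
  maps_transcripts(ex, source = if (length(src) == 1L) src else "MAPS")
}

#' Write an ORF database as protein FASTA
#'
#' One entry per ORF record; the header encodes transcript, frame, genomic
#' span, extension lengths and SNP count so any downstream peptide hit is
#' traceable to its genomic origin:
#' \code{transcript|f<frame>|contig:spans:strand|ext5:n|ext3:n|snps:k}.
#' Distinct ORFs with identical peptide sequence are all kept -- a search
#' hit must remain traceable to every genomic origin that can produce it.
#'
#' @param orfs ORF database (data.frame from [build_orf_db()]).
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_protein_fasta <- function(orfs, path) {
  if (is.null(orfs) || nrow(orfs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(nchar(orfs$aa) > 0L))
  spans <- vapply(orfs$spans, function(m)
    paste(sprintf("%d-%d", m[, 1L] + 1L, m[, 2L]), collapse = ","),
    character(1))
  hdr <- sprintf("%s|f%d|%s:%s:%s|ext5:%d|ext3:%d|snps:%d",
                 orfs$transcript_id, orfs$frame, orfs$contig, spans,
                 orfs$strand, orfs$ext5, orfs$ext3, orfs$snp_count)
  if (anyDuplicated(hdr)) stop("duplicate protein FASTA headers")
  aa <- Biostrings::AAStringSet(orfs$aa)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a peptide list (plain text or FASTA)
#'
#' @param path one peptide per line, or a FASTA file.
#' @return character vector of uppercase peptide sequences.
#' @export
read_peptides <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    toupper(as.character(Biostrings::readAAStringSet(path)))
  } else {
    x <- trimws(readLines(path))
    toupper(x[nzchar(x) & !startsWith(x, "#")])
  }
}
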