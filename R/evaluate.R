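## Assembler evaluation by exon overlap: a transcript is recovered when at
## least one of its exons overlaps an exon of some transcript in the other
## set by >= 1 nt.

#' Do two transcripts overlap at the exon level?
#'
#' TRUE iff some exon of \code{a} intersects some exon of \code{b} by at
#' least one nucleotide on the same contig (and strand, when
#' \code{strand_aware}). Transcripts sharing only intron space do not
#' overlap. Symmetric in its arguments.
#'
#' @param a,b exon tables (data.frames with contig, strand, start, end) of
#'   one transcript each, 0-based half-open.
#' @param strand_aware require matching strands (default FALSE: the
#'   recovery definition is strand-silent).
#' @return logical.
#' @export
transcripts_overlap <- function(a, b, strand_aware = FALSE) {
  same_ctg <- outer(a$contig, b$contig, "==")
  if (strand_aware) same_ctg <- same_ctg & outer(a$strand, b$strand, "==")
  ov <- outer(a$start, b$end, "<") & outer(a$end, b$start, ">")
  any(same_ctg & ov)
}

#' Evaluate an assembly against a reference annotation
#'
#' A reference transcript is recovered when any assembled transcript
#' overlaps it under the exon-overlap rule (once, however many assembled
#' transcripts hit it); an assembled transcript overlapping no reference
#' transcript is spurious. Recall = recovered / n_reference; precision =
#' matched assembled / n_assembled. Empty inputs give NA for the undefined
#' ratio.
#'
#' @param assembled,reference \code{maps_transcripts} objects.
#' @param strand_aware require matching strands (default FALSE).
#' @return object of class \code{maps_eval}: list of counts, precision,
#'   recall, total assembled transcriptome nt, and a per-reference match
#'   table.
#' @export
evaluate_assembly <- function(assembled, reference, strand_aware = FALSE) {
  stopifnot(inherits(assembled, "maps_transcripts"),
            inherits(reference, "maps_transcripts"))
  a_ex <- assembled$exons; r_ex <- reference$exons
  a_ids <- assembled$transcripts$transcript_id
  r_ids <- reference$transcripts$transcript_id
  if (nrow(a_ex) && nrow(r_ex)) {
    agr <- GenomicRanges::GRanges(a_ex$contig,
                                  IRanges::IRanges(a_ex$start + 1L, a_ex$end),
                                  strand = a_ex$strand)
    rgr <- GenomicRanges::GRanges(r_ex$contig,
                                  IRanges::IRanges(r_ex$start + 1L, r_ex$end),
                                  strand = r_ex$strand)
    ov <- GenomicRanges::findOverlaps(agr, rgr,
                                      ignore.strand = !strand_aware)
    hit_a <- unique(a_ex$transcript_id[S4Vectors::queryHits(ov)])
    hit_r <- unique(r_ex$transcript_id[S4Vectors::subjectHits(ov)])
  } else hit_a <- hit_r <- character(0)
  n_ref <- length(r_ids); n_asm <- length(a_ids)
  tp <- length(hit_r)
  fp <- n_asm - length(hit_a)
  total_nt <- if (nrow(a_ex)) sum(a_ex$end - a_ex$start) else 0L
  res <- list(
    n_reference = n_ref, n_assembled = n_asm,
    n_recovered = tp, n_missed = n_ref - tp,
    n_unmatched_assembled = fp,
    recall = if (n_ref > 0L) tp / n_ref else NA_real_,
    precision = if (n_asm > 0L) (n_asm - fp) / n_asm else NA_real_,
    total_transcriptome_nt = as.integer(total_nt),
    matches = data.frame(transcript_id = r_ids,
                         recovered = r_ids %in% hit_r,
                         stringsAsFactors = FALSE))
  class(res) <- "maps_eval"
  res
}

#' @export
print.maps_eval <- function(x, ...) {
  cat(sprintf(paste0("maps_eval: %d assembled vs %d reference | recall ",
                     "%.3f, precision %.3f, %d nt assembled\n"),
              x$n_assembled, x$n_reference,
              x$recall, x$precision, x$total_transcriptome_nt))
  invisible(x)
}

#' Write an evaluation result as JSON (plus optional match table TSV)
#'
#' @param ev a \code{maps_eval}.
#' @param path JSON output path.
#' @param tsv_path optional path for the per-reference match table.
#' @return \code{path}, invisibly.
#' @export
write_eval_json <- function(ev, path, tsv_path = NULL) {
  x <- ev[c("n_reference", "n_assembled", "n_recovered", "n_missed",
            "n_unmatched_assembled", "recall", "precision",
            "total_transcriptome_nt")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(tsv_path))
    write.table(ev$matches, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
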