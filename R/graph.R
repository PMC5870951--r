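## Stage 2: junctions and all read-supported candidate exons, derived by
## subdividing contiguous covered regions at retained junction points.

#' Collect splice junctions from spliced alignments
#'
#' One junction per distinct (contig, donor_end, acceptor_start, strand),
#' with a supporting read count. The intron is the half-open interval
#' \code{[donor_end, acceptor_start)}. Gaps shorter than \code{min_intron}
#' are treated as alignment deletions, not introns.
#'
#' @param aln a \code{maps_alignments}.
#' @param min_intron minimum intron length in nt (default 20).
#' @return data.frame: contig, strand, donor_end, acceptor_start, count.
#' @export
collect_junctions <- function(aln, min_intron = 20L) {
  stopifnot(inherits(aln, "maps_alignments"))
  bl <- aln$blocks
  empty <- data.frame(contig = character(), strand = character(),
                      donor_end = integer(), acceptor_start = integer(),
                      count = integer(), stringsAsFactors = FALSE)
  if (nrow(bl) == 0L) return(empty)
  gaps <- bl[, if (.N > 1L) list(donor_end = end[-.N],
                                 acceptor_start = start[-1L]),
             by = .(read, contig, lib_strand)]
  if (nrow(gaps) == 0L) return(empty)
  gaps <- gaps[acceptor_start - donor_end >= min_intron]
  if (nrow(gaps) == 0L) return(empty)
  j <- gaps[, .(count = .N),
            by = .(contig, strand = lib_strand, donor_end, acceptor_start)]
  setorder(j, contig, strand, donor_end, acceptor_start)
  as.data.frame(j)
}

## keep the highest-count member of every same-shared-endpoint cluster whose
## free endpoints lie within `window` nt of an already accepted one
.dominant_keep <- function(shared, free, count, window) {
  keep <- rep(TRUE, length(shared))
  for (grp in split(seq_along(shared), shared)) {
    if (length(grp) < 2L) next
    ord <- grp[order(-count[grp], free[grp])]
    acc <- integer(0)
    for (i in ord) {
      if (length(acc) && any(abs(free[i] - acc) <= window)) keep[i] <- FALSE
      else acc <- c(acc, free[i])
    }
  }
  keep
}

#' Filter junctions by support, intron length, and endpoint plausibility
#'
#' Removes junctions with fewer than \code{min_junction_reads} supporting
#' reads and junctions whose intron exceeds \code{max_intron} nt
#' (biologically implausible; the bound is inclusive, an intron of exactly
#' \code{max_intron} is retained). Among junctions that share one endpoint
#' and whose other endpoints lie within \code{endpoint_window} nt of each
#' other, only the best-supported one is kept -- the dominant-count reading
#' of keeping only the most probable intron endpoints.
#'
#' @param junctions data.frame from [collect_junctions()].
#' @param min_junction_reads minimum supporting reads (default 2).
#' @param max_intron maximum intron length in nt (default 1e6).
#' @param endpoint_window clustering window in nt for the endpoint
#'   plausibility rule (default 10).
#' @return filtered junction data.frame.
#' @export
filter_junctions <- function(junctions, min_junction_reads = 2L,
                             max_intron = 1000000L, endpoint_window = 10L) {
  j <- junctions
  if (nrow(j) == 0L) return(j)
  j <- j[j$count >= min_junction_reads &
         (j$acceptor_start - j$donor_end) <= max_intron, , drop = FALSE]
  if (nrow(j) == 0L) return(j)
  grp <- paste(j$contig, j$strand, sep = "\r")
  k1 <- .dominant_keep(paste(grp, j$donor_end), j$acceptor_start, j$count,
                       endpoint_window)
  k2 <- .dominant_keep(paste(grp, j$acceptor_start), j$donor_end, j$count,
                       endpoint_window)
  j <- j[k1 & k2, , drop = FALSE]
  rownames(j) <- NULL
  j
}

#' Contiguous read-covered regions with gap filling
#'
#' Per (contig, strand), the maximal regions of depth > 0, after bridging
#' zero-coverage gaps of at most \code{max_fill_gap} nt that are flanked by
#' coverage on both sides (internal reads extended to fill gaps).
#'
#' @param aln a \code{maps_alignments}.
#' @param max_fill_gap largest zero-coverage gap to bridge (default 50 nt).
#' @return data.frame: contig, strand, start, end (0-based half-open).
#' @export
build_coverage_contigs <- function(aln, max_fill_gap = 50L) {
  stopifnot(inherits(aln, "maps_alignments"))
  bl <- aln$blocks
  if (nrow(bl) == 0L)
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer()))
  out <- bl[, {
    r <- IRanges::reduce(IRanges::IRanges(start + 1L, end),
                         min.gapwidth = max_fill_gap + 1L)
    list(start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r))
  }, by = .(contig, strand = lib_strand)]
  setorder(out, contig, strand, start)
  as.data.frame(out)
}

#' Generate all candidate exons with read coverage
#'
#' Every coverage contig is cut at every retained junction point (donor
#' ends and acceptor starts) that falls inside it, and one candidate exon
#' is emitted for each pair of boundary choices (contig edge or junction
#' point) on each side -- the "all possible exons" set. A candidate may not
#' overlap the intron of a retained junction on the same strand; with
#' \code{emit_retained_introns} the variants that fully contain an intron
#' are kept and flagged instead.
#'
#' Each candidate's expression \code{X} is its overlapping read count per
#' kilobase of exon length. Candidates with \code{X} below
#' \code{min_exon_support} are dropped, and junction-less (single-exon
#' transcript) candidates shorter than \code{short_single_exon_len} nt must
#' reach \code{short_single_exon_support} supporting reads -- short
#' single-exon transcripts need elevated support or they dominate the
#' database.
#'
#' @param contigs data.frame from [build_coverage_contigs()].
#' @param junctions retained junctions from [filter_junctions()].
#' @param aln the \code{maps_alignments} used to build both.
#' @param min_exon_support minimum X in reads/kb (default 1).
#' @param short_single_exon_len length threshold in nt (default 1000).
#' @param short_single_exon_support read support required below it
#'   (default 4).
#' @param emit_retained_introns keep (flagged) intron-retention variants
#'   (default FALSE).
#' @param max_boundaries_per_contig safety cap on cut points per coverage
#'   contig (default 40) against combinatorial explosion.
#' @return data.frame of candidate exons: exon_id, contig, strand, start,
#'   end, length, n_reads, X, left_jb, right_jb, retained_intron.
#' @export
make_candidate_exons <- function(contigs, junctions, aln,
                                 min_exon_support = 1,
                                 short_single_exon_len = 1000L,
                                 short_single_exon_support = 4L,
                                 emit_retained_introns = FALSE,
                                 max_boundaries_per_contig = 40L) {
  stopifnot(inherits(aln, "maps_alignments"))
  cand <- list()
  used_j <- rep(FALSE, nrow(junctions))
  for (i in seq_len(nrow(contigs))) {
    ctg <- contigs$contig[i]; str <- contigs$strand[i]
    S <- contigs$start[i]; E <- contigs$end[i]
    jj <- junctions[junctions$contig == ctg & junctions$strand == str, ,
                    drop = FALSE]
    acc <- sort(unique(jj$acceptor_start[jj$acceptor_start >= S &
                                         jj$acceptor_start < E]))
    don <- sort(unique(jj$donor_end[jj$donor_end > S & jj$donor_end <= E]))
    used_j <- used_j | (junctions$contig == ctg & junctions$strand == str &
                        ((junctions$acceptor_start >= S &
                          junctions$acceptor_start < E) |
                         (junctions$donor_end > S &
                          junctions$donor_end <= E)))
    if (length(acc) + length(don) > max_boundaries_per_contig) {
      warning("coverage contig ", ctg, ":", S, "-", E, " has ",
              length(acc) + length(don),
              " junction boundaries; keeping the strongest")
      topj <- jj[order(-jj$count), , drop = FALSE]
      topj <- topj[seq_len(min(nrow(topj), max_boundaries_per_contig %/% 2L)), ]
      acc <- sort(unique(topj$acceptor_start[topj$acceptor_start >= S &
                                             topj$acceptor_start < E]))
      don <- sort(unique(topj$donor_end[topj$donor_end > S &
                                        topj$donor_end <= E]))
    }
    lefts <- sort(unique(c(S, acc)))
    rights <- sort(unique(c(E, don)))
    pairs <- expand.grid(start = lefts, end = rights)
    pairs <- pairs[pairs$end > pairs$start, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    ## no candidate may straddle a retained intron on the same strand
    introns <- jj[, c("donor_end", "acceptor_start")]
    if (nrow(introns)) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(pairs$start + 1L, pairs$end),
        IRanges::IRanges(introns$donor_end + 1L, introns$acceptor_start))
      overlaps <- unique(S4Vectors::queryHits(ov))
      contains <- unique(S4Vectors::queryHits(ov)[
        pairs$start[S4Vectors::queryHits(ov)] <=
          introns$donor_end[S4Vectors::subjectHits(ov)] &
        pairs$end[S4Vectors::queryHits(ov)] >=
          introns$acceptor_start[S4Vectors::subjectHits(ov)]])
      partial <- setdiff(overlaps, contains)
      ri <- rep(FALSE, nrow(pairs))
      if (emit_retained_introns) {
        ri[contains] <- TRUE
        drop_idx <- partial
      } else drop_idx <- overlaps
      keep <- setdiff(seq_len(nrow(pairs)), drop_idx)
      pairs <- pairs[keep, , drop = FALSE]
      ri <- ri[keep]
    } else ri <- rep(FALSE, nrow(pairs))
    if (nrow(pairs) == 0L) next
    cand[[length(cand) + 1L]] <- data.frame(
      contig = ctg, strand = str, start = pairs$start, end = pairs$end,
      left_jb = pairs$start %in% acc, right_jb = pairs$end %in% don,
      retained_intron = ri, stringsAsFactors = FALSE)
  }
  ## junction points falling outside every coverage contig
  if (any(!used_j) && nrow(junctions))
    warning(sum(!used_j), " junction(s) outside all coverage contigs ignored")
  if (!length(cand))
    return(data.frame(exon_id = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), length = integer(),
                      n_reads = integer(), X = numeric(),
                      left_jb = logical(), right_jb = logical(),
                      retained_intron = logical()))
  ex <- do.call(rbind, cand)
  ## read support: distinct reads with >= 1 block overlapping the exon
  bl <- aln$blocks
  exr <- GenomicRanges::GRanges(ex$contig, IRanges::IRanges(ex$start + 1L,
                                                            ex$end),
                                strand = ex$strand)
  blr <- GenomicRanges::GRanges(bl$contig, IRanges::IRanges(bl$start + 1L,
                                                            bl$end),
                                strand = bl$lib_strand)
  ov <- GenomicRanges::findOverlaps(exr, blr)
  hit <- unique(data.table(exon = S4Vectors::queryHits(ov),
                           read = bl$read[S4Vectors::subjectHits(ov)]))
  nreads <- hit[, .N, by = exon]
  ex$n_reads <- 0L
  ex$n_reads[nreads$exon] <- nreads$N
  ex$length <- ex$end - ex$start
  ex$X <- ex$n_reads / (ex$length / 1000)
  keep <- ex$X >= min_exon_support
  single <- !ex$left_jb & !ex$right_jb
  keep <- keep & !(single & ex$length < short_single_exon_len &
                   ex$n_reads < short_single_exon_support)
  ex <- ex[keep, , drop = FALSE]
  ex <- ex[order(ex$contig, ex$strand, ex$start, ex$end), , drop = FALSE]
  rownames(ex) <- NULL
  ex$exon_id <- sprintf("e%d", seq_len(nrow(ex)))
  ex[, c("exon_id", "contig", "strand", "start", "end", "length",
         "n_reads", "X", "left_jb", "right_jb", "retained_intron")]
}

#' Write retained junctions as 6-column BED (score = read count)
#'
#' @param junctions junction data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  if (nrow(junctions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(junctions$contig, junctions$donor_end,
                    junctions$acceptor_start,
                    sprintf("J%d", seq_len(nrow(junctions))),
                    junctions$count, junctions$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
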