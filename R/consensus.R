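## Per-position consensus from aligned read bases, so translation reflects
## sample-specific point mutations rather than the reference genome.

#' Build a per-position consensus database from aligned reads
#'
#' Tallies the aligned base of every read (once per read) at every covered
#' reference position. \code{N} bases -- sequencing no-calls and the padding
#' inserted over read deletions -- are ignored. A position receives a
#' consensus call only when its coverage reaches \code{min_cov} and the
#' majority base accounts for at least \code{maj_frac} of the tally; ties
#' never produce a call. Counts are pooled across read strands: a genomic
#' substitution is strand-symmetric.
#'
#' @param aln a \code{maps_alignments} object (multimappers already removed).
#' @param min_cov minimum coverage for a call (default 5).
#' @param maj_frac minimum majority fraction for a call (default 0.8).
#' @return object of class \code{maps_consensus}: a data.table keyed by
#'   (\code{contig}, \code{pos}) with counts \code{A,C,G,T},
#'   \code{coverage} and \code{call} (NA where no call).
#' @export
build_consensus <- function(aln, min_cov = 5L, maj_frac = 0.8) {
  stopifnot(inherits(aln, "maps_alignments"))
  bl <- aln$blocks
  empty <- data.table(contig = character(), pos = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), coverage = integer(),
                      call = character())
  if (nrow(bl) == 0L)
    return(structure(setkey(empty, contig, pos), min_cov = min_cov,
                     maj_frac = maj_frac, class = c("maps_consensus",
                                                    class(empty))))
  w <- nchar(bl$bases)
  tall <- data.table(
    contig = rep(bl$contig, w),
    pos = rep(bl$start, w) + sequence(w) - 1L,
    base = unlist(strsplit(bl$bases, "", fixed = TRUE), use.names = FALSE))
  tall <- tall[base %chin% c("A", "C", "G", "T")]
  if (nrow(tall) == 0L)
    return(structure(setkey(empty, contig, pos), min_cov = min_cov,
                     maj_frac = maj_frac, class = c("maps_consensus",
                                                    class(empty))))
  cnt <- dcast(tall[, .N, by = .(contig, pos, base)],
               contig + pos ~ base, value.var = "N", fill = 0L)
  for (b in c("A", "C", "G", "T"))
    if (!b %in% names(cnt)) cnt[, (b) := 0L]
  m <- as.matrix(cnt[, c("A", "C", "G", "T"), with = FALSE])
  cov <- as.integer(rowSums(m))
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  ties <- rowSums(m == mx) > 1L
  top <- c("A", "C", "G", "T")[max.col(m, ties.method = "first")]
  call <- ifelse(!ties & cov >= min_cov & mx / cov >= maj_frac, top,
                 NA_character_)
  cnt[, coverage := cov]
  cnt[, call := call]
  setkey(cnt, contig, pos)
  structure(cnt, min_cov = min_cov, maj_frac = maj_frac,
            class = c("maps_consensus", class(cnt)))
}

#' @export
print.maps_consensus <- function(x, ...) {
  cat("maps_consensus:", nrow(x), "covered positions,",
      sum(!is.na(x$call)), "called",
      sprintf("(min_cov=%d, maj_frac=%g)\n",
              attr(x, "min_cov"), attr(x, "maj_frac")))
  invisible(x)
}

#' Apply consensus calls to a genomic interval
#'
#' Returns the genome slice over \code{[start, end)} with the consensus base
#' substituted wherever a call exists and differs from the reference, plus
#' the list of substitutions made. Idempotent; with \code{cons = NULL} it is
#' the identity on the reference slice.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param cons a \code{maps_consensus} (or NULL for reference-only).
#' @param contig contig name.
#' @param start,end 0-based half-open interval, within contig bounds.
#' @return list with \code{seq} (character) and \code{substitutions}
#'   (data.frame: contig, pos, ref, alt, depth, fraction).
#' @export
apply_consensus <- function(genome, cons, contig, start, end) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  L <- Biostrings::width(genome[contig])
  if (start < 0L || end > L || end < start)
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, contig, L))
  ref <- as.character(Biostrings::subseq(genome[[contig]], start + 1L, end))
  no_subs <- data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        depth = integer(), fraction = numeric(),
                        stringsAsFactors = FALSE)
  if (is.null(cons) || nrow(cons) == 0L || end == start)
    return(list(seq = ref, substitutions = no_subs))
  .ctg <- contig; .lo <- start; .hi <- end
  sel <- cons[list(.ctg), nomatch = NULL][pos >= .lo & pos < .hi &
                                          !is.na(call)]
  if (nrow(sel) == 0L) return(list(seq = ref, substitutions = no_subs))
  rel <- sel$pos - start
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  refb <- chars[rel + 1L]
  diff <- sel$call != refb
  if (!any(diff)) return(list(seq = ref, substitutions = no_subs))
  sel <- sel[diff]; rel <- rel[diff]; refb <- refb[diff]
  chars[rel + 1L] <- sel$call
  m <- as.matrix(sel[, c("A", "C", "G", "T"), with = FALSE])
  altn <- m[cbind(seq_len(nrow(m)), match(sel$call, c("A", "C", "G", "T")))]
  list(seq = paste(chars, collapse = ""),
       substitutions = data.frame(
         contig = contig, pos = sel$pos, ref = refb, alt = sel$call,
         depth = sel$coverage, fraction = altn / sel$coverage,
         stringsAsFactors = FALSE))
}

#' All consensus substitutions relative to the reference genome
#'
#' @param cons a \code{maps_consensus}.
#' @param genome [Biostrings::DNAStringSet].
#' @return data.frame: contig, pos (0-based), ref, alt, depth, fraction.
#' @export
consensus_substitutions <- function(cons, genome) {
  out <- list()
  for (ctg in intersect(unique(cons$contig), names(genome))) {
    rng <- cons[contig == ctg & !is.na(call)]
    if (nrow(rng) == 0L) next
    res <- apply_consensus(genome, cons, ctg, min(rng$pos),
                           max(rng$pos) + 1L)
    out[[ctg]] <- res$substitutions
  }
  if (!length(out))
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), fraction = numeric()))
  do.call(rbind, unname(out))
}

#' Write consensus substitutions as TSV (VCF-lite)
#'
#' Columns: contig, 1-based position, ref, alt, depth, fraction.
#'
#' @param cons a \code{maps_consensus}.
#' @param genome [Biostrings::DNAStringSet].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_substitutions <- function(cons, genome, path) {
  subs <- consensus_substitutions(cons, genome)
  subs$pos <- subs$pos + 1L
  write.table(subs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
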