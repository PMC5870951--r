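## Stage 3: greedy chaining of candidate exons across retained junctions.
## At each step the next endpoint maximizes normalized junction support
## times a distance weight, and the next exon maximizes length-normalized
## read count; a single stringency parameter then trades transcriptome
## size against diversity.

#' Assembly configuration
#'
#' Bundles every tunable of the pipeline with its default. \code{stringency}
#' in [0,1] is the single diversity/size dial: 0 keeps the maximal-diversity
#' transcript set, 1 applies the full expression and similarity filters.
#'
#' @param stringency transcript filter modulation in [0,1] (default 0.3).
#' @param distance_weight endpoint distance weighting: \code{"inverse"}
#'   (proximal preference, default), \code{"linear"} (distal preference:
#'   score proportional to junction distance), or \code{"none"}.
#' @param d0 distance scale in nt for the inverse weight (default 10000).
#' @param branch_cutoff minimum normalized junction support for a secondary
#'   branch (default 0.15); the best endpoint is always followed.
#' @param max_per_seed maximum chains emitted per seed exon (default 16).
#' @param seed_all seed a chain from every exon, not only exons without an
#'   incoming junction (default FALSE).
#' @param expression_threshold_base base expression threshold; NULL means
#'   the median X over all candidate exons, so the modulated threshold
#'   scales with dataset depth.
#' @param min_junction_reads,max_intron,endpoint_window,min_intron see
#'   [filter_junctions()] / [collect_junctions()].
#' @param max_fill_gap see [build_coverage_contigs()].
#' @param min_exon_support,short_single_exon_len,short_single_exon_support,
#'   emit_retained_introns see [make_candidate_exons()].
#' @param min_cov,maj_frac consensus thresholds, see [build_consensus()].
#' @param min_orf_aa,max_ext,six_frame translation options, see
#'   [build_orf_db()].
#' @param strand_mode,drop_multimappers alignment ingestion, see
#'   [read_alignments()].
#' @return a list of class \code{maps_config}.
#' @export
maps_config <- function(stringency = 0.3,
                        distance_weight = c("inverse", "linear", "none"),
                        d0 = 10000, branch_cutoff = 0.15,
                        max_per_seed = 16L, seed_all = FALSE,
                        expression_threshold_base = NULL,
                        min_junction_reads = 2L, max_intron = 1000000L,
                        endpoint_window = 10L, min_intron = 20L,
                        max_fill_gap = 50L, min_exon_support = 1,
                        short_single_exon_len = 1000L,
                        short_single_exon_support = 4L,
                        emit_retained_introns = FALSE,
                        min_cov = 5L, maj_frac = 0.8,
                        min_orf_aa = 8L, max_ext = 10000L,
                        six_frame = FALSE,
                        strand_mode = "firststrand",
                        drop_multimappers = TRUE) {
  stopifnot(stringency >= 0, stringency <= 1)
  cfg <- list(stringency = stringency,
              distance_weight = match.arg(distance_weight), d0 = d0,
              branch_cutoff = branch_cutoff,
              max_per_seed = as.integer(max_per_seed), seed_all = seed_all,
              expression_threshold_base = expression_threshold_base,
              min_junction_reads = as.integer(min_junction_reads),
              max_intron = as.integer(max_intron),
              endpoint_window = as.integer(endpoint_window),
              min_intron = as.integer(min_intron),
              max_fill_gap = as.integer(max_fill_gap),
              min_exon_support = min_exon_support,
              short_single_exon_len = as.integer(short_single_exon_len),
              short_single_exon_support = as.integer(short_single_exon_support),
              emit_retained_introns = emit_retained_introns,
              min_cov = as.integer(min_cov), maj_frac = maj_frac,
              min_orf_aa = as.integer(min_orf_aa),
              max_ext = as.integer(max_ext), six_frame = six_frame,
              strand_mode = strand_mode,
              drop_multimappers = drop_multimappers)
  class(cfg) <- "maps_config"
  cfg
}

#' @export
print.maps_config <- function(x, ...) {
  cat("maps_config:\n")
  for (nm in names(x))
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(x[[nm]])) "NULL (data-derived)" else
                  paste(x[[nm]], collapse = ",")))
  invisible(x)
}

#' Score candidate chain endpoints from an exon
#'
#' For an exon ending at a donor with outgoing junction read counts
#' \code{C} and junction distances \code{D} (acceptor - donor, > 0), the
#' score of each endpoint is its support normalized over all outgoing
#' junctions, \code{C / sum(C)}, multiplied by a distance weight
#' \code{w(D)}: \code{1 / (1 + D/d0)} (proximal preference, default),
#' \code{D} (distal preference), or 1. The chained endpoint is the argmax;
#' ties break on higher normalized support, then higher weight, then
#' leftmost acceptor.
#'
#' @param C integer vector of junction read counts.
#' @param D numeric vector of junction distances (same length).
#' @param distance_weight \code{"inverse"}, \code{"linear"} or \code{"none"}.
#' @param d0 distance scale for the inverse weight.
#' @return data.frame with \code{norm}, \code{w}, \code{score}.
#' @export
endpoint_scores <- function(C, D, distance_weight = "inverse", d0 = 10000) {
  stopifnot(length(C) == length(D), all(D > 0))
  w <- switch(distance_weight,
              inverse = 1 / (1 + D / d0),
              linear = as.numeric(D),
              none = rep(1, length(D)),
              stop("unknown distance_weight: ", distance_weight))
  norm <- C / sum(C)
  data.frame(norm = norm, w = w, score = norm * w)
}

## deterministic ordering of endpoints by (score, norm, w, leftmost)
.endpoint_order <- function(sc, acceptor) {
  order(-sc$score, -sc$norm, -sc$w, acceptor)
}

## best exon among those starting at an endpoint: max X, then longest
.best_exon <- function(idx, exons) {
  idx[order(-exons$X[idx], -exons$end[idx])][1L]
}

#' Assemble transcripts by greedy chain extension
#'
#' Grows an exon chain from each seed exon (exons with no incoming retained
#' junction; all exons with \code{seed_all}). At the current exon the next
#' endpoint is the [endpoint_scores()] argmax over junctions leaving its
#' right boundary, and the next exon is the highest-X candidate starting at
#' that endpoint. Secondary endpoints whose normalized support reaches
#' \code{branch_cutoff} spawn extra chains, up to \code{max_per_seed}
#' complete chains per seed -- the probability-based guard against
#' combinatorial explosion. Chains terminate when no junction leaves the
#' exon or no candidate exon starts at the chosen endpoint. Duplicate
#' chains reached from different seeds are emitted once.
#'
#' @param exons candidate exons from [make_candidate_exons()].
#' @param junctions retained junctions from [filter_junctions()].
#' @param config a [maps_config()] (fields \code{distance_weight},
#'   \code{d0}, \code{branch_cutoff}, \code{max_per_seed},
#'   \code{seed_all} are used).
#' @return a \code{maps_transcripts} whose exon table keeps per-exon
#'   \code{x} and whose transcript table carries \code{mean_x}.
#' @export
assemble_transcripts <- function(exons, junctions, config = maps_config()) {
  if (nrow(exons) == 0L)
    return(maps_transcripts(data.frame(transcript_id = character(),
                                       contig = character(),
                                       strand = character(),
                                       start = integer(), end = integer(),
                                       x = numeric())))
  ## per (contig,strand) lookup tables
  key <- paste(exons$contig, exons$strand)
  jkey <- paste(junctions$contig, junctions$strand)
  ex_by_start <- split(seq_len(nrow(exons)), paste(key, exons$start))
  j_by_donor <- split(seq_len(nrow(junctions)),
                      paste(jkey, junctions$donor_end))
  acceptors <- unique(paste(jkey, junctions$acceptor_start))

  seeds <- if (isTRUE(config$seed_all)) seq_len(nrow(exons)) else
    which(!paste(key, exons$start) %in% acceptors)
  seeds <- seeds[order(exons$contig[seeds], exons$strand[seeds],
                       exons$start[seeds], exons$end[seeds])]

  chains <- new.env(parent = emptyenv())
  chain_list <- list()

  grow <- function(chain, counter) {
    if (counter$n >= config$max_per_seed) return(invisible())
    e <- chain[length(chain)]
    jid <- j_by_donor[[paste(key[e], exons$end[e])]]
    extended <- FALSE
    if (length(jid)) {
      sc <- endpoint_scores(junctions$count[jid],
                            junctions$acceptor_start[jid] -
                              junctions$donor_end[jid],
                            config$distance_weight, config$d0)
      ord <- .endpoint_order(sc, junctions$acceptor_start[jid])
      selected <- ord[c(TRUE, sc$norm[ord[-1L]] >= config$branch_cutoff)]
      for (k in seq_along(selected)) {
        if (counter$n >= config$max_per_seed) break
        p <- junctions$acceptor_start[jid[selected[k]]]
        nxt <- ex_by_start[[paste(key[e], p)]]
        if (is.null(nxt)) next
        grow(c(chain, .best_exon(nxt, exons)), counter)
        extended <- TRUE
      }
    }
    if (!extended && counter$n < config$max_per_seed) {
      counter$n <- counter$n + 1L
      sig <- paste(chain, collapse = ",")
      if (is.null(chains[[sig]])) {
        chains[[sig]] <- TRUE
        chain_list[[length(chain_list) + 1L]] <<- chain
      }
    }
    invisible()
  }

  for (s in seeds) {
    counter <- new.env(parent = emptyenv()); counter$n <- 0L
    grow(s, counter)
  }
  if (!length(chain_list))
    return(maps_transcripts(data.frame(transcript_id = character(),
                                       contig = character(),
                                       strand = character(),
                                       start = integer(), end = integer(),
                                       x = numeric())))
  ## deterministic ids: sort chains by genomic position
  first <- vapply(chain_list, function(ch) exons$start[ch[1L]], integer(1))
  last <- vapply(chain_list, function(ch) exons$end[ch[length(ch)]],
                 integer(1))
  ctg <- vapply(chain_list, function(ch) exons$contig[ch[1L]], character(1))
  str <- vapply(chain_list, function(ch) exons$strand[ch[1L]], character(1))
  ord <- order(ctg, first, last, str,
               vapply(chain_list, length, integer(1)))
  chain_list <- chain_list[ord]
  ex_rows <- do.call(rbind, lapply(seq_along(chain_list), function(i) {
    ch <- chain_list[[i]]
    data.frame(transcript_id = sprintf("MAPS.%d", i),
               contig = exons$contig[ch], strand = exons$strand[ch],
               start = exons$start[ch], end = exons$end[ch],
               x = exons$X[ch], stringsAsFactors = FALSE)
  }))
  maps_transcripts(ex_rows)
}

## internal junction chain of one transcript, as "donor:acceptor" strings
.junction_chain <- function(starts, ends) {
  if (length(starts) < 2L) return(character(0))
  paste(ends[-length(ends)], starts[-1L], sep = ":")
}

#' Filter assembled transcripts at a given stringency
#'
#' Realizes the tunable size/diversity trade-off. Transcripts are walked in
#' order of decreasing exon count; a transcript is dropped when (a) its mean
#' exon expression falls below \code{stringency * expression_threshold_base},
#' or (b) its internal junction chain is a subset of an already-accepted
#' transcript's chain and its mean expression is below \code{stringency}
#' times that transcript's (similar internal structure needs
#' proportionally strong support to stay). Junction-less (single-exon)
#' transcripts have no internal structure and are never dropped as similar.
#' At stringency 0 the input passes unchanged.
#'
#' @param tx a \code{maps_transcripts} from [assemble_transcripts()].
#' @param stringency value in [0,1].
#' @param expression_threshold_base base threshold; NULL uses the median
#'   per-exon X of \code{tx}.
#' @return filtered \code{maps_transcripts}, deterministically ordered.
#' @export
filter_transcripts <- function(tx, stringency = 0.3,
                               expression_threshold_base = NULL) {
  stopifnot(inherits(tx, "maps_transcripts"),
            stringency >= 0, stringency <= 1)
  t <- tx$transcripts
  if (nrow(t) == 0L) return(tx)
  if (is.null(expression_threshold_base))
    expression_threshold_base <- median(tx$exons$x)
  exo <- tx$exons[order(tx$exons$transcript_id, tx$exons$start), ,
                  drop = FALSE]
  ex_by_tx <- split(exo, exo$transcript_id)
  chains <- lapply(ex_by_tx, function(e) .junction_chain(e$start, e$end))
  chains <- chains[t$transcript_id]
  first_start <- vapply(ex_by_tx, function(e) min(e$start),
                        integer(1))[t$transcript_id]
  ord <- order(-t$n_exons, -t$mean_x, t$contig, first_start,
               t$transcript_id)
  accepted <- integer(0)
  for (i in ord) {
    if (t$mean_x[i] < stringency * expression_threshold_base) next
    similar_drop <- FALSE
    ch <- chains[[i]]
    if (length(ch)) {
      for (a in accepted) {
        if (t$contig[a] == t$contig[i] && t$strand[a] == t$strand[i] &&
            all(ch %in% chains[[a]]) &&
            t$mean_x[i] < t$mean_x[a] * stringency) {
          similar_drop <- TRUE
          break
        }
      }
    }
    if (!similar_drop) accepted <- c(accepted, i)
  }
  keep_ids <- t$transcript_id[sort(accepted)]
  out <- maps_transcripts(
    tx$exons[tx$exons$transcript_id %in% keep_ids, , drop = FALSE],
    source = tx$source)
  out
}
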