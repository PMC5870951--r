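## Orchestration: alignment ingestion -> consensus -> junction/exon graph
## -> greedy assembly -> stringency filtering -> translation -> annotation
## -> evaluation, with a manifest so identical inputs give identical bytes.

#' Run the full assembly-to-proteome pipeline
#'
#' Chains every stage and writes the output bundle into \code{out_dir}:
#' \code{transcripts.gtf}, \code{junctions.bed}, \code{substitutions.tsv},
#' \code{proteins.fasta}, \code{orfs.tsv}, plus \code{smorf_report.tsv}
#' when peptides (and a proteome) are given and \code{evaluation.json} /
#' \code{evaluation_matches.tsv} when a reference annotation is given.
#' \code{manifest.json} records input checksums, the full configuration
#' and the package version; \code{maps.log} records per-stage tallies.
#' Rerunning on identical inputs and configuration is byte-identical.
#'
#' @param genome genome FASTA path or [Biostrings::DNAStringSet].
#' @param alignments SAM/BAM path or a \code{maps_alignments}.
#' @param out_dir output directory (created if needed).
#' @param config a [maps_config()].
#' @param reference_gtf optional reference annotation (path or
#'   \code{maps_transcripts}) for evaluation.
#' @param proteome optional reference proteome (path or AAStringSet) for
#'   peptide annotation.
#' @param peptides optional peptide list (path or character vector).
#' @param use_consensus build the protein database from the read consensus
#'   (default TRUE); FALSE gives the reference-genome-only database.
#' @return invisibly, a list with every intermediate object
#'   (\code{alignments}, \code{consensus}, \code{junctions}, \code{exons},
#'   \code{transcripts}, \code{orfs}, \code{report}, \code{evaluation},
#'   \code{paths}).
#' @export
run_maps <- function(genome, alignments, out_dir, config = maps_config(),
                     reference_gtf = NULL, proteome = NULL, peptides = NULL,
                     use_consensus = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message("[mapsr] ", msg)
  }
  input_paths <- list()
  if (is.character(genome)) {
    input_paths$genome <- genome
    genome <- read_genome(genome)
  }
  if (is.character(alignments)) {
    input_paths$alignments <- alignments
    alignments <- read_alignments(alignments, genome = genome,
                                  drop_multimappers = config$drop_multimappers,
                                  strand_mode = config$strand_mode)
  }
  say("loaded %d reads (%d blocks), dropped %d multimappers",
      nrow(alignments$reads), nrow(alignments$blocks),
      alignments$n_multimappers)

  cons <- build_consensus(alignments, min_cov = config$min_cov,
                          maj_frac = config$maj_frac)
  say("consensus over %d covered positions, %d called", nrow(cons),
      sum(!is.na(cons$call)))

  jx <- collect_junctions(alignments, min_intron = config$min_intron)
  jxf <- filter_junctions(jx, min_junction_reads = config$min_junction_reads,
                          max_intron = config$max_intron,
                          endpoint_window = config$endpoint_window)
  say("junctions: %d observed, %d retained", nrow(jx), nrow(jxf))
  contigs <- build_coverage_contigs(alignments,
                                    max_fill_gap = config$max_fill_gap)
  exons <- make_candidate_exons(
    contigs, jxf, alignments,
    min_exon_support = config$min_exon_support,
    short_single_exon_len = config$short_single_exon_len,
    short_single_exon_support = config$short_single_exon_support,
    emit_retained_introns = config$emit_retained_introns)
  say("%d coverage contigs -> %d candidate exons", nrow(contigs),
      nrow(exons))

  asm <- assemble_transcripts(exons, jxf, config)
  base <- config$expression_threshold_base %||%
    (if (nrow(exons)) median(exons$X) else 0)
  tx <- filter_transcripts(asm, stringency = config$stringency,
                           expression_threshold_base = base)
  say("assembled %d chains, %d transcripts at stringency %.2f",
      nrow(asm$transcripts), nrow(tx$transcripts), config$stringency)

  paths <- list(gtf = file.path(out_dir, "transcripts.gtf"),
                bed = file.path(out_dir, "junctions.bed"),
                subs = file.path(out_dir, "substitutions.tsv"),
                proteins = file.path(out_dir, "proteins.fasta"),
                orfs = file.path(out_dir, "orfs.tsv"))
  write_gtf(tx, paths$gtf)
  write_junction_bed(jxf, paths$bed)
  write_substitutions(cons, genome, paths$subs)

  orfs <- build_orf_db(tx, genome, cons = if (use_consensus) cons else NULL,
                       min_orf_aa = config$min_orf_aa,
                       max_ext = config$max_ext,
                       six_frame = config$six_frame)
  say("ORF database: %d records (%d consensus-altered)", nrow(orfs),
      sum(orfs$snp_count > 0L))
  write_protein_fasta(orfs, paths$proteins)
  write_orf_tsv(orfs, paths$orfs)

  report <- NULL
  if (!is.null(peptides)) {
    if (is.character(peptides) && length(peptides) == 1L &&
        file.exists(peptides)) {
      input_paths$peptides <- peptides
      peptides <- read_peptides(peptides)
    }
    if (!is.null(proteome) && is.character(proteome)) {
      input_paths$proteome <- proteome
      proteome <- read_proteome(proteome)
    }
    report <- annotate_peptides(peptides, orfs, proteome = proteome)
    paths$report <- file.path(out_dir, "smorf_report.tsv")
    write_smorf_report(report, paths$report)
    say("annotated %d peptides: %s", nrow(report),
        paste(sprintf("%d %s", table(report$status),
                      names(table(report$status))), collapse = ", "))
  }

  ev <- NULL
  if (!is.null(reference_gtf)) {
    ref <- reference_gtf
    if (is.character(ref)) {
      input_paths$reference_gtf <- ref
      ref <- read_gtf(ref)
    }
    ev <- evaluate_assembly(tx, ref)
    paths$eval <- file.path(out_dir, "evaluation.json")
    write_eval_json(ev, paths$eval,
                    file.path(out_dir, "evaluation_matches.tsv"))
    say("evaluation: recall %.3f, precision %.3f", ev$recall, ev$precision)
  }

  manifest <- list(
    tool = "mapsr", version = as.character(packageVersion("mapsr")),
    inputs = lapply(input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    config = config[order(names(config))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "maps.log"))

  invisible(list(alignments = alignments, consensus = cons,
                 junctions = jxf, contigs = contigs, exons = exons,
                 assembled = asm, transcripts = tx, orfs = orfs,
                 report = report, evaluation = ev, paths = paths))
}
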