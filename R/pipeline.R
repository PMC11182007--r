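# End-to-end pipeline: scan -> curate -> fold-verify -> mutate-propose,
# with a deterministic report bundle.

#' Pipeline configuration
#'
#' @param descriptor path to a descriptor file.
#' @param fasta path(s) to FASTA genome file(s).
#' @param gff optional GFF3 annotation path.
#' @param filter a [filter_config()].
#' @param fold a [fold_config()].
#' @param scan a [scan_config()].
#' @param out_dir output directory.
#' @param seed seed recorded in the run log (the discovery stages are
#'   deterministic; the seed matters for simulation subcommands).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(descriptor, fasta, gff = NULL,
                            filter = filter_config(), fold = fold_config(),
                            scan = scan_config(), out_dir = ".", seed = 1L) {
  structure(list(descriptor = descriptor, fasta = fasta, gff = gff,
                 filter = filter, fold = fold, scan = scan,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    ts_error("stage", sprintf("[%s] %s", name, conditionMessage(e)))
  })
}

#' Run the discovery pipeline
#'
#' Executes scan, curation, fold verification and mutation proposal over
#' every FASTA record, then writes `matches.tsv`, `matches.bed`,
#' `candidates.tsv`, `candidates.json`, `mutations.tsv` and `run_log.txt`
#' (which echoes the verbatim descriptor, package version, seed and
#' parameters, so a published search is reproducible from its log).
#' Reports are byte-identical across repeated runs on equal inputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with `matches`, `candidates` (per record),
#'   `mutations`, and the output paths.
#' @export
run_pipeline <- function(cfg) {
  if (!file.exists(cfg$descriptor))
    ts_error("stage", sprintf("[config] descriptor file not found: %s",
                              cfg$descriptor))
  for (f in cfg$fasta)
    if (!file.exists(f))
      ts_error("stage", sprintf("[config] FASTA file not found: %s", f))
  if (!is.null(cfg$gff) && !file.exists(cfg$gff))
    ts_error("stage", sprintf("[config] GFF3 file not found: %s", cfg$gff))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  desc_text <- paste(readLines(cfg$descriptor, warn = FALSE), collapse = "\n")
  d <- stage("parse", parse_descriptor(desc_text))
  ann <- if (!is.null(cfg$gff)) stage("annotations", read_gff3(cfg$gff)) else NULL

  all_matches <- list()
  all_cands <- list()
  for (f in cfg$fasta) {
    seqs <- stage("fasta", read_fasta(f))
    for (id in names(seqs)) {
      m <- stage("scan", scan_sequence(seqs[[id]], d, cfg$scan, sequence_id = id))
      all_matches <- c(all_matches, m)
      cands <- stage("curate",
                     filter_and_rank(m, d, annotations = ann,
                                     cfg = cfg$filter, seq = seqs[[id]],
                                     fold_cfg = cfg$fold))
      all_cands <- c(all_cands, cands)
    }
  }
  all_matches <- structure(all_matches, class = "motif_matches")
  all_cands <- structure(all_cands, class = "thermometer_candidates")

  mut_rows <- list()
  for (c in all_cands) {
    if (!c$all_pass) next
    for (p in stage("mutate", propose_stabilizing_mutations(c, cfg$fold))) {
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        sequence_id = c$match$sequence_id, strand = c$match$strand,
        match_start = c$match$start, name = p$name,
        positions = paste(p$positions, collapse = ","),
        delta_stability = p$delta_stability, stringsAsFactors = FALSE)
    }
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(sequence_id = character(0), strand = character(0),
               match_start = integer(0), name = character(0),
               positions = character(0), delta_stability = numeric(0))

  paths <- list(
    matches_tsv = file.path(cfg$out_dir, "matches.tsv"),
    matches_bed = file.path(cfg$out_dir, "matches.bed"),
    candidates_tsv = file.path(cfg$out_dir, "candidates.tsv"),
    candidates_json = file.path(cfg$out_dir, "candidates.json"),
    mutations_tsv = file.path(cfg$out_dir, "mutations.tsv"),
    log = file.path(cfg$out_dir, "run_log.txt"))
  stage("report", {
    write_matches_tsv(all_matches, paths$matches_tsv)
    write_matches_bed(all_matches, paths$matches_bed)
    write_candidates(all_cands, paths$candidates_tsv, paths$candidates_json)
    utils::write.table(mutations, paths$mutations_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(c(
      sprintf("thermoscan %s",
              as.character(utils::packageVersion("thermoscan"))),
      sprintf("seed: %s", cfg$seed),
      sprintf("strand_mode: %s", cfg$scan$strand_mode),
      sprintf("sd window: %d-%d (%s)", cfg$filter$sd_spacing_min,
              cfg$filter$sd_spacing_max, cfg$filter$spacing_convention),
      sprintf("min wobble: %d; fourU run: %d", cfg$filter$min_wobble_pairs,
              cfg$filter$fourU_run_min),
      sprintf("matches: %d; candidates: %d (passing %d)",
              length(all_matches), length(all_cands),
              sum(vapply(all_cands, `[[`, logical(1), "all_pass"))),
      "descriptor:",
      desc_text), paths$log)
  })
  invisible(list(matches = all_matches, candidates = all_cands,
                 mutations = mutations, paths = paths))
}
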