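# File-format adapters: FASTA (via Biostrings), a GFF3 subset, match and
# candidate reports (TSV / BED6 / JSON), assay CSV.
#
# Conventions: internal coordinates are 0-based half-open; TSV reports are
# 1-based inclusive (stated in a header comment); BED is 0-based half-open.

#' Read a FASTA file
#'
#' Multi-record, wrapped lines, case-insensitive; sequences are normalized
#' to the RNA alphabet (T -> U) and IUPAC ambiguity codes are preserved.
#' Whether a record contained T (i.e. was DNA) is recorded in the
#' `was_dna` attribute.
#'
#' @param path FASTA file path.
#' @return named character vector of RNA sequences, with attribute
#'   `was_dna` (logical vector).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    ts_error("fasta_missing", sprintf("no such file: %s", path))
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0L || all(!nzchar(trimws(raw))))
    ts_error("fasta_empty", sprintf("empty FASTA file: %s", path))
  first <- raw[nzchar(trimws(raw))][1]
  if (!startsWith(first, ">"))
    ts_error("fasta_malformed", sprintf("not a FASTA file (no '>'): %s", path))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  was_dna <- grepl("T", seqs, fixed = TRUE)
  seqs <- vapply(seqs, function(s) normalize_seq(s, "FASTA record"),
                 character(1))
  attr(seqs, "was_dna") <- was_dna
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a GFF3 subset
#'
#' Reads `gene`/`CDS` features from a GFF3 file, keeping seqid, span,
#' strand and the `ID` and `product` attributes. Coordinates are converted
#' to 0-based half-open.
#'
#' @param path GFF3 file path.
#' @param types feature types to keep (default `c("gene", "CDS")`).
#' @return data.frame with `sequence_id`, `start`, `end`, `strand`,
#'   `gene_id`, `product`, `type`.
#' @export
read_gff3 <- function(path, types = c("gene", "CDS")) {
  if (!file.exists(path))
    ts_error("gff_missing", sprintf("no such file: %s", path))
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (length(raw) == 0L)
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0), product = character(0),
                      type = character(0)))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L)
    ts_error("gff_malformed",
             sprintf("GFF3 line %d does not have 9 tab-separated columns", bad[1]))
  tab <- do.call(rbind, fields)
  keep <- tab[, 3] %in% types
  tab <- tab[keep, , drop = FALSE]
  attr_of <- function(s, key) {
    m <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([^;]*)"), s))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  data.frame(sequence_id = tab[, 1],
             start = as.integer(tab[, 4]) - 1L,
             end = as.integer(tab[, 5]),
             strand = tab[, 7],
             gene_id = attr_of(tab[, 9], "ID"),
             product = attr_of(tab[, 9], "product"),
             type = tab[, 3],
             stringsAsFactors = FALSE)
}

#' Write annotations as GFF3
#'
#' @param ann annotation data.frame (0-based half-open `start`/`end`).
#' @param path output path.
#' @param type feature type to write (default `"CDS"`).
#' @export
write_gff3 <- function(ann, path, type = "CDS") {
  lines <- "##gff-version 3"
  if (nrow(ann) > 0L)
    lines <- c(lines, sprintf("%s\tthermoscan\t%s\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
                              ann$sequence_id, type, ann$start + 1L, ann$end,
                              ann$strand, ann$gene_id, ann$product))
  writeLines(lines, path)
  invisible(path)
}

#' Write a match report TSV (1-based inclusive coordinates)
#'
#' @param matches a `motif_matches` list.
#' @param path output path.
#' @export
write_matches_tsv <- function(matches, path) {
  df <- as.data.frame(matches)
  if (nrow(df) > 0L) df$start <- df$start + 1L  # 1-based inclusive
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# thermoscan match report; coordinates are 1-based inclusive", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write matches as BED6 (0-based half-open)
#'
#' @param matches a `motif_matches` list.
#' @param path output path.
#' @export
write_matches_bed <- function(matches, path) {
  if (length(matches) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- vapply(seq_along(matches), function(i) {
    m <- matches[[i]]
    sprintf("%s\t%d\t%d\tmatch%04d\t%d\t%s", m$sequence_id, m$start, m$end,
            i, m$score, m$strand)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write candidate reports (TSV + JSON)
#'
#' The TSV is 1-based inclusive; the JSON carries one record per candidate
#' with all spans and flags (0-based half-open, as internally).
#'
#' @param cands a `thermometer_candidates` list.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_candidates <- function(cands, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- as.data.frame(cands)
    if (nrow(df) > 0L && "start" %in% names(df)) {
      df$start <- df$start + 1L
      df$sd_start <- df$sd_start + 1L
      df$start_codon_pos <- df$start_codon_pos + 1L
    }
    con <- file(tsv_path, "w")
    writeLines("# thermoscan candidate report; coordinates are 1-based inclusive",
               con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    recs <- lapply(cands, function(c) list(
      sequence_id = c$match$sequence_id, strand = c$match$strand,
      start = c$match$start, end = c$match$end, rank = c$rank,
      all_pass = c$all_pass, flags = as.list(c$flags),
      sd = c$sd_span, start_codon_pos = c$start_codon_pos,
      sd_spacing = c$sd_spacing, wobble_count = c$wobble_count,
      hairpin_support = c$hairpin_support,
      gene_id = c$gene_id, gene_distance = c$gene_distance,
      orf_codons = c$orf_codons,
      spans = c$match$spans))
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  }
  invisible(NULL)
}

#' Read the assay CSV schema
#'
#' Columns: `construct_id,temperature_C,replicate,A420,A550,OD600,time_min,volume_mL`
#' (header required; `A550` optional).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path))
    ts_error("assay_missing", sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "temperature_C", "replicate", "A420", "OD600",
            "time_min", "volume_mL")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    ts_error("assay_malformed",
             sprintf("assay CSV lacks column(s): %s",
                     paste(missing, collapse = ", ")))
  df
}

#' Write simulated fixtures to a directory
#'
#' Emits `genome.fasta`, `annotations.gff3`, `truth.tsv` and, when given,
#' `assay.csv`.
#'
#' @param gen a [generate_genome()] result.
#' @param dir output directory (created if needed).
#' @param assay optional [simulate_assay()] data.frame.
#' @return the directory, invisibly.
#' @export
write_simdata <- function(gen, dir, assay = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(gen$sequence, file.path(dir, "genome.fasta"))
  write_gff3(gen$annotations, file.path(dir, "annotations.gff3"))
  utils::write.table(gen$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(assay))
    utils::write.csv(assay, file.path(dir, "assay.csv"), row.names = FALSE)
  invisible(dir)
}
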