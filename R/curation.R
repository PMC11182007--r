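# Candidate curation: Shine-Dalgarno / start-codon location, fourU and
# wobble rules, SD-AUG spacing, gene-annotation linkage, ranking.

#' Curation filter configuration
#'
#' Defaults encode the fourU thermometer motif rules: the predicted SD
#' should sit 5-10 nt upstream of the start codon, the terminal hairpin
#' should pair a run of >= 4 consecutive U residues with the SD, and that
#' duplex should contain >= 2 G:U wobble pairs.
#'
#' @param sd_spacing_min,sd_spacing_max allowed SD-to-start-codon distance
#'   window in nt (defaults 5 and 10).
#' @param min_wobble_pairs minimum G:U wobble pairs in the fourU/SD duplex
#'   (default 2).
#' @param fourU_run_min minimum consecutive-U run length (default 4).
#' @param annotation_mode `"annotated"` links candidates to provided gene
#'   annotations; `"orf_free"` instead requires an open reading frame of at
#'   least `min_orf_codons` codons starting at the match's AUG.
#' @param min_orf_codons ORF length threshold for `orf_free` mode
#'   (default 50).
#' @param spacing_convention how SD-AUG distance is measured:
#'   `"from_sd_end"` (default) counts the nucleotides strictly between the
#'   last SD base and the A of AUG -- the measure whose 7-10 nt range under
#'   the shipped descriptor geometry sits inside the canonical 5-10 nt
#'   ribosome-initiation window; `"from_sd_start"` counts from the first
#'   SD base instead.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(sd_spacing_min = 5L, sd_spacing_max = 10L,
                          min_wobble_pairs = 2L, fourU_run_min = 4L,
                          annotation_mode = c("annotated", "orf_free"),
                          min_orf_codons = 50L,
                          spacing_convention = c("from_sd_end",
                                                 "from_sd_start")) {
  if (sd_spacing_min < 0L || sd_spacing_min > sd_spacing_max)
    ts_error("bad_config", "need 0 <= sd_spacing_min <= sd_spacing_max")
  structure(list(sd_spacing_min = sd_spacing_min,
                 sd_spacing_max = sd_spacing_max,
                 min_wobble_pairs = min_wobble_pairs,
                 fourU_run_min = fourU_run_min,
                 annotation_mode = match.arg(annotation_mode),
                 min_orf_codons = min_orf_codons,
                 spacing_convention = match.arg(spacing_convention)),
            class = "filter_config")
}

# maximal fixed-literal runs of a pattern: data.frame(start, len, string)
literal_runs <- function(pat) {
  is_lit <- !pat$optional & pat$symbols != "N"
  if (!any(is_lit))
    return(data.frame(start = integer(0), len = integer(0),
                      string = character(0)))
  r <- rle(is_lit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], len = r$lengths[keep],
             string = vapply(keep, function(j)
               paste(pat$symbols[starts[j]:ends[j]], collapse = ""),
               character(1)),
             stringsAsFactors = FALSE)
}

# offset (0-based, within the realized strand) of pattern position `ppos`
# for the first optional-subset layout consistent with `realized`
layout_offset <- function(realized, pat, ppos, mm = 0L) {
  seg <- strsplit(realized, "", fixed = TRUE)[[1]]
  need <- length(seg) - sum(!pat$optional)
  opt_idx <- which(pat$optional)
  for (sub in subsets_of_size(length(opt_idx), need)) {
    keep <- !pat$optional
    keep[opt_idx[sub]] <- TRUE
    sym <- pat$symbols[keep]
    if (sum(!symbol_matches(seg, sym)) <= mm)
      return(sum(keep[seq_len(ppos - 1L)]))
  }
  NA_integer_
}

# identify the SD-carrying helix and the AUG anchor of a descriptor;
# errors with thermoscan_not_sd_anchored when absent
sd_anchor_info <- function(d) {
  helices <- Filter(function(e) e$kind == "helix", d$elements)
  best <- NULL
  for (e in helices) {
    runs <- literal_runs(e$pattern3)
    if (nrow(runs) == 0L) next
    j <- which.max(runs$len)
    if (is.null(best) || runs$len[j] > best$run_len)
      best <- list(helix = e$name, run_start = runs$start[j],
                   run_len = runs$len[j], sd = runs$string[j])
  }
  if (is.null(best))
    ts_error("not_sd_anchored",
             "descriptor has no helix with a literal SD block on its 3' strand")
  last_id <- d$map_order$id[nrow(d$map_order)]
  last <- d$elements[[last_id]]
  aug <- NULL
  if (last$kind == "ss") {
    runs <- literal_runs(last$pattern)
    for (j in seq_len(nrow(runs))) {
      at <- regexpr("AUG", runs$string[j], fixed = TRUE)
      if (at > 0L)
        aug <- list(element = last_id, ppos = runs$start[j] + at - 1L)
    }
  }
  if (is.null(aug))
    ts_error("not_sd_anchored",
             "descriptor's final element does not anchor an AUG start codon")
  c(best, aug_element = aug$element, aug_ppos = aug$ppos)
}

#' Locate the Shine-Dalgarno block and start codon within a match
#'
#' The SD is the maximal contiguous literal block in the descriptor's
#' SD-helix 3' pattern (e.g. `AGGAG`); the start codon is the `AUG`
#' anchored by the final single-strand element. Both are resolved to
#' positions in the scanned-strand coordinates of the match.
#'
#' @param m a `motif_match`.
#' @param d the descriptor the match came from.
#' @return list with `sd_span` (list `start`, `end` 0-based half-open,
#'   `realized`), `start_codon_pos` (0-based position of the A of AUG),
#'   `sd_helix` (element id), and `sd_offset3` (0-based offset of the SD
#'   within the realized helix 3' strand).
#' @export
locate_sd_and_start <- function(m, d) {
  info <- sd_anchor_info(d)
  rows <- d$map_order
  k3 <- which(rows$id == info$helix & rows$strand == 2L)
  e_h <- d$elements[[info$helix]]
  off3 <- layout_offset(m$spans$realized[k3], e_h$pattern3, info$run_start)
  if (is.na(off3))
    ts_error("bad_match", "helix 3' strand realization inconsistent with pattern")
  sd_start <- m$spans$start[k3] + off3
  sd_span <- list(start = sd_start, end = sd_start + info$run_len,
                  realized = substr(m$spans$realized[k3], off3 + 1L,
                                    off3 + info$run_len))
  k5s <- which(rows$id == info$aug_element)
  e_s <- d$elements[[info$aug_element]]
  offA <- layout_offset(m$spans$realized[k5s], e_s$pattern, info$aug_ppos,
                        mm = e_s$max_mismatches)
  if (is.na(offA))
    ts_error("bad_match", "final element realization inconsistent with pattern")
  list(sd_span = sd_span,
       start_codon_pos = m$spans$start[k5s] + offA,
       sd_helix = info$helix, sd_offset3 = off3)
}

#' Check the fourU / wobble rule on a candidate duplex
#'
#' Passes iff the realized SD-helix 5' strand contains a run of at least
#' `cfg$fourU_run_min` consecutive U residues whose antiparallel partners
#' overlap the SD block, and the helix pairs within the U-run plus
#' SD-paired region include at least `cfg$min_wobble_pairs` G:U wobble
#' pairs. With `fourU_run_min = 0` the run requirement is vacuous.
#'
#' @param c a candidate (or any list) with fields `strand5`, `strand3`
#'   (realized SD-helix strands, sequence order) and `sd_span3` (1-based
#'   inclusive range of the SD within `strand3`).
#' @param rules a [pairing_rules()] object.
#' @param cfg a [filter_config()].
#' @return list: `pass` (logical), `fourU_range5` (1-based inclusive range
#'   of the qualifying U run within `strand5`, or `NULL`), `wobble_count`,
#'   `reasons` (character, empty when passing).
#' @export
check_fourU <- function(c, rules = pairing_rules(), cfg = filter_config()) {
  pr <- helix_pairs(c$strand5, c$strand3)
  L <- nrow(pr)
  sd3 <- c$sd_span3
  # strand5 positions whose partner lies in the SD block
  sd_partner5 <- pr$pos5[pr$pos3 >= sd3[1] & pr$pos3 <= sd3[2]]
  run_range <- NULL
  if (cfg$fourU_run_min > 0L) {
    isU <- pr$base5 == "U"
    r <- rle(isU)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= cfg$fourU_run_min)) {
      if (any(seq(starts[j], ends[j]) %in% sd_partner5)) {
        run_range <- c(starts[j], ends[j])
        break
      }
    }
  }
  region <- sort(unique(c(if (!is.null(run_range)) seq(run_range[1], run_range[2]),
                          sd_partner5)))
  wobble_count <- sum(pr$class[region] == "wobble")
  reasons <- character(0)
  if (cfg$fourU_run_min > 0L && is.null(run_range))
    reasons <- c(reasons, sprintf("no U-run of length >= %d pairing into the SD",
                                  cfg$fourU_run_min))
  if (wobble_count < cfg$min_wobble_pairs)
    reasons <- c(reasons, sprintf("wobble pairs %d < %d", wobble_count,
                                  cfg$min_wobble_pairs))
  list(pass = length(reasons) == 0L, fourU_range5 = run_range,
       wobble_count = wobble_count, reasons = reasons)
}

#' SD-AUG spacing test
#'
#' @param c a candidate with fields `sd_spacing` (nt strictly between the
#'   SD 3' end and the A of AUG) and `sd_len` (SD block length).
#' @param cfg a [filter_config()]; `spacing_convention` selects the
#'   measure, the `sd_spacing_min`/`sd_spacing_max` window bounds it.
#' @return logical.
#' @export
sd_spacing_ok <- function(c, cfg = filter_config()) {
  measure <- spacing_measure(c, cfg)
  measure >= cfg$sd_spacing_min && measure <= cfg$sd_spacing_max
}

spacing_measure <- function(c, cfg) {
  switch(cfg$spacing_convention,
         from_sd_end = c$sd_spacing,
         from_sd_start = c$sd_spacing + c$sd_len)
}

#' Link a match to the nearest downstream annotated gene
#'
#' In `annotated` mode, returns the gene whose annotated start coincides
#' with the match's AUG (distance 0), else the nearest same-strand gene
#' start downstream of the AUG with its signed distance; `NULL` when no
#' such gene exists. In `orf_free` mode the annotation table is ignored and
#' an open reading frame of at least `cfg$min_orf_codons` codons starting
#' at the AUG is required instead.
#'
#' @param m a `motif_match`.
#' @param annotations data.frame with columns `sequence_id`, `start`,
#'   `end` (0-based half-open), `strand`, `gene_id`, `product`.
#' @param start_codon_pos AUG position in scanned-strand coordinates (from
#'   [locate_sd_and_start()]).
#' @param seq the scanned sequence (forward orientation); required for
#'   `orf_free` mode.
#' @param cfg a [filter_config()].
#' @return list with `gene_id`, `product`, `distance` (nt from AUG to the
#'   annotated start, 0 = exact), `orf_codons` (orf_free mode), and `pass`.
#' @export
attach_annotation <- function(m, annotations, start_codon_pos, seq = NULL,
                              cfg = filter_config()) {
  L <- if (!is.null(seq)) nchar(seq) else NA_integer_
  aug_fwd <- if (m$strand == "+") start_codon_pos else L - 1L - start_codon_pos

  if (cfg$annotation_mode == "orf_free") {
    if (is.null(seq))
      ts_error("bad_config", "orf_free mode requires the sequence")
    scanned <- if (m$strand == "+") normalize_seq(seq) else
      revcomp(normalize_seq(seq))
    n_codons <- orf_codons_from(scanned, start_codon_pos)
    return(list(gene_id = NA_character_, product = NA_character_,
                distance = NA_integer_, orf_codons = n_codons,
                pass = n_codons >= cfg$min_orf_codons))
  }

  empty <- list(gene_id = NA_character_, product = NA_character_,
                distance = NA_integer_, orf_codons = NA_integer_,
                pass = FALSE)
  if (is.null(annotations) || nrow(annotations) == 0L) return(empty)
  ann <- annotations[annotations$sequence_id == m$sequence_id &
                       annotations$strand == m$strand, , drop = FALSE]
  if (nrow(ann) == 0L) return(empty)
  if (m$strand == "+") {
    gene_start <- ann$start
    dist <- gene_start - aug_fwd
  } else {
    if (is.na(aug_fwd))
      ts_error("bad_config", "minus-strand annotation linkage requires the sequence")
    gene_start <- ann$end - 1L       # 5' end of a minus-strand gene
    dist <- aug_fwd - gene_start
  }
  ok <- which(dist >= 0L)
  if (length(ok) == 0L) return(empty)
  j <- ok[which.min(dist[ok])]
  list(gene_id = ann$gene_id[j], product = ann$product[j],
       distance = as.integer(dist[j]), orf_codons = NA_integer_, pass = TRUE)
}

STOP_CODONS <- c("UAA", "UAG", "UGA")

# codons from `pos0` (0-based, scanned orientation) until the first stop
orf_codons_from <- function(scanned, pos0) {
  chars <- strsplit(scanned, "", fixed = TRUE)[[1]]
  n <- 0L
  i <- pos0 + 1L
  while (i + 2L <= length(chars)) {
    codon <- paste(chars[i:(i + 2L)], collapse = "")
    if (codon %in% STOP_CODONS) break
    n <- n + 1L
    i <- i + 3L
  }
  n
}

#' Filter matches into ranked thermometer candidates
#'
#' Applies the curation rules to every match: SD anchoring, the fourU/
#' wobble duplex rule, SD-AUG spacing, and gene linkage (or ORF presence).
#' Candidates failing any hard rule are retained with fail flags but sort
#' after all passers. The rank key is (all rules passed, gene distance
#' ascending, hairpin support descending, wobble count descending, start
#' ascending), with the span tuple as final tiebreak for a deterministic
#' total order. Hairpin support is the fraction of descriptor-implied
#' SD-helix pairs recovered by the weighted Nussinov fold of the matched
#' region.
#'
#' @param matches a `motif_matches` list from [scan_sequence()].
#' @param d the descriptor.
#' @param annotations optional gene annotation data.frame (see
#'   [attach_annotation()]).
#' @param cfg a [filter_config()].
#' @param seq the scanned sequence; required for `orf_free` mode and for
#'   minus-strand annotation linkage.
#' @param fold_cfg a [fold_config()] used for hairpin support.
#' @return an object of class `thermometer_candidates` (ordered list of
#'   candidate records; see [as.data.frame.thermometer_candidates()]).
#' @export
filter_and_rank <- function(matches, d, annotations = NULL,
                            cfg = filter_config(), seq = NULL,
                            fold_cfg = fold_config()) {
  sd_anchor_info(d)  # errors early if the descriptor is not SD-anchored
  cands <- lapply(matches, function(m)
    build_candidate(m, d, annotations, cfg, seq, fold_cfg))
  if (length(cands) == 0L)
    return(structure(list(), class = "thermometer_candidates"))
  key <- vapply(cands, function(c) {
    paste(if (c$all_pass) "0" else "1",
          formatC(if (is.na(c$gene_distance)) 999999L else c$gene_distance,
                  width = 7, flag = "0"),
          formatC(round((1 - c$hairpin_support) * 1e6), width = 7, flag = "0"),
          formatC(999L - c$wobble_count, width = 4, flag = "0"),
          formatC(c$match$start, width = 10, flag = "0"),
          paste(formatC(c$match$spans$end - c$match$spans$start,
                        width = 5, flag = "0"), collapse = ","),
          if (c$match$strand == "+") "0" else "1",
          sep = "|")
  }, character(1))
  cands <- cands[order(key)]
  for (i in seq_along(cands)) cands[[i]]$rank <- i
  structure(cands, class = "thermometer_candidates")
}

build_candidate <- function(m, d, annotations, cfg, seq, fold_cfg) {
  loc <- locate_sd_and_start(m, d)
  rows <- d$map_order
  k5 <- which(rows$id == loc$sd_helix & rows$strand == 1L)
  k3 <- which(rows$id == loc$sd_helix & rows$strand == 2L)
  strand5 <- m$spans$realized[k5]
  strand3 <- m$spans$realized[k3]
  sd_in3 <- c(loc$sd_offset3 + 1L,
              loc$sd_offset3 + (loc$sd_span$end - loc$sd_span$start))
  cand <- list(match = m,
               region = paste(m$spans$realized, collapse = ""),
               region_offset = m$spans$start[1],
               strand5 = strand5, strand3 = strand3, sd_span3 = sd_in3,
               h5_start = m$spans$start[k5], h3_start = m$spans$start[k3],
               sd_span = loc$sd_span,
               start_codon_pos = loc$start_codon_pos,
               sd_helix = loc$sd_helix,
               sd_len = loc$sd_span$end - loc$sd_span$start,
               sd_spacing = loc$start_codon_pos - loc$sd_span$end)
  fu <- check_fourU(cand, d$pairing, cfg)
  cand$wobble_count <- fu$wobble_count
  cand$fourU_span <- if (is.null(fu$fourU_range5)) NULL else
    list(start = m$spans$start[k5] + fu$fourU_range5[1] - 1L,
         end = m$spans$start[k5] + fu$fourU_range5[2])
  link <- attach_annotation(m, annotations, loc$start_codon_pos, seq, cfg)
  cand$gene_id <- link$gene_id
  cand$product <- link$product
  cand$gene_distance <- link$distance
  cand$orf_codons <- link$orf_codons

  # hairpin support from the stand-in fold of the matched region
  ss <- nussinov_fold(cand$region, fold_cfg)
  cand$hairpin_support <- hairpin_support(cand, ss)

  aug_codon <- substr(cand$region,
                      loc$start_codon_pos - cand$region_offset + 1L,
                      loc$start_codon_pos - cand$region_offset + 3L)
  cand$flags <- c(sd_anchor = identical(aug_codon, "AUG"),
                  fourU = is.null(fu$fourU_range5) == (cfg$fourU_run_min == 0L),
                  wobble = fu$wobble_count >= cfg$min_wobble_pairs,
                  spacing = sd_spacing_ok(cand, cfg),
                  gene_link = link$pass)
  cand$all_pass <- all(cand$flags)
  class(cand) <- "thermometer_candidate"
  cand
}

#' @export
print.thermometer_candidate <- function(x, ...) {
  cat(sprintf("candidate %s:%d-%d (%s)  rank %s  %s\n",
              x$match$sequence_id, x$match$start, x$match$end,
              x$match$strand, x$rank %||% "-",
              if (x$all_pass) "PASS" else
                paste("fail:", paste(names(x$flags)[!x$flags], collapse = ","))))
  cat(sprintf("  SD %s at %d-%d; AUG at %d; spacing(end) %d; wobble %d; support %.2f\n",
              x$sd_span$realized, x$sd_span$start, x$sd_span$end,
              x$start_codon_pos, x$sd_spacing, x$wobble_count,
              x$hairpin_support))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate candidates
#'
#' @param x a `thermometer_candidates` list.
#' @param row.names,optional,... ignored.
#' @return one row per candidate with spans, flags, rank and rule outputs.
#' @export
as.data.frame.thermometer_candidates <- function(x, row.names = NULL,
                                                 optional = FALSE, ...) {
  if (length(x) == 0L)
    return(data.frame(sequence_id = character(0)))
  do.call(rbind, lapply(x, function(c) {
    data.frame(sequence_id = c$match$sequence_id, strand = c$match$strand,
               start = c$match$start, end = c$match$end,
               rank = c$rank %||% NA_integer_,
               all_pass = c$all_pass,
               sd = c$sd_span$realized,
               sd_start = c$sd_span$start,
               start_codon_pos = c$start_codon_pos,
               sd_spacing = c$sd_spacing,
               wobble_count = c$wobble_count,
               hairpin_support = c$hairpin_support,
               gene_id = c$gene_id, gene_distance = c$gene_distance,
               orf_codons = c$orf_codons,
               flag_sd_anchor = unname(c$flags["sd_anchor"]),
               flag_fourU = unname(c$flags["fourU"]),
               flag_wobble = unname(c$flags["wobble"]),
               flag_spacing = unname(c$flags["spacing"]),
               flag_gene_link = unname(c$flags["gene_link"]),
               stringsAsFactors = FALSE)
  }))
}
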