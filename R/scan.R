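# Descriptor scanning: locate all occurrences of a motif descriptor in a
# nucleotide sequence.
#
# The engine is an anchored backtracking search over the descriptor's map
# order. A match is identified by its span tuple (strand, start and the
# per-map-entry segment lengths); distinct optional-position choices that
# realize the same span tuple are reported once. Coordinates are 0-based
# half-open internally (BED-like); human-readable reports are 1-based
# inclusive.

#' Scan configuration
#'
#' @param strand_mode `"both"` (default) scans the forward sequence and its
#'   reverse complement; `"forward"` scans only the given orientation.
#' @param overlap_policy `"report_all"` (default) reports every placement;
#'   `"leftmost_shortest_per_start"` keeps only the shortest match at each
#'   (strand, start).
#' @param max_matches optional cap on the number of reported matches
#'   (applied after deterministic ordering).
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(strand_mode = c("both", "forward"),
                        overlap_policy = c("report_all",
                                           "leftmost_shortest_per_start"),
                        max_matches = Inf) {
  structure(list(strand_mode = match.arg(strand_mode),
                 overlap_policy = match.arg(overlap_policy),
                 max_matches = max_matches),
            class = "scan_config")
}

# ---- low-level matchers ------------------------------------------------

# exact-consumption match of chars[a..b] against a strand pattern with at
# most `mm` mismatches at fixed literal positions. Optional positions are
# N, so they can be present/absent freely.
ss_match <- function(chars, a, b, pat, mm) {
  len <- b - a + 1L
  n_fixed <- sum(!pat$optional)
  n_all <- length(pat$symbols)
  if (len < n_fixed || len > n_all) return(FALSE)
  lits <- which(pat$symbols != "N")
  if (length(lits) == 0L) return(TRUE)
  # suffix counts for pruning
  fixed_sfx <- rev(cumsum(rev(!pat$optional)))
  total_sfx <- rev(cumsum(rev(rep(1L, n_all))))
  rec <- function(pi, si, used) {
    if (pi > n_all) return(si > b)
    remaining <- b - si + 1L
    if (remaining < fixed_sfx[pi] || remaining > total_sfx[pi]) return(FALSE)
    if (pat$optional[pi] && rec(pi + 1L, si, used)) return(TRUE)   # skip optional
    if (si > b) return(FALSE)
    sym <- pat$symbols[pi]
    hit <- sym == "N" || chars[si] == sym
    if (!hit) {
      if (pat$optional[pi]) return(FALSE)  # optional positions are N; unreachable
      if (used >= mm) return(FALSE)
      used <- used + 1L
    }
    rec(pi + 1L, si + 1L, used)
  }
  rec(1L, a, 0L)
}

# precompute all joint optional-subset layouts of a helix
helix_layouts <- function(e) {
  n_slot <- nrow(e$opt_slots)
  subsets <- if (n_slot == 0L) list(integer(0)) else {
    out <- list(integer(0))
    for (sz in seq_len(n_slot))
      out <- c(out, utils::combn(n_slot, sz, simplify = FALSE))
    out
  }
  lapply(subsets, function(sub) {
    keep5 <- !e$pattern5$optional
    keep5[e$opt_slots$i5[sub]] <- TRUE
    keep3 <- !e$pattern3$optional
    keep3[e$opt_slots$i3[sub]] <- TRUE
    list(sym5 = e$pattern5$symbols[keep5],
         sym3 = e$pattern3$symbols[keep3],
         len = sum(keep5))
  })
}

# count disallowed antiparallel pairs between two equal-length base vectors
count_mispairs <- function(v5, v3, allowed) {
  p3 <- rev(v3)
  acgu <- v5 %in% c("A", "C", "G", "U") & p3 %in% c("A", "C", "G", "U")
  keys <- pair_key(v5, p3)
  sum(!acgu | !(keys %in% allowed))
}

# one-time scan preparation shared by engine calls
prep_descriptor <- function(d) {
  n <- nrow(d$map_order)
  entries <- vector("list", n)
  for (k in seq_len(n)) {
    id <- d$map_order$id[k]
    e <- d$elements[[id]]
    if (e$kind == "ss") {
      r <- pattern_length_range(e$pattern)
      entries[[k]] <- list(kind = "ss", id = id, e = e,
                           min = r[[1]], max = r[[2]])
    } else {
      r <- pattern_length_range(e$pattern5)
      entries[[k]] <- list(kind = "helix", id = id, strand = d$map_order$strand[k],
                           e = e, layouts = helix_layouts(e),
                           min = r[[1]], max = r[[2]])
    }
  }
  mins <- vapply(entries, `[[`, integer(1), "min")
  maxs <- vapply(entries, `[[`, integer(1), "max")
  list(entries = entries, n = n,
       sfx_min = rev(cumsum(rev(mins))), sfx_max = rev(cumsum(rev(maxs))),
       pre_min = cumsum(mins) - mins, pre_max = cumsum(maxs) - maxs,
       allowed = d$pairing$allowed_pairs)
}

# backtracking over map entries from a fixed 1-based start; returns a list
# of integer length-tuples (one per distinct match at this start)
scan_from_start <- function(chars, prep, start1) {
  L <- length(chars)
  n <- prep$n
  lens <- integer(n)
  found <- new.env(parent = emptyenv())
  layout_of <- list()  # helix id -> layout index
  sub5_of <- list()    # helix id -> realized 5' bases
  rec <- function(k, pos) {
    if (k > n) {
      key <- paste(lens, collapse = ",")
      if (is.null(found[[key]])) found[[key]] <- lens
      return(invisible(NULL))
    }
    avail <- L - pos + 1L
    if (avail < prep$sfx_min[k]) return(invisible(NULL))
    en <- prep$entries[[k]]
    rest_min <- if (k < n) prep$sfx_min[k + 1L] else 0L
    if (en$kind == "ss") {
      for (l in en$min:en$max) {
        if (l > avail - rest_min) break
        if (ss_match(chars, pos, pos + l - 1L, en$e$pattern, en$e$max_mismatches)) {
          lens[k] <<- l
          rec(k + 1L, pos + l)
        }
      }
    } else if (en$strand == 1L) {
      for (li in seq_along(en$layouts)) {
        lay <- en$layouts[[li]]
        l <- lay$len
        if (l > avail - rest_min) next
        sub <- chars[pos:(pos + l - 1L)]
        if (all(symbol_matches(sub, lay$sym5))) {
          layout_of[[en$id]] <<- li
          sub5_of[[en$id]] <<- sub
          lens[k] <<- l
          rec(k + 1L, pos + l)
        }
      }
    } else {
      li <- layout_of[[en$id]]
      if (is.null(li)) return(invisible(NULL))
      lay <- en$layouts[[li]]
      l <- lay$len
      if (l > avail - rest_min) return(invisible(NULL))
      sub <- chars[pos:(pos + l - 1L)]
      if (all(symbol_matches(sub, lay$sym3)) &&
          count_mispairs(sub5_of[[en$id]], sub, prep$allowed) <=
            en$e$allowance_first) {
        lens[k] <<- l
        rec(k + 1L, pos + l)
      }
    }
    invisible(NULL)
  }
  rec(1L, start1)
  as.list(found)
}

# pick the longest fixed-literal run across all element strands; NULL when
# no run of length >= 3 exists (the engine then scans every start)
find_anchor <- function(d, prep) {
  best <- NULL
  for (k in seq_len(prep$n)) {
    en <- prep$entries[[k]]
    pat <- if (en$kind == "ss") {
      if (en$e$max_mismatches > 0L) next  # mismatches could break the literal
      en$e$pattern
    } else if (en$strand == 1L) en$e$pattern5 else en$e$pattern3
    is_lit <- !pat$optional & pat$symbols != "N"
    if (!any(is_lit)) next
    r <- rle(is_lit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run_len <- r$lengths[j]
      if (is.null(best) || run_len > best$run_len) {
        i0 <- starts[j]
        best <- list(
          entry = k, run_len = run_len,
          run = paste(pat$symbols[i0:(i0 + run_len - 1L)], collapse = ""),
          # 0-based offsets of the run within the realized strand
          offs = sum(!pat$optional[seq_len(i0 - 1L)]) +
            0:sum(pat$optional[seq_len(i0 - 1L)])
        )
      }
    }
  }
  if (!is.null(best) && best$run_len >= 3L) best else NULL
}

# candidate 1-based match starts for one strand of sequence text
candidate_starts <- function(seqstr, L, prep, anchor) {
  min_span <- prep$sfx_min[1]
  if (L < min_span) return(integer(0))
  if (is.null(anchor)) return(seq_len(L - min_span + 1L))
  # lookahead so overlapping anchor occurrences are all found
  hits <- gregexpr(sprintf("(?=%s)", anchor$run), seqstr, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  k <- anchor$entry
  before <- prep$pre_min[k]:prep$pre_max[k]
  offs <- anchor$offs
  starts <- unique(as.vector(outer(hits, as.vector(outer(offs, before, "+")), "-")))
  starts <- starts[starts >= 1L & starts <= L - min_span + 1L]
  sort(starts)
}

make_match <- function(sequence_id, strand, start1, lens, chars, map_tokens,
                       L_fwd) {
  ends <- start1 - 1L + cumsum(lens)     # 0-based exclusive on scanned strand
  starts <- ends - lens
  realized <- vapply(seq_along(lens), function(i) {
    if (lens[i] == 0L) "" else
      paste(chars[(starts[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  s0 <- starts[1]; e0 <- ends[length(ends)]
  if (strand == "+") {
    fstart <- s0; fend <- e0
  } else {
    fstart <- L_fwd - e0; fend <- L_fwd - s0
  }
  structure(list(
    sequence_id = sequence_id, strand = strand,
    start = fstart, end = fend, score = e0 - s0,
    spans = data.frame(element = map_tokens,
                       start = as.integer(starts), end = as.integer(ends),
                       realized = realized, stringsAsFactors = FALSE)
  ), class = "motif_match")
}

scan_one_strand <- function(seqstr, d, prep, strand, sequence_id, L_fwd) {
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  anchor <- find_anchor(d, prep)
  starts <- candidate_starts(seqstr, length(chars), prep, anchor)
  out <- list()
  for (s1 in starts) {
    tuples <- scan_from_start(chars, prep, s1)
    for (lens in tuples)
      out[[length(out) + 1L]] <-
        make_match(sequence_id, strand, s1, lens, chars,
                   d$map_order$token, L_fwd)
  }
  out
}

order_matches <- function(matches) {
  if (length(matches) == 0L) return(matches)
  key <- vapply(matches, function(m) {
    paste(formatC(m$start, width = 10, flag = "0"),
          formatC(m$score, width = 6, flag = "0"),
          paste(formatC(m$spans$end - m$spans$start, width = 6, flag = "0"),
                collapse = ","),
          if (m$strand == "+") "0" else "1",
          sep = "|")
  }, character(1))
  matches[order(key)]
}

#' Scan a sequence for descriptor matches
#'
#' Returns every placement of the descriptor in the sequence: a start
#' position plus a per-element segmentation such that all single-strand
#' patterns match within their mismatch allowances and all helix strands
#' match their patterns and pair antiparallel under the descriptor's
#' pairing rules. Matches are reported in a deterministic order (ascending
#' start, then total length, then lexicographic segment-length tuple, plus
#' strand last). Minus-strand matches are found on the reverse complement
#' and reported in forward coordinates with `strand == "-"`; their spans
#' are in reverse-complement coordinates.
#'
#' @param seq nucleotide string (DNA or RNA; IUPAC ambiguity codes allowed
#'   in the subject, where they match only pattern `N`).
#' @param d a [parse_descriptor()] result.
#' @param cfg a [scan_config()].
#' @param sequence_id identifier recorded in each match.
#' @return an object of class `motif_matches`: a list of `motif_match`
#'   records (fields `sequence_id`, `strand`, `start`/`end` 0-based
#'   half-open forward coordinates, `score` = total realized length,
#'   `spans`).
#' @export
scan_sequence <- function(seq, d, cfg = scan_config(), sequence_id = "seq") {
  if (!inherits(d, "motif_descriptor"))
    ts_error("bad_descriptor", "d must be a motif_descriptor")
  if (nrow(d$map_order) == 0L)
    ts_error("bad_descriptor", "empty descriptor")
  seqstr <- normalize_seq(seq)
  if (nchar(seqstr) < 1L)
    ts_error("bad_alphabet", "sequence must have length >= 1")
  prep <- prep_descriptor(d)
  L <- nchar(seqstr)
  matches <- scan_one_strand(seqstr, d, prep, "+", sequence_id, L)
  if (cfg$strand_mode == "both") {
    rc <- revcomp(seqstr)
    matches <- c(matches, scan_one_strand(rc, d, prep, "-", sequence_id, L))
  }
  matches <- order_matches(matches)
  if (cfg$overlap_policy == "leftmost_shortest_per_start" && length(matches)) {
    key <- vapply(matches, function(m) paste(m$strand, m$start), character(1))
    matches <- matches[!duplicated(key)]
  }
  if (is.finite(cfg$max_matches) && length(matches) > cfg$max_matches)
    matches <- matches[seq_len(cfg$max_matches)]
  structure(matches, class = "motif_matches")
}

#' Validate a match against its descriptor
#'
#' Re-checks an emitted (or externally constructed) match: spans must be
#' gap-free, ordered per the map and in bounds (violations raise errors);
#' the function then returns `TRUE` iff every span satisfies its element
#' spec for some optional-position choice and all helix pairs are allowed
#' within the mispair allowance.
#'
#' @param seq the subject sequence the match refers to (forward
#'   orientation).
#' @param d the descriptor.
#' @param m a `motif_match`. Spans of minus-strand matches are interpreted
#'   on the reverse complement.
#' @return logical.
#' @export
verify_match <- function(seq, d, m) {
  seqstr <- normalize_seq(seq)
  scanned <- if (m$strand == "+") seqstr else revcomp(seqstr)
  chars <- strsplit(scanned, "", fixed = TRUE)[[1]]
  sp <- m$spans
  if (nrow(sp) != nrow(d$map_order) ||
      !identical(sp$element, d$map_order$token))
    ts_error("bad_match", "spans do not follow the descriptor map order")
  if (any(sp$end < sp$start) || sp$start[1] < 0L ||
      sp$end[nrow(sp)] > length(chars))
    ts_error("out_of_bounds", "span out of sequence bounds")
  if (nrow(sp) > 1L && any(sp$start[-1] != sp$end[-nrow(sp)]))
    ts_error("non_contiguous", "spans are not contiguous in map order")
  sub5_of <- list(); layout_of <- list()
  for (k in seq_len(nrow(sp))) {
    id <- d$map_order$id[k]
    e <- d$elements[[id]]
    a <- sp$start[k] + 1L; b <- sp$end[k]
    seg <- if (b >= a) chars[a:b] else character(0)
    if (nzchar(sp$realized[k]) &&
        paste(seg, collapse = "") != sp$realized[k]) return(FALSE)
    if (e$kind == "ss") {
      if (!ss_match(chars, a, b, e$pattern, e$max_mismatches)) return(FALSE)
    } else if (d$map_order$strand[k] == 1L) {
      lays <- helix_layouts(e)
      ok <- which(vapply(lays, function(l)
        l$len == length(seg) && all(symbol_matches(seg, l$sym5)), logical(1)))
      if (length(ok) == 0L) return(FALSE)
      layout_of[[id]] <- lays[ok]
      sub5_of[[id]] <- seg
    } else {
      lays <- layout_of[[id]]
      if (is.null(lays)) return(FALSE)
      good <- any(vapply(lays, function(l)
        l$len == length(seg) && all(symbol_matches(seg, l$sym3)), logical(1)))
      if (!good) return(FALSE)
      if (length(sub5_of[[id]]) != length(seg)) return(FALSE)
      if (count_mispairs(sub5_of[[id]], seg, d$pairing$allowed_pairs) >
          e$allowance_first) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("motif match %s:%d-%d (%s), score %d  [1-based: %d-%d]\n",
              x$sequence_id, x$start, x$end, x$strand, x$score,
              x$start + 1L, x$end))
  cat(paste(sprintf("  %s=%s", x$spans$element, x$spans$realized),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.motif_matches <- function(x, ...) {
  cat(sprintf("%d motif match(es)\n", length(x)))
  invisible(x)
}

#' Tabulate matches
#'
#' @param x a `motif_matches` list.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per match: `sequence_id`, `strand`,
#'   `start`, `end` (0-based half-open, forward coordinates), `score`, and
#'   one `<element>` column per map entry holding the realized string.
#' @export
as.data.frame.motif_matches <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  if (length(x) == 0L)
    return(data.frame(sequence_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      score = integer(0)))
  base <- data.frame(
    sequence_id = vapply(x, `[[`, character(1), "sequence_id"),
    strand = vapply(x, `[[`, character(1), "strand"),
    start = vapply(x, `[[`, integer(1), "start"),
    end = vapply(x, `[[`, integer(1), "end"),
    score = vapply(x, `[[`, integer(1), "score"),
    stringsAsFactors = FALSE)
  toks <- x[[1]]$spans$element
  for (i in seq_along(toks))
    base[[toks[i]]] <- vapply(x, function(m) m$spans$realized[i], character(1))
  base
}
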