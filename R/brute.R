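# Exhaustive reference scanner, used as the testing oracle for
# scan_sequence(). Deliberately written as plain enumeration -- every start
# position, every per-element length tuple, every optional-subset choice --
# with none of the anchoring or backtracking machinery of the main engine.
# Intended for sequences up to a few hundred nucleotides.

# all subsets of 1..n of size k, as a list of integer vectors
subsets_of_size <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  if (k > n) return(list())
  utils::combn(n, k, simplify = FALSE)
}

# does segment `seg` match single-strand pattern under <= mm mismatches,
# for at least one choice of present optional positions?
bf_ss_ok <- function(seg, pat, mm) {
  need <- length(seg) - sum(!pat$optional)
  if (need < 0L || need > sum(pat$optional)) return(FALSE)
  opt_idx <- which(pat$optional)
  for (sub in subsets_of_size(length(opt_idx), need)) {
    keep <- !pat$optional
    keep[opt_idx[sub]] <- TRUE
    sym <- pat$symbols[keep]
    mism <- sum(!symbol_matches(seg, sym))
    if (mism <= mm) return(TRUE)
  }
  FALSE
}

# joint check of both helix segments over all joint optional-subset choices
bf_helix_ok <- function(seg5, seg3, e, allowed) {
  if (length(seg5) != length(seg3)) return(FALSE)
  k <- length(seg5) - sum(!e$pattern5$optional)
  n_slot <- nrow(e$opt_slots)
  if (k < 0L || k > n_slot) return(FALSE)
  for (sub in subsets_of_size(n_slot, k)) {
    keep5 <- !e$pattern5$optional
    keep5[e$opt_slots$i5[sub]] <- TRUE
    keep3 <- !e$pattern3$optional
    keep3[e$opt_slots$i3[sub]] <- TRUE
    if (!all(symbol_matches(seg5, e$pattern5$symbols[keep5]))) next
    if (!all(symbol_matches(seg3, e$pattern3$symbols[keep3]))) next
    if (count_mispairs(seg5, seg3, allowed) <= e$allowance_first) return(TRUE)
  }
  FALSE
}

bf_scan_strand <- function(seqstr, d, strand, sequence_id, L_fwd) {
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  L <- length(chars)
  n <- nrow(d$map_order)
  ranges <- lapply(seq_len(n), function(k)
    element_length_range(d$elements[[d$map_order$id[k]]]))
  min_span <- sum(vapply(ranges, `[[`, integer(1), 1))
  matches <- list()
  if (L < min_span) return(matches)

  # enumerate all per-entry length tuples (helix strands share their k)
  tuples <- list(integer(0))
  for (k in seq_len(n)) {
    id <- d$map_order$id[k]
    is_h2 <- d$map_order$kind[k] == "helix" && d$map_order$strand[k] == 2L
    new <- list()
    for (t in tuples) {
      if (is_h2) {
        prev <- t[match(id, d$map_order$id[seq_along(t)])]
        new[[length(new) + 1L]] <- c(t, prev)
      } else {
        for (l in ranges[[k]][1]:ranges[[k]][2])
          new[[length(new) + 1L]] <- c(t, l)
      }
    }
    tuples <- new
  }
  tuples <- Filter(function(t) sum(t) <= L, tuples)

  # memo of per-(entry, position, length) checks: each distinct segment is
  # still checked by plain enumeration, just only once
  memo <- new.env(parent = emptyenv())
  cached <- function(key, value_fn) {
    got <- memo[[key]]
    if (is.null(got)) {
      got <- value_fn()
      memo[[key]] <- got
    }
    got
  }
  seg_at <- function(a, len) if (len > 0L) chars[(a + 1L):(a + len)] else character(0)

  for (s1 in seq_len(L - min_span + 1L)) {
    for (t in tuples) {
      if (s1 + sum(t) - 1L > L) next
      ends <- s1 - 1L + cumsum(t)
      starts <- ends - t
      ok <- TRUE
      pos_of <- list()
      for (k in seq_len(n)) {
        id <- d$map_order$id[k]
        e <- d$elements[[id]]
        if (e$kind == "ss") {
          if (!cached(paste0("s", k, ":", starts[k], ":", t[k]), function()
            bf_ss_ok(seg_at(starts[k], t[k]), e$pattern, e$max_mismatches))) {
            ok <- FALSE; break
          }
        } else if (d$map_order$strand[k] == 1L) {
          # necessary pattern-only condition; the joint check runs at the
          # 3' strand
          if (!cached(paste0("p", k, ":", starts[k], ":", t[k]), function()
            bf_ss_ok(seg_at(starts[k], t[k]), e$pattern5, 0L))) {
            ok <- FALSE; break
          }
          pos_of[[id]] <- c(starts[k], t[k])
        } else {
          p5 <- pos_of[[id]]
          if (!cached(paste0("h", k, ":", p5[1], ":", p5[2], ":",
                             starts[k], ":", t[k]), function()
            bf_helix_ok(seg_at(p5[1], p5[2]), seg_at(starts[k], t[k]), e,
                        d$pairing$allowed_pairs))) {
            ok <- FALSE; break
          }
        }
      }
      if (ok)
        matches[[length(matches) + 1L]] <-
          make_match(sequence_id, strand, s1, t, chars,
                     d$map_order$token, L_fwd)
    }
  }
  matches
}

#' Exhaustive reference scan (testing oracle)
#'
#' Same contract and output ordering as [scan_sequence()], implemented by
#' brute-force enumeration of every start position, segmentation and
#' optional-position choice. Exponential in descriptor size; intended for
#' short sequences (a few hundred nt).
#'
#' @inheritParams scan_sequence
#' @return a `motif_matches` list.
#' @export
brute_force_scan <- function(seq, d, cfg = scan_config(), sequence_id = "seq") {
  if (!inherits(d, "motif_descriptor"))
    ts_error("bad_descriptor", "d must be a motif_descriptor")
  seqstr <- normalize_seq(seq)
  if (nchar(seqstr) < 1L)
    ts_error("bad_alphabet", "sequence must have length >= 1")
  L <- nchar(seqstr)
  matches <- bf_scan_strand(seqstr, d, "+", sequence_id, L)
  if (cfg$strand_mode == "both")
    matches <- c(matches, bf_scan_strand(revcomp(seqstr), d, "-", sequence_id, L))
  matches <- order_matches(matches)
  if (cfg$overlap_policy == "leftmost_shortest_per_start" && length(matches)) {
    key <- vapply(matches, function(m) paste(m$strand, m$start), character(1))
    matches <- matches[!duplicated(key)]
  }
  if (is.finite(cfg$max_matches) && length(matches) > cfg$max_matches)
    matches <- matches[seq_len(cfg$max_matches)]
  structure(matches, class = "motif_matches")
}
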