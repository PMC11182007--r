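# Motif descriptor language: parsing, validation, ranges, sampling.
#
# A descriptor file has the layout printed by descriptor-driven motif search
# tools for RNA: a map line giving element order (a helix id appears twice,
# its 3' strand marked with a prime), then one definition line per element:
#
#   s1 h1 s2 h2 s3 h2' s4 h1' s5
#   s1 0   NNN******
#   h1 0:0 *NNNNN:NNNNN*
#   ...
#
# "N" is any nucleotide; "*" marks a position that may or may not be
# present. In helices the k-th optional position from the outside on the 5'
# strand corresponds to the k-th from the outside on the 3' strand, and the
# two are jointly present or absent.

PRIME_CHARS_RE <- "['\"′]+$"

parse_pattern <- function(str, line = NULL) {
  ch <- strsplit(chartr("T", "U", toupper(str)), "", fixed = TRUE)[[1]]
  if (length(ch) == 0L)
    ts_error("parse", "empty pattern", line = line)
  bad <- setdiff(unique(ch), c("A", "C", "G", "U", "N", "*"))
  if (length(bad) > 0L)
    ts_error("unknown_symbol",
             sprintf("unknown pattern symbol(s): %s", paste(bad, collapse = ", ")),
             line = line)
  optional <- ch == "*"
  symbols <- ifelse(optional, "N", ch)
  structure(list(symbols = symbols, optional = optional),
            class = "strand_pattern")
}

pattern_string <- function(p) {
  paste(ifelse(p$optional, "*", p$symbols), collapse = "")
}

pattern_length_range <- function(p) {
  c(sum(!p$optional), length(p$symbols))
}

# paired optional slots of a helix: 5' optionals in order of distance from
# the outer (left) end, 3' optionals in order of distance from the outer
# (right) end.
helix_opt_slots <- function(pattern5, pattern3) {
  i5 <- which(pattern5$optional)
  i3 <- rev(which(pattern3$optional))
  data.frame(i5 = i5, i3 = i3)
}

#' Length range of a descriptor element, per strand
#'
#' The minimum realized length of a strand is its number of fixed positions;
#' the maximum adds the optional positions. For a helix both strands have
#' the same range (optional positions are paired and fixed counts must be
#' equal).
#'
#' @param spec an element of a parsed [motif_descriptor].
#' @return integer vector `c(min, max)`.
#' @export
element_length_range <- function(spec) {
  p <- if (spec$kind == "ss") spec$pattern else spec$pattern5
  r <- pattern_length_range(p)
  c(min = r[[1]], max = r[[2]])
}

#' Total span range of a descriptor
#'
#' Sum of per-element length ranges over the map order; each helix strand
#' contributes once per map occurrence (so twice per helix).
#'
#' @param d a [motif_descriptor].
#' @return integer vector `c(min, max)` of realizable total lengths.
#' @export
descriptor_span_range <- function(d) {
  mins <- 0L; maxs <- 0L
  for (k in seq_len(nrow(d$map_order))) {
    r <- element_length_range(d$elements[[d$map_order$id[k]]])
    mins <- mins + r[[1]]; maxs <- maxs + r[[2]]
  }
  c(min = mins, max = maxs)
}

#' Parse a motif descriptor file
#'
#' Parses the text descriptor format: a map line followed by one definition
#' line per element -- `name allowance pattern` for single-stranded
#' elements, `name a:b pattern5:pattern3` for helices. `#` starts a
#' comment; `T` is normalized to `U`; the primed (3') strand token of a
#' helix may be written `h2'`, `h2"` or with a Unicode prime.
#'
#' Validation errors are signalled as classed conditions
#' (`thermoscan_missing_definition`, `thermoscan_helix_strand_count`,
#' `thermoscan_crossing_helices`, `thermoscan_unknown_symbol`,
#' `thermoscan_allowance_exceeds_fixed`, ...) carrying the offending line
#' number in the message.
#'
#' @param text descriptor file contents (single string or character vector
#'   of lines).
#' @param wobble allow G:U wobble pairs in the descriptor's pairing rules
#'   (default `TRUE`).
#' @return an object of class `motif_descriptor` with fields `map_order`
#'   (data.frame: `token`, `id`, `strand`), `elements` (named list of
#'   element specs) and `pairing` ([pairing_rules()]).
#' @export
parse_descriptor <- function(text, wobble = TRUE) {
  if (length(text) == 0L || all(!nzchar(text)))
    ts_error("parse", "empty descriptor text")
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  stripped <- sub("#.*$", "", lines)
  stripped <- trimws(stripped)
  content <- which(nzchar(stripped))
  if (length(content) == 0L)
    ts_error("parse", "descriptor contains no content lines")

  rules <- pairing_rules(wobble = wobble)

  # --- map line ---
  map_ln <- content[1]
  toks <- strsplit(stripped[map_ln], "[[:space:]]+")[[1]]
  base <- sub(PRIME_CHARS_RE, "", toks)
  primed <- base != toks
  kind <- ifelse(grepl("^s", base), "ss",
                 ifelse(grepl("^h", base), "helix", NA))
  if (anyNA(kind))
    ts_error("parse",
             sprintf("map ids must start with 's' or 'h': %s",
                     paste(base[is.na(kind)], collapse = ", ")),
             line = map_ln)
  if (any(primed & kind == "ss"))
    ts_error("parse", "single-strand ids cannot be primed", line = map_ln)

  for (id in unique(base[kind == "ss"])) {
    if (sum(base == id) != 1L)
      ts_error("parse", sprintf("single-strand id '%s' must appear exactly once", id),
               line = map_ln)
  }
  for (id in unique(base[kind == "helix"])) {
    occ <- which(base == id)
    if (length(occ) != 2L)
      ts_error("helix_strand_count",
               sprintf("helix '%s' must appear exactly twice in the map (found %d)",
                       id, length(occ)),
               line = map_ln)
    if (primed[occ[1]] || !primed[occ[2]])
      ts_error("helix_strand_count",
               sprintf("helix '%s': unprimed strand must precede the primed strand", id),
               line = map_ln)
  }
  # proper nesting of helices
  stack <- character(0)
  for (k in seq_along(base)) {
    if (kind[k] != "helix") next
    if (!primed[k]) {
      stack <- c(stack, base[k])
    } else {
      if (length(stack) == 0L || stack[length(stack)] != base[k])
        ts_error("crossing_helices",
                 sprintf("helix '%s' closes out of order (pseudoknotted maps are not supported)",
                         base[k]),
                 line = map_ln)
      stack <- stack[-length(stack)]
    }
  }

  map_order <- data.frame(token = toks, id = base,
                          strand = ifelse(primed, 2L, 1L),
                          kind = kind, stringsAsFactors = FALSE)

  # --- definition lines ---
  elements <- list()
  for (ln in content[-1]) {
    parts <- strsplit(stripped[ln], "[[:space:]]+")[[1]]
    if (length(parts) != 3L)
      ts_error("parse", sprintf("expected 'name allowance pattern', got: %s",
                                stripped[ln]), line = ln)
    name <- parts[1]
    if (!(name %in% base))
      ts_error("unknown_element",
               sprintf("definition for '%s' which is not in the map", name),
               line = ln)
    if (!is.null(elements[[name]]))
      ts_error("parse", sprintf("duplicate definition for '%s'", name), line = ln)

    if (grepl("^s", name)) {
      mm <- suppressWarnings(as.integer(parts[2]))
      if (is.na(mm) || mm < 0L)
        ts_error("parse", "single-strand allowance must be a non-negative integer",
                 line = ln)
      pat <- parse_pattern(parts[3], line = ln)
      if (mm > sum(!pat$optional))
        ts_error("allowance_exceeds_fixed",
                 sprintf("'%s': mismatch allowance %d exceeds fixed position count %d",
                         name, mm, sum(!pat$optional)),
                 line = ln)
      elements[[name]] <- list(kind = "ss", name = name,
                               max_mismatches = mm, pattern = pat)
    } else {
      ab <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
      if (length(ab) != 2L)
        ts_error("parse", "helix allowance must have the form a:b", line = ln)
      a <- suppressWarnings(as.integer(ab[1]))
      b <- suppressWarnings(as.integer(ab[2]))
      if (is.na(a) || is.na(b) || a < 0L || b < 0L)
        ts_error("parse", "helix allowances must be non-negative integers", line = ln)
      if (b > 0L)
        ts_error("unsupported_insertions",
                 sprintf("'%s': insertion allowance %d is not supported (must be 0)",
                         name, b),
                 line = ln)
      pp <- strsplit(parts[3], ":", fixed = TRUE)[[1]]
      if (length(pp) != 2L)
        ts_error("parse", "helix pattern must have the form pattern5:pattern3",
                 line = ln)
      p5 <- parse_pattern(pp[1], line = ln)
      p3 <- parse_pattern(pp[2], line = ln)
      if (sum(p5$optional) != sum(p3$optional))
        ts_error("helix_optional_mismatch",
                 sprintf("'%s': optional position counts differ between strands", name),
                 line = ln)
      if (sum(!p5$optional) != sum(!p3$optional))
        ts_error("helix_strand_length",
                 sprintf("'%s': fixed position counts differ between strands", name),
                 line = ln)
      if (a > sum(!p5$optional))
        ts_error("allowance_exceeds_fixed",
                 sprintf("'%s': mispair allowance %d exceeds fixed position count %d",
                         name, a, sum(!p5$optional)),
                 line = ln)
      # literal-vs-literal compatibility at the all-present alignment
      L <- length(p5$symbols)
      for (i in seq_len(L)) {
        s5 <- p5$symbols[i]; s3 <- p3$symbols[L + 1L - i]
        if (s5 != "N" && s3 != "N" && !pair_allowed(s5, s3, rules))
          ts_error("pattern_pair_conflict",
                   sprintf("'%s': literal positions %d:%d (%s:%s) cannot pair",
                           name, i, L + 1L - i, s5, s3),
                   line = ln)
      }
      elements[[name]] <- list(kind = "helix", name = name,
                               allowance_first = a, allowance_second = b,
                               pattern5 = p5, pattern3 = p3,
                               opt_slots = helix_opt_slots(p5, p3))
    }
  }

  missing <- setdiff(base, names(elements))
  if (length(missing) > 0L)
    ts_error("missing_definition",
             sprintf("map id(s) without definition: %s", paste(missing, collapse = ", ")),
             line = map_ln)

  d <- structure(list(map_order = map_order, elements = elements,
                      pairing = rules),
                 class = "motif_descriptor")
  rng <- descriptor_span_range(d)
  if (rng[[1]] < 1L)
    ts_error("empty_match_descriptor",
             "descriptor admits empty matches (total minimum span is 0)")
  d
}

#' Serialize a motif descriptor to its text format
#'
#' The output round-trips through [parse_descriptor()] to an identical
#' structure.
#'
#' @param d a `motif_descriptor`.
#' @return a character scalar in the descriptor file layout.
#' @export
format_descriptor <- function(d) {
  lines <- paste(d$map_order$token, collapse = " ")
  for (id in unique(d$map_order$id)) {
    e <- d$elements[[id]]
    if (e$kind == "ss") {
      lines <- c(lines, sprintf("%s %d %s", id, e$max_mismatches,
                                pattern_string(e$pattern)))
    } else {
      lines <- c(lines, sprintf("%s %d:%d %s:%s", id, e$allowance_first,
                                e$allowance_second,
                                pattern_string(e$pattern5),
                                pattern_string(e$pattern3)))
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
print.motif_descriptor <- function(x, ...) {
  n_ss <- sum(vapply(x$elements, function(e) e$kind == "ss", logical(1)))
  n_h <- length(x$elements) - n_ss
  rng <- descriptor_span_range(x)
  cat(sprintf("motif descriptor: %d single-strand element(s), %d helix(es), map length %d\n",
              n_ss, n_h, nrow(x$map_order)))
  cat(sprintf("total span range: %d-%d nt; wobble pairing %s\n",
              rng[[1]], rng[[2]],
              if (x$pairing$wobble_enabled) "on" else "off"))
  cat(format_descriptor(x), "\n")
  invisible(x)
}

# run a block with a locally seeded RNG, restoring global state after
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

DEFAULT_BACKGROUND <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)

#' Sample a sequence instance of a descriptor
#'
#' Draws one realized occurrence of the motif: each optional position is
#' included with probability 0.5 (paired helix optionals jointly), `N`
#' positions are filled from the background distribution, and helix 3'
#' strands are filled antiparallel-complementary to the 5' realization
#' while respecting both strands' literals. An unsatisfiable literal pair
#' raises `thermoscan_unsatisfiable_pair`.
#'
#' @param d a `motif_descriptor`.
#' @param seed integer RNG seed.
#' @param background named probabilities over `A`, `C`, `G`, `U`.
#' @return a list with `sequence` (RNA string) and `truth`, a data.frame of
#'   per-map-entry spans (`element`, `start` 0-based, `end` exclusive,
#'   `realized`).
#' @export
sample_instance <- function(d, seed = 1L, background = DEFAULT_BACKGROUND) {
  stopifnot(inherits(d, "motif_descriptor"))
  background <- background / sum(background)
  with_local_seed(seed, {
    bases <- names(background)
    draw <- function(n) sample(bases, n, replace = TRUE, prob = background)

    realized <- character(nrow(d$map_order))
    # realize helices jointly, cache the 3' strand for its map slot
    cache3 <- list()
    for (k in seq_len(nrow(d$map_order))) {
      id <- d$map_order$id[k]
      e <- d$elements[[id]]
      if (e$kind == "ss") {
        keep <- !e$pattern$optional | (stats::runif(length(e$pattern$optional)) < 0.5)
        sym <- e$pattern$symbols[keep]
        out <- ifelse(sym == "N", draw(length(sym)), sym)
        realized[k] <- paste(out, collapse = "")
      } else if (d$map_order$strand[k] == 1L) {
        slots <- e$opt_slots
        keep_slot <- stats::runif(nrow(slots)) < 0.5
        keep5 <- !e$pattern5$optional
        keep5[slots$i5[keep_slot]] <- TRUE
        keep3 <- !e$pattern3$optional
        keep3[slots$i3[keep_slot]] <- TRUE
        sym5 <- e$pattern5$symbols[keep5]
        sym3 <- e$pattern3$symbols[keep3]
        L <- length(sym5)
        b5 <- character(L); b3 <- character(L)
        for (i in seq_len(L)) {
          s5 <- sym5[i]; s3 <- sym3[L + 1L - i]
          if (s5 != "N" && s3 != "N") {
            if (!pair_allowed(s5, s3, d$pairing))
              ts_error("unsatisfiable_pair",
                       sprintf("helix '%s': literals %s:%s cannot pair", id, s5, s3))
            b5[i] <- s5; b3[L + 1L - i] <- s3
          } else if (s5 != "N") {
            b5[i] <- s5
            b3[L + 1L - i] <- sample(allowed_partners(s5, d$pairing), 1L)
          } else if (s3 != "N") {
            b3[L + 1L - i] <- s3
            b5[i] <- sample(allowed_partners(s3, d$pairing), 1L)
          } else {
            b5[i] <- draw(1L)
            b3[L + 1L - i] <- sample(allowed_partners(b5[i], d$pairing), 1L)
          }
        }
        realized[k] <- paste(b5, collapse = "")
        cache3[[id]] <- paste(b3, collapse = "")
      } else {
        realized[k] <- cache3[[id]]
      }
    }
    lens <- nchar(realized)
    ends <- cumsum(lens)
    starts <- ends - lens
    list(sequence = paste(realized, collapse = ""),
         truth = data.frame(element = d$map_order$token,
                            start = as.integer(starts),
                            end = as.integer(ends),
                            realized = realized,
                            stringsAsFactors = FALSE))
  })
}
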