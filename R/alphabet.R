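# Nucleotide alphabet, normalization and base-pairing rules.
#
# All sequences are handled internally as uppercase RNA (T -> U). Subject
# sequences may carry IUPAC ambiguity codes; pattern strings are restricted
# to A/C/G/U/N plus the optional-position marker "*".

IUPAC_RNA <- c("A", "C", "G", "U", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = "N",
                    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                    B = "V", D = "H", H = "D", V = "B")

# structured condition constructor; subclass becomes thermoscan_<subclass>
ts_error <- function(subclass, message, line = NULL, call. = FALSE) {
  if (!is.null(line)) message <- sprintf("line %d: %s", line, message)
  stop(structure(
    class = c(paste0("thermoscan_", subclass), "thermoscan_error",
              "error", "condition"),
    list(message = message, call = NULL)
  ))
}

#' Normalize a nucleotide sequence to the internal RNA alphabet
#'
#' Upper-cases the input and maps T to U. Subject sequences may contain
#' IUPAC ambiguity codes; anything outside the IUPAC nucleotide alphabet
#' raises an error of class `thermoscan_bad_alphabet`.
#'
#' @param x character scalar, DNA or RNA.
#' @param what label used in error messages.
#' @return uppercase RNA character scalar.
#' @export
normalize_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    ts_error("bad_alphabet", sprintf("%s must be a single character string", what))
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), IUPAC_RNA)
  if (length(bad) > 0L)
    ts_error("bad_alphabet",
             sprintf("%s contains non-IUPAC characters: %s",
                     what, paste(bad, collapse = ", ")))
  x
}

#' Reverse complement of an RNA sequence
#'
#' @param x uppercase RNA character scalar (IUPAC codes allowed).
#' @return the reverse complement, same alphabet.
#' @export
revcomp <- function(x) {
  ch <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  paste(RNA_COMPLEMENT[ch], collapse = "")
}

#' Base-pairing rules
#'
#' The default rule set allows the Watson-Crick pairs A:U and G:C plus the
#' noncanonical G:U wobble pair; disabling wobble removes G:U only.
#'
#' @param wobble logical; allow the G:U wobble pair (default `TRUE`).
#' @return an object of class `pairing_rules`.
#' @export
pairing_rules <- function(wobble = TRUE) {
  pairs <- c("AU", "CG")
  if (wobble) pairs <- c(pairs, "GU")
  structure(list(allowed_pairs = pairs, wobble_enabled = wobble),
            class = "pairing_rules")
}

# canonical unordered key for a base pair
pair_key <- function(b1, b2) {
  ifelse(b1 <= b2, paste0(b1, b2), paste0(b2, b1))
}

#' Test whether two bases may pair
#'
#' @param b1,b2 single bases in `A`, `C`, `G`, `U` (ambiguity codes never
#'   pair -- conservative).
#' @param rules a [pairing_rules()] object.
#' @return logical.
#' @export
pair_allowed <- function(b1, b2, rules = pairing_rules()) {
  if (!(b1 %in% c("A", "C", "G", "U")) || !(b2 %in% c("A", "C", "G", "U")))
    return(FALSE)
  pair_key(b1, b2) %in% rules$allowed_pairs
}

#' Classify a base pair as Watson-Crick, wobble, or unpaired
#'
#' @param b1,b2 single bases in `A`, `C`, `G`, `U`.
#' @return one of `"watson_crick"`, `"wobble"`, `"none"`. Symmetric in its
#'   arguments.
#' @export
classify_pair <- function(b1, b2) {
  ok <- c("A", "C", "G", "U")
  if (!(is.character(b1) && is.character(b2) &&
        b1 %in% ok && b2 %in% ok))
    ts_error("bad_alphabet", "classify_pair expects single bases A/C/G/U")
  key <- pair_key(b1, b2)
  if (key %in% c("AU", "CG")) return("watson_crick")
  if (key == "GU") return("wobble")
  "none"
}

# bases that can partner `b` under `rules`
allowed_partners <- function(b, rules = pairing_rules()) {
  partners <- c("A", "C", "G", "U")
  partners[vapply(partners, function(p) pair_allowed(b, p, rules), logical(1))]
}

#' Antiparallel pairing of two helix strands
#'
#' Pairs position i of the 5' strand with position L + 1 - i of the 3'
#' strand, the geometry of an RNA helix read in sequence order on both
#' strands.
#'
#' @param strand5,strand3 RNA strings of equal length.
#' @return a data.frame with columns `pos5`, `pos3`, `base5`, `base3`,
#'   `class` (from [classify_pair()]).
#' @export
helix_pairs <- function(strand5, strand3) {
  s5 <- strsplit(normalize_seq(strand5, "strand5"), "", fixed = TRUE)[[1]]
  s3 <- strsplit(normalize_seq(strand3, "strand3"), "", fixed = TRUE)[[1]]
  if (length(s5) != length(s3))
    ts_error("length_mismatch", "helix strands must have equal lengths")
  L <- length(s5)
  b3 <- s3[L + 1L - seq_len(L)]
  cls <- vapply(seq_len(L), function(i) {
    if (s5[i] %in% c("A", "C", "G", "U") && b3[i] %in% c("A", "C", "G", "U"))
      classify_pair(s5[i], b3[i]) else "none"
  }, character(1))
  data.frame(pos5 = seq_len(L), pos3 = L + 1L - seq_len(L),
             base5 = s5, base3 = b3, class = cls,
             stringsAsFactors = FALSE)
}

# does subject letter satisfy a pattern symbol? N matches anything
# (including subject ambiguity codes); a literal matches only itself.
symbol_matches <- function(subject, symbol) {
  symbol == "N" | subject == symbol
}
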