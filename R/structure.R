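# Lightweight secondary-structure verification and stabilizing-mutation
# design.
#
# A thermodynamic folder is deliberately not re-implemented: motif
# verification uses a weighted Nussinov maximum-pairing model (G:C 3,
# A:U 2, G:U 1, minimum loop 3), and import_structure() accepts dot-bracket
# strings from any external folder for users who run one.

#' Folding configuration
#'
#' @param min_loop minimum hairpin loop size in nt (default 3): a pair
#'   (i, j) requires j - i - 1 >= min_loop.
#' @param pair_weights named positive weights for `GC`, `AU`, `GU` pairs
#'   (defaults 3, 2, 1).
#' @return an object of class `fold_config`.
#' @export
fold_config <- function(min_loop = 3L, pair_weights = c(GC = 3, AU = 2, GU = 1)) {
  if (any(pair_weights <= 0)) ts_error("bad_config", "pair weights must be positive")
  if (!all(c("GC", "AU", "GU") %in% names(pair_weights)))
    ts_error("bad_config", "pair_weights needs GC, AU and GU entries")
  structure(list(min_loop = as.integer(min_loop), pair_weights = pair_weights),
            class = "fold_config")
}

pair_weight <- function(b1, b2, cfg) {
  key <- pair_key(b1, b2)
  w <- c(AU = unname(cfg$pair_weights["AU"]),
         CG = unname(cfg$pair_weights["GC"]),
         GU = unname(cfg$pair_weights["GU"]))
  if (key %in% names(w)) w[[key]] else 0
}

#' Weighted Nussinov fold
#'
#' Maximizes total pair weight over all nested structures subject to the
#' minimum loop size. The traceback is deterministic: at each interval,
#' pairing the right end is preferred over leaving it unpaired, and among
#' optimal pairings the smallest partner index is taken.
#'
#' @param seq RNA string (A/C/G/U after normalization; ambiguity codes
#'   never pair).
#' @param cfg a [fold_config()].
#' @return an object of class `secondary_structure`: `dot_bracket`,
#'   `pairs` (data.frame `i`, `j`, 1-based, i < j), `score`.
#' @export
nussinov_fold <- function(seq, cfg = fold_config()) {
  s <- strsplit(normalize_seq(seq), "", fixed = TRUE)[[1]]
  n <- length(s)
  ml <- cfg$min_loop
  # precomputed pairwise weight matrix; 0 = cannot pair (code 5 =
  # ambiguity code, never pairs)
  code <- match(s, c("A", "C", "G", "U"))
  code[is.na(code)] <- 5L
  wm <- matrix(0, 5, 5)
  wm[1, 4] <- wm[4, 1] <- cfg$pair_weights[["AU"]]
  wm[2, 3] <- wm[3, 2] <- cfg$pair_weights[["GC"]]
  wm[3, 4] <- wm[4, 3] <- cfg$pair_weights[["GU"]]
  wfull <- wm[code, code, drop = FALSE]
  # candidate values for pairing some k in i..(j-ml-1) with j:
  # w(k,j) + W[i,k-1] + W[k+1,j-1], as contiguous row/column slices
  pair_vals <- function(W, i, j) {
    ks <- i:(j - ml - 1L)
    left <- if (length(ks) > 1L) c(0, W[i, ks[-length(ks)]]) else 0
    kp <- ks + 1L
    right <- numeric(length(ks))
    valid <- kp <= j - 1L           # all but possibly the last (min_loop 0)
    if (any(valid)) right[valid] <- W[kp[valid], j - 1L]
    list(ks = ks, w = wfull[ks, j], v = wfull[ks, j] + left + right)
  }
  W <- matrix(0, n, n)
  if (n > ml + 1L) {
    for (span in (ml + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        pv <- pair_vals(W, i, j)
        pairable <- pv$w > 0
        best <- W[i, j - 1L]
        if (any(pairable)) best <- max(best, pv$v[pairable])
        W[i, j] <- best
      }
    }
  }
  pairs_i <- integer(0); pairs_j <- integer(0)
  tb <- function(i, j) {
    while (j - i > ml) {
      pv <- pair_vals(W, i, j)
      ks <- pv$ks
      hit <- which(pv$w > 0 & pv$v == W[i, j])
      if (length(hit) > 0L) {
        k <- ks[hit[1]]   # smallest partner index among optimal pairings
        pairs_i <<- c(pairs_i, k); pairs_j <<- c(pairs_j, j)
        if (k > i) tb(i, k - 1L)
        i <- k + 1L; j <- j - 1L
      } else j <- j - 1L
    }
  }
  if (n > 1L) tb(1L, n)
  db <- rep(".", n)
  db[pairs_i] <- "("; db[pairs_j] <- ")"
  ord <- order(pairs_i)
  structure(list(dot_bracket = paste(db, collapse = ""),
                 pairs = data.frame(i = pairs_i[ord], j = pairs_j[ord]),
                 score = if (n > 1L) W[1L, n] else 0),
            class = "secondary_structure")
}

#' Import a dot-bracket structure (external folder hook)
#'
#' Accepts the dot-bracket string printed by an external thermodynamic
#' folder so its structure can be used wherever a [nussinov_fold()] result
#' is, e.g. in [hairpin_support()].
#'
#' @param dot_bracket string over `.`, `(`, `)`.
#' @param score optional score/energy to carry along.
#' @return a `secondary_structure`.
#' @export
import_structure <- function(dot_bracket, score = NA_real_) {
  ch <- strsplit(dot_bracket, "", fixed = TRUE)[[1]]
  if (length(setdiff(unique(ch), c(".", "(", ")"))) > 0L)
    ts_error("bad_structure", "dot-bracket may contain only '.', '(' and ')'")
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (length(stack) == 0L)
        ts_error("bad_structure", "unbalanced dot-bracket string")
      pi <- c(pi, stack[length(stack)]); pj <- c(pj, k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L)
    ts_error("bad_structure", "unbalanced dot-bracket string")
  ord <- order(pi)
  structure(list(dot_bracket = dot_bracket,
                 pairs = data.frame(i = pi[ord], j = pj[ord]), score = score),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary structure: %d pair(s), score %s\n%s\n",
              nrow(x$pairs), format(x$score), x$dot_bracket))
  invisible(x)
}

#' Fraction of descriptor-implied SD-helix pairs recovered by a fold
#'
#' @param c a `thermometer_candidate` (from [filter_and_rank()]).
#' @param s a `secondary_structure` computed on the candidate's matched
#'   region.
#' @return fraction in `[0, 1]`.
#' @export
hairpin_support <- function(c, s) {
  L <- nchar(c$strand5)
  if (L == 0L) return(0)
  r5 <- (c$h5_start - c$region_offset) + seq_len(L)          # 1-based in region
  r3 <- (c$h3_start - c$region_offset) + (L:1)
  have <- paste(s$pairs$i, s$pairs$j)
  sum(paste(r5, r3) %in% have) / L
}

#' Propose stabilizing U-to-C mutations at wobble positions
#'
#' Finds every U in the candidate's fourU run that is wobble-paired to a G
#' in the SD strand and proposes converting them to C, turning G:U wobble
#' pairs into canonical G:C pairs. The proposal name encodes before-bases,
#' 1-based positions within the candidate's matched region, and
#' after-bases, e.g. `UU2930CC` for U's at positions 29 and 30.
#'
#' @param c a `thermometer_candidate`.
#' @param cfg a [fold_config()] supplying the pair weights used for
#'   `delta_stability` (sum of GC minus GU weights over edited pairs).
#' @return a list of `mutation_proposal` objects (empty when the fourU
#'   region has no wobble pairs).
#' @export
propose_stabilizing_mutations <- function(c, cfg = fold_config()) {
  if (is.null(c$fourU_span)) return(list())
  pr <- helix_pairs(c$strand5, c$strand3)
  run5 <- (c$fourU_span$start - c$h5_start + 1L):(c$fourU_span$end - c$h5_start)
  edit <- pr$pos5[pr$pos5 %in% run5 & pr$base5 == "U" & pr$class == "wobble"]
  if (length(edit) == 0L) return(list())
  positions <- (c$h5_start - c$region_offset) + edit      # 1-based in region
  delta <- length(edit) *
    (cfg$pair_weights[["GC"]] - cfg$pair_weights[["GU"]])
  name <- paste0(paste(rep("U", length(edit)), collapse = ""),
                 paste(positions, collapse = ""),
                 paste(rep("C", length(edit)), collapse = ""))
  list(structure(list(name = name, positions = positions,
                      before = rep("U", length(edit)),
                      after = rep("C", length(edit)),
                      delta_stability = delta),
                 class = "mutation_proposal"))
}

#' @export
print.mutation_proposal <- function(x, ...) {
  cat(sprintf("mutation %s (positions %s, delta stability +%g)\n",
              x$name, paste(x$positions, collapse = ","), x$delta_stability))
  invisible(x)
}

#' Apply a mutation proposal to a sequence
#'
#' @param seq the sequence the proposal's positions refer to (1-based).
#' @param proposal a `mutation_proposal`.
#' @return the edited sequence. A before-base mismatch raises
#'   `thermoscan_before_base_mismatch`.
#' @export
apply_mutation <- function(seq, proposal) {
  seqstr <- normalize_seq(seq)
  if (length(proposal$positions) == 0L) return(seqstr)
  ch <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  if (any(proposal$positions < 1L | proposal$positions > length(ch)))
    ts_error("out_of_bounds", "mutation position outside the sequence")
  found <- ch[proposal$positions]
  if (!all(found == proposal$before))
    ts_error("before_base_mismatch",
             sprintf("expected %s at positions %s, found %s",
                     paste(proposal$before, collapse = ""),
                     paste(proposal$positions, collapse = ","),
                     paste(found, collapse = "")))
  ch[proposal$positions] <- proposal$after
  paste(ch, collapse = "")
}
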