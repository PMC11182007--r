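# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately written as plain enumeration, independent
# of the package's scanning / folding code paths.

shipped_descriptor_text <- function() {
  readLines(system.file("extdata", "fourU_agsA_stem2.descriptor",
                        package = "thermoscan"))
}

shipped_descriptor <- function() parse_descriptor(shipped_descriptor_text())

# --- span-range oracle: enumerate every optional-subset of every element
# strand and sum the min/max realized lengths ---------------------------
oracle_span_range <- function(d) {
  strand_lengths <- function(pat) {
    n_opt <- sum(pat$optional)
    lens <- integer(0)
    for (k in 0:n_opt) lens <- c(lens, sum(!pat$optional) + k)
    sort(unique(lens))
  }
  mins <- 0L; maxs <- 0L
  for (k in seq_len(nrow(d$map_order))) {
    e <- d$elements[[d$map_order$id[k]]]
    pat <- if (e$kind == "ss") e$pattern else
      if (d$map_order$strand[k] == 1L) e$pattern5 else e$pattern3
    ls <- strand_lengths(pat)
    mins <- mins + min(ls); maxs <- maxs + max(ls)
  }
  c(mins, maxs)
}

# --- folding oracle: explicitly enumerate all nested structures --------
# returns the maximum total pair weight over every valid pair set
oracle_fold_score <- function(seq, min_loop = 3L,
                              weights = c(GC = 3, AU = 2, GU = 1)) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  w_of <- function(i, j) {
    key <- paste(sort(c(s[i], s[j])), collapse = "")
    switch(key, "CG" = weights[["GC"]], "AU" = weights[["AU"]],
           "GU" = weights[["GU"]], 0)
  }
  memo <- new.env(parent = emptyenv())
  # list of all structures on [i, j], each a numeric score
  enum <- function(i, j) {
    if (j - i < min_loop + 1L) return(0)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    scores <- enum(i, j - 1L)                 # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      w <- w_of(k, j)
      if (w > 0) {
        left <- if (k > i) enum(i, k - 1L) else 0
        inner <- enum(k + 1L, j - 1L)
        scores <- c(scores, as.vector(outer(left, outer(inner, w, "+"), "+")))
      }
    }
    out <- sort(unique(scores))
    memo[[key]] <- out
    out
  }
  max(enum(1L, n))
}

# structure validity: balanced, nested, min_loop respected, pairable bases
structure_valid <- function(seq, s, min_loop = 3L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- s$pairs
  if (nrow(p) == 0L) return(TRUE)
  if (any(p$j - p$i - 1L < min_loop)) return(FALSE)
  if (any(duplicated(c(p$i, p$j)))) return(FALSE)
  for (a in seq_len(nrow(p))) for (b in seq_len(nrow(p))) {
    if (a == b) next
    # crossing check
    if (p$i[a] < p$i[b] && p$i[b] < p$j[a] && p$j[a] < p$j[b]) return(FALSE)
  }
  all(vapply(seq_len(nrow(p)), function(a)
    classify_pair(ch[p$i[a]], ch[p$j[a]]) != "none", logical(1)))
}

# --- misc helpers -------------------------------------------------------
random_rna <- function(n, probs = c(A = .25, C = .25, G = .25, U = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

match_key <- function(m) {
  paste(m$strand, m$start,
        paste(m$spans$end - m$spans$start, collapse = ","))
}

match_keys <- function(ms) vapply(ms, match_key, character(1))

# key of a truth table from sample_instance()/generate_genome() spans
truth_key <- function(tr, strand = "+") {
  paste(strand, tr$start[1], paste(tr$end - tr$start, collapse = ","))
}

# --- descriptor fuzzer --------------------------------------------------
# generates small random valid descriptors for oracle-equivalence tests
random_pattern <- function(len, n_opt, alphabet = c("A", "C", "G", "U", "N")) {
  sym <- sample(alphabet, len, replace = TRUE,
                prob = c(1, 1, 1, 1, 3)[seq_along(alphabet)])
  opt <- rep(FALSE, len)
  if (n_opt > 0L) opt[sample.int(len, n_opt)] <- TRUE
  paste(ifelse(opt, "*", sym), collapse = "")
}

# 3' helix pattern compatible with a 5' pattern (antiparallel literals)
partner_pattern <- function(pat5) {
  ch <- strsplit(pat5, "", fixed = TRUE)[[1]]
  partner <- vapply(rev(ch), function(c) {
    if (c %in% c("*", "N")) c
    else {
      opts <- switch(c, A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")
      sample(c(opts, "N"), 1L)
    }
  }, character(1))
  paste(partner, collapse = "")
}

random_descriptor <- function() {
  shape <- sample(c("ss", "ss2", "hairpin", "flanked"), 1L)
  pat <- function(maxlen = 4L, max_opt = 1L) {
    len <- sample.int(maxlen, 1L)
    random_pattern(len, sample(0:min(max_opt, len - 1L), 1L))
  }
  txt <- switch(shape,
    ss = c("s1", sprintf("s1 %d %s", sample(0:1, 1L, prob = c(.8, .2)),
                         pat(5L, 2L))),
    ss2 = c("s1 s2", sprintf("s1 0 %s", pat()), sprintf("s2 0 %s", pat())),
    hairpin = {
      p5 <- pat(3L, 1L)
      c("h1 s1 h1'", sprintf("h1 0:0 %s:%s", p5, partner_pattern(p5)),
        sprintf("s1 0 %s", pat(4L, 0L)))
    },
    flanked = {
      p5 <- pat(3L, 1L)
      c("s1 h1 s2 h1' s3", sprintf("s1 0 %s", pat(3L, 1L)),
        sprintf("h1 0:0 %s:%s", p5, partner_pattern(p5)),
        sprintf("s2 0 %s", pat(4L, 0L)), sprintf("s3 0 %s", pat(3L, 1L)))
    })
  tryCatch(parse_descriptor(txt), thermoscan_error = function(e) NULL)
}

fuzz_case <- function() {
  repeat {
    d <- random_descriptor()
    if (!is.null(d)) break
  }
  # embed an instance half the time so matches actually occur
  n <- sample(40:160, 1L)
  seq <- random_rna(n)
  if (stats::runif(1) < 0.5) {
    inst <- tryCatch(sample_instance(d, seed = sample.int(1e6, 1L)),
                     thermoscan_error = function(e) NULL)
    if (!is.null(inst) && nchar(inst$sequence) < n - 2L) {
      at <- sample.int(n - nchar(inst$sequence), 1L)
      substr(seq, at, at + nchar(inst$sequence) - 1L) <- inst$sequence
    }
  }
  list(d = d, seq = seq)
}
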