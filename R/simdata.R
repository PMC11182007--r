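# Synthetic data: genomes with planted descriptor instances, decoys,
# annotations, and simulated reporter-assay readings.
#
# The generator's world is the one the discovery pipeline targets: an
# i.i.d. background genome at a configured GC content, planted fourU
# instances each followed by an annotated ORF starting at the instance's
# AUG, plus decoy loci (dinucleotide-shuffled, pairing-broken, or
# SD-removed copies of sampled instances). All randomness flows through
# one seeded generator, so equal seeds give byte-identical fixtures.

#' Simulation configuration
#'
#' @param genome_length genome size in nt (default 100000).
#' @param gc_content background GC fraction (default 0.5).
#' @param n_plants number of planted true instances (default 50).
#' @param n_decoys number of decoy loci (default 0); decoy classes are
#'   cycled from `decoy_kinds`.
#' @param seed RNG seed.
#' @param orf_codons length of each planted ORF in codons, including the
#'   AUG (default 60).
#' @param decoy_kinds character vector drawn from `"shuffled"`,
#'   `"pairing_broken"`, `"sd_removed"`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L, gc_content = 0.5,
                       n_plants = 50L, n_decoys = 0L, seed = 1L,
                       orf_codons = 60L,
                       decoy_kinds = c("shuffled", "pairing_broken",
                                       "sd_removed")) {
  if (gc_content < 0 || gc_content > 1)
    ts_error("bad_config", "gc_content must be in [0, 1]")
  bad <- setdiff(decoy_kinds, c("shuffled", "pairing_broken", "sd_removed"))
  if (length(bad) > 0L)
    ts_error("bad_config", sprintf("unknown decoy kind(s): %s",
                                   paste(bad, collapse = ", ")))
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, n_plants = as.integer(n_plants),
                 n_decoys = as.integer(n_decoys), seed = seed,
                 orf_codons = as.integer(orf_codons),
                 decoy_kinds = decoy_kinds),
            class = "sim_config")
}

background_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
}

# truncate a sampled instance right after its AUG codon (legal because the
# trailing positions of the final element are optional); returns the
# instance with adjusted truth plus the AUG offset
truncate_at_aug <- function(inst, d) {
  info <- sd_anchor_info(d)
  n <- nrow(d$map_order)
  e_s <- d$elements[[info$aug_element]]
  realized <- inst$truth$realized[n]
  offA <- layout_offset(realized, e_s$pattern, info$aug_ppos,
                        mm = e_s$max_mismatches)
  if (is.na(offA))
    ts_error("plant_unsupported", "cannot locate the AUG in the sampled instance")
  keep <- offA + 3L
  if (keep < nchar(realized)) {
    after <- (info$aug_ppos + 3L):length(e_s$pattern$symbols)
    if (!all(e_s$pattern$optional[after]))
      ts_error("plant_unsupported",
               "final element has fixed positions after the AUG; cannot truncate")
    inst$truth$realized[n] <- substr(realized, 1L, keep)
    inst$truth$end[n] <- inst$truth$start[n] + keep
    inst$sequence <- substr(inst$sequence, 1L, inst$truth$end[n])
  }
  inst$aug_offset <- inst$truth$start[n] + offA
  inst
}

random_codons <- function(n, probs) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      codon <- paste(sample(names(probs), 3L, replace = TRUE, prob = probs),
                     collapse = "")
      if (!(codon %in% STOP_CODONS)) break
    }
    out[i] <- codon
  }
  out
}

#' Generate a synthetic genome with planted instances and decoys
#'
#' Each plant is a [sample_instance()] of the descriptor truncated at its
#' AUG, followed by an open reading frame of `cfg$orf_codons` codons (no
#' in-frame stop) and a UAA stop, annotated as a CDS starting at the AUG.
#' Decoys are derived from further sampled instances by [make_decoys()].
#' Payloads are placed without overlap at multinomially drawn gaps; the
#' background is i.i.d. at the configured GC content. Deterministic under
#' `cfg$seed`.
#'
#' @param d a `motif_descriptor`.
#' @param cfg a [sim_config()].
#' @param sequence_id name of the generated sequence record.
#' @return a list of class `sim_genome`: `sequence` (RNA string),
#'   `annotations` (data.frame as in [attach_annotation()]), `truth`
#'   (data.frame: `name`, `kind`, `decoy_class`, `start`, `end`,
#'   `aug_pos`, 0-based half-open), and `spans` (named list of per-element
#'   truth span tables in genome coordinates; `NULL` for shuffled decoys).
#' @export
generate_genome <- function(d, cfg = sim_config(), sequence_id = "simgenome") {
  probs <- background_probs(cfg$gc_content)
  with_local_seed(cfg$seed, {
    n_pay <- cfg$n_plants + cfg$n_decoys
    payloads <- vector("list", n_pay)
    kinds <- c(rep("plant", cfg$n_plants),
               if (cfg$n_decoys > 0L)
                 rep_len(cfg$decoy_kinds, cfg$n_decoys))
    for (i in seq_len(n_pay)) {
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      inst <- sample_instance(d, seed = sub_seed, background = probs)
      if (kinds[i] == "plant") {
        inst <- truncate_at_aug(inst, d)
        orf_rest <- paste(c(random_codons(cfg$orf_codons - 1L, probs), "UAA"),
                          collapse = "")
        payloads[[i]] <- list(kind = "plant", decoy_class = NA_character_,
                              seq = paste0(inst$sequence, orf_rest),
                              truth = inst$truth, aug_offset = inst$aug_offset,
                              inst_len = nchar(inst$sequence))
      } else {
        dec_seed <- sample.int(.Machine$integer.max, 1L)
        dec <- make_decoys(list(inst), kinds[i], d, seed = dec_seed)[[1]]
        payloads[[i]] <- list(kind = "decoy", decoy_class = kinds[i],
                              seq = dec$sequence,
                              truth = if (kinds[i] == "shuffled") NULL else dec$truth,
                              aug_offset = NA_integer_,
                              inst_len = nchar(dec$sequence))
      }
    }
    lens <- vapply(payloads, function(p) nchar(p$seq), integer(1))
    free <- cfg$genome_length - sum(lens)
    if (free < n_pay)  # require at least 1 nt between payloads
      ts_error("infeasible_packing",
               sprintf("payloads need %d nt but genome_length is %d",
                       sum(lens) + n_pay, cfg$genome_length))
    gaps <- if (n_pay > 0L)
      as.vector(stats::rmultinom(1L, free - n_pay, rep(1, n_pay + 1L))) +
        c(rep(1L, n_pay), 0L)
    else free
    pieces <- character(0)
    truth <- list(); spans <- list(); ann <- list()
    pos <- 0L
    for (i in seq_len(n_pay)) {
      gap_seq <- paste(sample(names(probs), gaps[i], replace = TRUE,
                              prob = probs), collapse = "")
      pieces <- c(pieces, gap_seq, payloads[[i]]$seq)
      start <- pos + gaps[i]
      p <- payloads[[i]]
      name <- sprintf("%s%03d", if (p$kind == "plant") "plant" else "decoy", i)
      aug_pos <- if (p$kind == "plant") start + p$aug_offset else NA_integer_
      truth[[i]] <- data.frame(
        sequence_id = sequence_id, name = name, kind = p$kind,
        decoy_class = p$decoy_class, start = start,
        end = start + p$inst_len, aug_pos = aug_pos,
        stringsAsFactors = FALSE)
      if (!is.null(p$truth)) {
        tr <- p$truth
        tr$start <- tr$start + start
        tr$end <- tr$end + start
        spans[[name]] <- tr
      } else spans[name] <- list(NULL)
      if (p$kind == "plant") {
        ann[[length(ann) + 1L]] <- data.frame(
          sequence_id = sequence_id, start = aug_pos,
          end = aug_pos + 3L * cfg$orf_codons + 3L, strand = "+",
          gene_id = sprintf("gene%03d", i),
          product = "synthetic planted ORF", stringsAsFactors = FALSE)
      }
      pos <- start + nchar(p$seq)
    }
    tail_len <- cfg$genome_length - pos
    pieces <- c(pieces, paste(sample(names(probs), tail_len, replace = TRUE,
                                     prob = probs), collapse = ""))
    structure(list(
      sequence = stats::setNames(paste(pieces, collapse = ""), sequence_id),
      annotations = if (length(ann)) do.call(rbind, ann) else
        data.frame(sequence_id = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   gene_id = character(0), product = character(0)),
      truth = if (length(truth)) do.call(rbind, truth) else NULL,
      spans = spans), class = "sim_genome")
  })
}

# ---- decoys ------------------------------------------------------------

# dinucleotide-preserving shuffle (random Eulerian walk over the
# transition multigraph, Altschul-Erickson style)
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(seq)
  verts <- unique(ch)
  last <- ch[n]
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  repeat {
    # pick a candidate "last edge" for every vertex except the final one
    last_edge <- stats::setNames(rep(NA_character_, length(verts)), verts)
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      outs <- edges[[v]]
      if (length(outs) == 0L) { ok <- FALSE; break }
      last_edge[v] <- outs[sample.int(length(outs), 1L)]
    }
    if (!ok) break  # degenerate composition; fall through to plain walk
    # the chosen edges must form a tree pointing toward `last`
    reaches <- function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || is.na(last_edge[v])) return(FALSE)
        seen <- c(seen, v)
        v <- last_edge[[v]]
      }
      TRUE
    }
    if (all(vapply(setdiff(verts, last), reaches, logical(1)))) break
  }
  ordered <- lapply(verts, function(v) {
    outs <- edges[[v]]
    if (!is.na(last_edge[v])) {
      drop <- match(last_edge[[v]], outs)
      outs <- c(sample(outs[-drop]), outs[drop])
    } else outs <- sample(outs)
    outs
  })
  names(ordered) <- verts
  used <- stats::setNames(rep(0L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  v <- ch[1]
  for (i in 2:n) {
    used[v] <- used[v] + 1L
    w <- ordered[[v]][used[[v]]]
    out[i] <- w
    v <- w
  }
  paste(out, collapse = "")
}

#' Derive decoy sequences from sampled instances
#'
#' * `shuffled`: dinucleotide-preserving shuffle of the whole instance.
#' * `pairing_broken`: one helix base flipped so its antiparallel partner
#'   no longer forms an allowed pair (a position whose pattern symbol is N
#'   is preferred, so the strand patterns still match but
#'   [verify_match()] fails).
#' * `sd_removed`: the realized SD literal block randomized until it
#'   differs from the SD, abolishing the descriptor match at the locus.
#'
#' @param instances list of [sample_instance()] results.
#' @param kind one of `"shuffled"`, `"pairing_broken"`, `"sd_removed"`.
#' @param d the descriptor the instances were sampled from.
#' @param seed RNG seed.
#' @return list of modified instances (`sequence` + `truth`).
#' @export
make_decoys <- function(instances, kind, d, seed = 1L) {
  if (!(kind %in% c("shuffled", "pairing_broken", "sd_removed")))
    ts_error("bad_config", sprintf("unknown decoy kind '%s'", kind))
  with_local_seed(seed, lapply(instances, function(inst) {
    switch(kind,
      shuffled = {
        inst$sequence <- dinuc_shuffle(inst$sequence)
        inst$truth <- NULL
        inst
      },
      pairing_broken = break_pairing(inst, d),
      sd_removed = remove_sd(inst, d))
  }))
}

break_pairing <- function(inst, d) {
  rows <- d$map_order
  ch <- strsplit(inst$sequence, "", fixed = TRUE)[[1]]
  for (id in unique(rows$id[rows$kind == "helix"])) {
    e <- d$elements[[id]]
    k5 <- which(rows$id == id & rows$strand == 1L)
    k3 <- which(rows$id == id & rows$strand == 2L)
    s5 <- inst$truth$realized[k5]; s3 <- inst$truth$realized[k3]
    pr <- helix_pairs(s5, s3)
    # prefer a position whose pattern symbol is N (strand patterns keep
    # matching, only the pairing breaks); fall back to a literal position
    for (i in pr$pos5) {
      partner <- pr$base3[pr$pos5 == i]
      alts <- setdiff(c("A", "C", "G", "U"), c(partner,
                      allowed_partners(partner, d$pairing)))
      if (length(alts) == 0L) next
      # pattern symbol governing this realized position (first layout)
      sym <- realized_symbol(s5, e$pattern5, i)
      cand <- if (sym == "N") alts else intersect(alts, sym)
      if (sym != "N" && length(cand) == 0L) next
      pos_abs <- inst$truth$start[k5] + i
      ch[pos_abs] <- if (sym == "N") sample(cand, 1L) else cand[1]
      inst$sequence <- paste(ch, collapse = "")
      inst$truth$realized[k5] <- substr(inst$sequence,
                                        inst$truth$start[k5] + 1L,
                                        inst$truth$end[k5])
      return(inst)
    }
  }
  ts_error("bad_config", "no helix position can be pairing-broken")
}

# pattern symbol at realized position `i` (1-based) for the first layout
# consistent with the realized strand
realized_symbol <- function(realized, pat, i) {
  seg <- strsplit(realized, "", fixed = TRUE)[[1]]
  need <- length(seg) - sum(!pat$optional)
  opt_idx <- which(pat$optional)
  for (sub in subsets_of_size(length(opt_idx), need)) {
    keep <- !pat$optional
    keep[opt_idx[sub]] <- TRUE
    if (all(symbol_matches(seg, pat$symbols[keep])))
      return(pat$symbols[keep][i])
  }
  "N"
}

remove_sd <- function(inst, d) {
  info <- sd_anchor_info(d)
  rows <- d$map_order
  k3 <- which(rows$id == info$helix & rows$strand == 2L)
  e <- d$elements[[info$helix]]
  s3 <- inst$truth$realized[k3]
  off3 <- layout_offset(s3, e$pattern3, info$run_start)
  ch <- strsplit(inst$sequence, "", fixed = TRUE)[[1]]
  idx <- inst$truth$start[k3] + off3 + seq_len(info$run_len)
  repeat {
    repl <- sample(c("A", "C", "G", "U"), info$run_len, replace = TRUE)
    if (paste(repl, collapse = "") != info$sd) break
  }
  ch[idx] <- repl
  inst$sequence <- paste(ch, collapse = "")
  inst$truth$realized[k3] <- substr(inst$sequence, inst$truth$start[k3] + 1L,
                                    inst$truth$end[k3])
  inst
}

#' Simulate reporter-assay measurements
#'
#' Draws A420 readings lognormally (mean preserved, coefficient of
#' variation `cv`) around the values that yield the target Miller units at
#' each temperature, with OD600, time and volume fixed. `cv = 0`
#' round-trips the true factors exactly through [miller_units_table()] and
#' [heat_induction_profile()].
#'
#' @param true_factors named numeric map temperature -> fold induction;
#'   must contain the reference temperature with factor 1.
#' @param base_mu Miller units at the reference temperature (default 100).
#' @param cv lognormal coefficient of variation (default 0.1).
#' @param n_reps replicates per temperature (default 3, the usual
#'   triplicate design).
#' @param seed RNG seed.
#' @param construct_id construct label.
#' @param reference_temp reference temperature (default 25).
#' @param od600,time_min,volume_mL fixed assay conditions (defaults 0.5,
#'   90 min, 0.02 mL -- a 20 uL culture sample).
#' @return data.frame in the assay CSV schema: `construct_id`,
#'   `temperature_C`, `replicate`, `A420`, `A550`, `OD600`, `time_min`,
#'   `volume_mL`.
#' @export
simulate_assay <- function(true_factors = c("25" = 1, "37" = 2.4, "42" = 4.3),
                           base_mu = 100, cv = 0.1, n_reps = 3L, seed = 1L,
                           construct_id = "construct",
                           reference_temp = 25,
                           od600 = 0.5, time_min = 90, volume_mL = 0.02) {
  if (cv < 0) ts_error("bad_config", "cv must be non-negative")
  if (n_reps < 1L) ts_error("bad_config", "n_reps must be at least 1")
  ref <- as.character(reference_temp)
  if (!(ref %in% names(true_factors)) || true_factors[[ref]] != 1)
    ts_error("bad_config",
             "true_factors must contain the reference temperature with factor 1")
  sdlog <- sqrt(log(1 + cv^2))
  with_local_seed(seed, {
    rows <- list()
    for (t in names(true_factors)) {
      target_mu <- base_mu * true_factors[[t]]
      a420_true <- target_mu * time_min * volume_mL * od600 / 1000
      noise <- if (cv == 0) rep(1, n_reps) else
        stats::rlnorm(n_reps, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      rows[[t]] <- data.frame(
        construct_id = construct_id, temperature_C = as.numeric(t),
        replicate = seq_len(n_reps), A420 = a420_true * noise, A550 = 0,
        OD600 = od600, time_min = time_min, volume_mL = volume_mL,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
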