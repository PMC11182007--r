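# SD/AUG location, fourU and wobble rules, spacing, annotation, ranking

shipped_cand <- function(seed, ann = NULL, cfg = filter_config(), flank = 20L) {
  d <- shipped_descriptor()
  set.seed(seed + 5000)
  inst <- sample_instance(d, seed = seed)
  seq <- paste0(random_rna(flank), inst$sequence, random_rna(flank))
  m <- scan_sequence(seq, d, scan_config("forward"))
  truth <- inst$truth; truth$start <- truth$start + flank
  truth$end <- truth$end + flank
  hit <- m[which(match_keys(m) == truth_key(truth))]
  list(d = d, seq = seq, inst = inst, truth = truth,
       cands = filter_and_rank(structure(hit, class = "motif_matches"), d,
                               annotations = ann, cfg = cfg, seq = seq))
}

test_that("SD and start codon are located from the descriptor anchors", {
  d <- shipped_descriptor()
  for (seed in c(3, 17, 88)) {
    inst <- sample_instance(d, seed = seed)
    m <- scan_sequence(inst$sequence, d, scan_config("forward"))
    hit <- m[[which(match_keys(m) == truth_key(inst$truth))]]
    loc <- locate_sd_and_start(hit, d)
    expect_identical(loc$sd_span$realized, "AGGAG")
    # SD sits where the realized 3' strand carries AGGAG
    h3 <- inst$truth$realized[6]
    expect_identical(substr(h3, loc$sd_span$start - inst$truth$start[6] + 1L,
                            loc$sd_span$end - inst$truth$start[6]), "AGGAG")
    # start codon anchored at s5 offset 1 (after the leading N)
    expect_equal(loc$start_codon_pos, inst$truth$start[9] + 1L)
    expect_identical(substr(inst$sequence, loc$start_codon_pos + 1L,
                            loc$start_codon_pos + 3L), "AUG")
  }
})

test_that("descriptors without SD/AUG anchors are rejected", {
  d <- parse_descriptor(c("s1", "s1 0 NNN"))
  expect_error(filter_and_rank(structure(list(), class = "motif_matches"), d),
               class = "thermoscan_not_sd_anchored")
})

test_that("SD-AUG spacing follows the descriptor geometry", {
  # distance between SD end and AUG = h2' trailing optional (0-1) +
  # s4 (1-2) + h1' (5-6) + s5 leading N (1): 7..10, always inside the
  # default 5-10 window under the from_sd_end convention
  for (seed in 1:40) {
    pc <- shipped_cand(seed)
    c1 <- pc$cands[[1]]
    expect_gte(c1$sd_spacing, 7L)
    expect_lte(c1$sd_spacing, 10L)
    expect_true(sd_spacing_ok(c1, filter_config()))
    # start-of-SD measure is spacing + 5 and fails the 5-10 window
    expect_false(sd_spacing_ok(c1, filter_config(
      spacing_convention = "from_sd_start")))
  }
})

test_that("sd_spacing_ok windows behave as configured", {
  c0 <- list(sd_spacing = 7L, sd_len = 5L)
  expect_true(sd_spacing_ok(c0, filter_config()))
  expect_false(sd_spacing_ok(list(sd_spacing = 4L, sd_len = 5L),
                             filter_config()))
  expect_true(sd_spacing_ok(list(sd_spacing = 4L, sd_len = 5L),
                            filter_config(sd_spacing_min = 0L,
                                          sd_spacing_max = 10000L)))
  # from_sd_start adds the SD length
  expect_true(sd_spacing_ok(c0, filter_config(
    sd_spacing_min = 12L, sd_spacing_max = 12L,
    spacing_convention = "from_sd_start")))
})

test_that("the fourU/wobble rule enumerates the CUUUU:AGGAG duplex", {
  core <- list(strand5 = "CUUUU", strand3 = "AGGAG", sd_span3 = c(1L, 5L))
  fu <- check_fourU(core)
  expect_true(fu$pass)
  expect_equal(fu$wobble_count, 2L)
  expect_equal(fu$fourU_range5, c(2L, 5L))
  pr <- helix_pairs("CUUUU", "AGGAG")
  expect_identical(pr$class, c("watson_crick", "watson_crick", "wobble",
                               "wobble", "watson_crick"))

  # replacing the two wobble-paired U's with C leaves no wobble pairs
  mut <- list(strand5 = "CUCCU", strand3 = "AGGAG", sd_span3 = c(1L, 5L))
  fm <- check_fourU(mut)
  expect_false(fm$pass)
  expect_equal(fm$wobble_count, 0L)
  expect_true(all(helix_pairs("CUCCU", "AGGAG")$class == "watson_crick"))

  # vacuous thresholds always pass
  expect_true(check_fourU(mut, cfg = filter_config(min_wobble_pairs = 0L,
                                                   fourU_run_min = 0L))$pass)
})

test_that("annotation linkage finds the nearest downstream gene", {
  ann <- function(start, end) data.frame(
    sequence_id = "seq", start = start, end = end, strand = "+",
    gene_id = "g1", product = "p", stringsAsFactors = FALSE)
  pc <- shipped_cand(11)
  aug <- pc$cands[[1]]$start_codon_pos
  exact <- attach_annotation(pc$cands[[1]]$match, ann(aug, aug + 90L), aug,
                             seq = pc$seq)
  expect_equal(exact$distance, 0L)
  down <- attach_annotation(pc$cands[[1]]$match, ann(aug + 12L, aug + 102L),
                            aug, seq = pc$seq)
  expect_equal(down$distance, 12L)
  none <- attach_annotation(pc$cands[[1]]$match, ann(aug - 50L, aug - 10L),
                            aug, seq = pc$seq)
  expect_false(none$pass)
})

test_that("orf_free mode requires an ORF at the AUG", {
  d <- shipped_descriptor()
  set.seed(6100)
  inst <- sample_instance(d, seed = 61)
  # build a 150-codon ORF directly after the instance AUG
  loc_m <- scan_sequence(inst$sequence, d, scan_config("forward"))
  hit <- loc_m[[which(match_keys(loc_m) == truth_key(inst$truth))]]
  aug <- locate_sd_and_start(hit, d)$start_codon_pos
  head_seq <- substr(inst$sequence, 1, aug + 3L)
  codons <- replicate(149, {
    repeat { cd <- random_rna(3); if (!cd %in% c("UAA", "UAG", "UGA")) break }
    cd
  })
  seq <- paste0(head_seq, paste(codons, collapse = ""), "UAA", random_rna(10))
  m <- scan_sequence(seq, d, scan_config("forward"))
  cfg <- filter_config(annotation_mode = "orf_free", min_orf_codons = 50L)
  cands <- filter_and_rank(m, d, cfg = cfg, seq = seq)
  best <- cands[[1]]
  expect_true(best$flags[["gene_link"]])
  expect_gte(best$orf_codons, 50L)
  # a stop right after the AUG fails the ORF requirement
  seq2 <- paste0(head_seq, "UAA", random_rna(450))
  m2 <- scan_sequence(seq2, d, scan_config("forward"))
  cands2 <- filter_and_rank(m2, d, cfg = cfg, seq = seq2)
  expect_false(any(vapply(cands2, function(c) c$flags[["gene_link"]],
                          logical(1))))
})

test_that("ranking puts passers first, then by gene distance", {
  d <- shipped_descriptor()
  gen <- generate_genome(d, sim_config(genome_length = 12000L, n_plants = 4L,
                                       n_decoys = 0L, seed = 31L))
  m <- scan_sequence(gen$sequence, d, scan_config("forward"),
                     sequence_id = "simgenome")
  # shift one gene start 12 nt downstream to create a distance-12 passerby
  ann <- gen$annotations
  ann$start[2] <- ann$start[2] + 12L
  cands <- filter_and_rank(m, d, annotations = ann, seq = gen$sequence)
  df <- as.data.frame(cands)
  expect_true(all(diff(df$all_pass) <= 0))  # passers first
  pass <- df[df$all_pass, ]
  expect_true(all(diff(pass$gene_distance) >= 0))
  # rank is deterministic
  cands2 <- filter_and_rank(m, d, annotations = ann, seq = gen$sequence)
  expect_identical(as.data.frame(cands2), df)
})

test_that("relaxing thresholds never removes a passing candidate", {
  pc <- shipped_cand(23)
  strict <- filter_config()
  relaxed <- filter_config(sd_spacing_min = 0L, sd_spacing_max = 50L,
                           min_wobble_pairs = 0L, fourU_run_min = 0L,
                           annotation_mode = "orf_free", min_orf_codons = 0L)
  d <- pc$d
  m <- scan_sequence(pc$seq, d, scan_config("forward"))
  c_strict <- filter_and_rank(m, d, cfg = filter_config(
    annotation_mode = "orf_free", min_orf_codons = 0L), seq = pc$seq)
  c_relax <- filter_and_rank(m, d, cfg = relaxed, seq = pc$seq)
  strict_pass <- match_keys(lapply(Filter(function(c) c$all_pass, c_strict),
                                   `[[`, "match"))
  relax_pass <- match_keys(lapply(Filter(function(c) c$all_pass, c_relax),
                                  `[[`, "match"))
  expect_true(all(strict_pass %in% relax_pass))
})

test_that("pairing-broken and SD-removed decoys never pass the motif rules", {
  d <- shipped_descriptor()
  gen <- generate_genome(d, sim_config(genome_length = 15000L, n_plants = 0L,
                                       n_decoys = 12L, seed = 99L))
  m <- scan_sequence(gen$sequence, d, scan_config("both"),
                     sequence_id = "simgenome")
  # no match may coincide with a decoy's truth span, and any candidate
  # overlapping a decoy locus must fail the wobble+fourU rules
  cands <- filter_and_rank(m, d, annotations = gen$annotations,
                           seq = gen$sequence)
  decoys <- gen$truth[gen$truth$kind == "decoy", ]
  for (i in seq_len(nrow(decoys))) {
    nm <- decoys$name[i]
    if (!is.null(gen$spans[[nm]]))
      expect_false(truth_key(gen$spans[[nm]]) %in% match_keys(m))
    overlapping <- Filter(function(c)
      c$match$strand == "+" && c$match$start < decoys$end[i] &&
        c$match$end > decoys$start[i], cands)
    for (c in overlapping)
      expect_false(c$flags[["fourU"]] && c$flags[["wobble"]] && c$all_pass)
  }
})
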