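# scanner engine vs brute-force oracle, strand symmetry, determinism

test_that("a planted instance is recovered with its truth spans", {
  d <- shipped_descriptor()
  set.seed(301)
  inst <- sample_instance(d, seed = 301)
  flank_l <- random_rna(30)
  flank_r <- random_rna(100 - 30 - nchar(inst$sequence) + 20)
  seq <- paste0(flank_l, inst$sequence, flank_r)
  truth <- inst$truth
  truth$start <- truth$start + 30L
  truth$end <- truth$end + 30L

  m <- scan_sequence(seq, d, scan_config("forward"))
  expect_true(truth_key(truth) %in% match_keys(m))
  # identical to the exhaustive oracle
  b <- brute_force_scan(seq, d, scan_config("forward"))
  expect_identical(match_keys(m), match_keys(b))
  hit <- m[[which(match_keys(m) == truth_key(truth))]]
  expect_identical(hit$spans$realized, truth$realized)
  expect_true(verify_match(seq, d, hit))
})

test_that("degenerate inputs give empty results or errors", {
  d <- shipped_descriptor()
  expect_length(scan_sequence(strrep("A", 120), d), 0L)
  expect_length(scan_sequence(strrep("A", 39), d), 0L)  # below min span
  expect_error(scan_sequence("ACGU!", d), class = "thermoscan_bad_alphabet")
  expect_error(scan_sequence("ACGU", structure(list(), class = "x")),
               class = "thermoscan_bad_descriptor")
})

test_that("a single-N descriptor matches every position", {
  d <- parse_descriptor(c("s1", "s1 0 N"))
  m <- scan_sequence("ACGU", d, scan_config("forward"))
  expect_length(m, 4L)
  expect_identical(match_keys(m), match_keys(
    brute_force_scan("ACGU", d, scan_config("forward"))))
})

test_that("subject ambiguity codes match pattern N but never literals", {
  d <- parse_descriptor(c("s1", "s1 0 NAN"))
  expect_length(scan_sequence("CAC", d, scan_config("forward")), 1L)
  expect_length(scan_sequence("CNC", d, scan_config("forward")), 0L)
  dN <- parse_descriptor(c("s1", "s1 0 NNN"))
  expect_length(scan_sequence("CNC", dN, scan_config("forward")), 1L)
})

test_that("scanner equals the brute-force oracle on fuzzed cases", {
  set.seed(401)
  for (case in 1:40) {
    fz <- fuzz_case()
    m <- scan_sequence(fz$seq, fz$d)
    b <- brute_force_scan(fz$seq, fz$d)
    expect_identical(match_keys(m), match_keys(b),
                     label = sprintf("case %d: %s on %s", case,
                                     format_descriptor(fz$d), fz$seq))
    for (x in m) expect_true(verify_match(fz$seq, fz$d, x))
  }
})

test_that("minus-strand matches mirror forward matches on the revcomp", {
  d <- shipped_descriptor()
  set.seed(402)
  inst <- sample_instance(d, seed = 77)
  seq <- paste0(random_rna(25), revcomp(inst$sequence), random_rna(25))
  both <- scan_sequence(seq, d, scan_config("both"))
  minus <- both[vapply(both, function(m) m$strand == "-", logical(1))]
  expect_gt(length(minus), 0L)
  fwd_rc <- scan_sequence(revcomp(seq), d, scan_config("forward"))
  L <- nchar(seq)
  mapped <- vapply(fwd_rc, function(m)
    paste(L - m$end, L - m$start), character(1))
  got <- vapply(minus, function(m) paste(m$start, m$end), character(1))
  expect_setequal(got, mapped)
})

test_that("plant-and-recover: planted instances are always found", {
  # 400 seeded plants in short flanked contexts (scaled from the 1000-plant
  # statement for runtime; recall must still be exactly 1)
  d <- shipped_descriptor()
  set.seed(403)
  miss <- 0L
  for (seed in 1:400) {
    inst <- sample_instance(d, seed = seed)
    seq <- paste0(random_rna(15), inst$sequence, random_rna(15))
    truth <- inst$truth
    truth$start <- truth$start + 15L
    truth$end <- truth$end + 15L
    m <- scan_sequence(seq, d, scan_config("forward"))
    if (!(truth_key(truth) %in% match_keys(m))) miss <- miss + 1L
  }
  expect_equal(miss, 0L)
})

test_that("verify_match validates spans and detects corruption", {
  d <- shipped_descriptor()
  inst <- sample_instance(d, seed = 9)
  m <- scan_sequence(inst$sequence, d, scan_config("forward"))
  hit <- m[[which(match_keys(m) == truth_key(inst$truth))]]
  expect_true(verify_match(inst$sequence, d, hit))

  # break one helix base pair (first base of h1 5' strand)
  ch <- strsplit(inst$sequence, "", fixed = TRUE)[[1]]
  i <- hit$spans$start[2] + 1L
  partner <- ch[hit$spans$end[8]]
  ch[i] <- setdiff(c("A", "C", "G", "U"),
                   c(allowed_partners(partner), ch[i]))[1]
  broken <- paste(ch, collapse = "")
  hit2 <- hit
  hit2$spans$realized[2] <- substr(broken, hit$spans$start[2] + 1L,
                                   hit$spans$end[2])
  expect_false(verify_match(broken, d, hit2))

  # reordered spans are structurally invalid
  hit3 <- hit
  hit3$spans <- hit3$spans[c(2, 1, 3:9), ]
  expect_error(verify_match(inst$sequence, d, hit3),
               class = "thermoscan_bad_match")
  # out-of-bounds span
  hit4 <- hit
  hit4$spans$end[9] <- nchar(inst$sequence) + 5L
  expect_error(verify_match(inst$sequence, d, hit4),
               class = "thermoscan_out_of_bounds")
})

test_that("scan reports are deterministic and policies apply", {
  d <- shipped_descriptor()
  set.seed(404)
  inst <- sample_instance(d, seed = 51)
  seq <- paste0(random_rna(40), inst$sequence, random_rna(40))
  m1 <- scan_sequence(seq, d)
  m2 <- scan_sequence(seq, d)
  f1 <- tempfile(); f2 <- tempfile()
  write_matches_tsv(m1, f1); write_matches_tsv(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  one <- scan_sequence(seq, d, scan_config(overlap_policy =
                                             "leftmost_shortest_per_start"))
  key <- vapply(one, function(m) paste(m$strand, m$start), character(1))
  expect_false(any(duplicated(key)))
  capped <- scan_sequence(seq, d, scan_config(max_matches = 3))
  expect_lte(length(capped), 3L)
})
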