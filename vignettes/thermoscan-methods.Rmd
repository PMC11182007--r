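---
title: "thermoscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermoscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscan)
```

## The problem

RNA thermometers are hairpin elements in bacterial 5′-UTRs that occlude
the Shine–Dalgarno (SD) sequence at low temperature and melt at
heat-shock temperatures, de-repressing translation. The fourU class pairs
a run of at least four consecutive uridines with the SD, typically
through at least two G•U wobble pairs whose weakness sets the melting
point. Because sequence conservation across thermometers is poor while
secondary structure is conserved, discovery works best with
*structure descriptors*: a user-written map of single-stranded and
helical elements with per-position constraints, searched exhaustively
against genomes.

`thermoscan` implements that loop — descriptor parsing, exhaustive
scanning, motif-rule curation, lightweight structure verification,
stabilizing-mutation design, and reporter-assay quantification — with a
synthetic-data generator so the whole pipeline is testable offline.

## The descriptor language

A descriptor is a map line followed by one definition per element:

```
s1 h1 s2 h2 s3 h2' s4 h1' s5
s1 0   NNN******
h1 0:0 *NNNNN:NNNNN*
s2 0   N*
h2 0:0 *CUUUUNNNN*:*NNNNAGGAG*
s3 0   NNN****
s4 0   N*
s5 0   NAUG***
```

`N` matches any nucleotide; `*` marks a position that may or may not be
present. A helix id appears twice in the map (5′ then primed 3′ strand)
and helices must nest (hairpins, no pseudoknots). The integer after a
single-strand id is its mismatch allowance, counted at fixed literal
positions only; the `a:b` pair on a helix is its mispair and insertion
allowance. Only `a:b = 0:0` appears in the shipped descriptor; non-zero
mispair allowance is supported as a relaxation, non-zero insertion
allowance is rejected as unsupported — the two integers are never defined
in print, so the package implements exactly the zero case it can verify
and names the rest.

Semantics the package commits to (they are not stated by the format):

* **`*` is positional**, not greedy end-trimming: each optional position
  is independently present or absent at its own location, so literals
  flanked by stars keep their geometry.
* **Helix optionals are paired**: the k-th optional from the outside on
  the 5′ strand corresponds to the k-th from the outside on the 3′
  strand, and the two are jointly present or absent. Both strands of a
  helix must therefore carry equal fixed and equal optional counts.
* **Pairing rules** default to {A:U, G:C, G:U}; disabling wobble removes
  G:U only. Subject-sequence ambiguity codes match pattern `N` but never
  literals, and they never pair — conservative on real genomes.
* DNA input is mapped T→U on entry; everything internal is RNA.

The shipped descriptor's total span range is 40–61 nt (verified in the
tests against a brute-force enumeration over all optional choices).

## Scanning

`scan_sequence()` reports **every** placement: a start position plus a
per-element segmentation satisfying all patterns and all helix
complementarity constraints, on both strands (minus-strand matches are
computed on the reverse complement and reported in forward coordinates).
A match is identified by its span tuple; different optional-subset
choices realizing the same spans are reported once. Output order is
deterministic: ascending start, then total length, then the
lexicographic segment-length tuple, strand last.

The engine anchors on the longest fixed literal run in the descriptor
(e.g. `CUUUU`) — found with an overlap-tolerant lookahead search — and
runs a backtracking placement only from start positions consistent with
an anchor occurrence; descriptors with no literal run of length ≥ 3 fall
back to scanning every start. Completeness does not depend on the
anchoring (anchors only prune starts), and is checked against
`brute_force_scan()`, an independent plain-enumeration oracle, on
hundreds of fuzzed descriptor/sequence cases.

Coordinates are 0-based half-open internally (BED-compatible); TSV
reports are 1-based inclusive and say so in a header comment.

## Curation rules

For each match, the SD is located as the maximal literal block of the
SD-helix 3′ pattern (`AGGAG` here) and the start codon as the `AUG`
anchored by the final element — the descriptor already encodes both, so
no independent SD rediscovery is attempted. The rules are then:

* **fourU**: a run of ≥ `fourU_run_min` (default 4) U's in the helix 5′
  strand whose antiparallel partners overlap the SD block;
* **wobble**: ≥ `min_wobble_pairs` (default 2) G•U pairs within that
  run-plus-SD region;
* **spacing**: the SD must sit 5–10 nt upstream of the start codon
  (`sd_spacing_min`/`sd_spacing_max`);
* **gene linkage**: the nearest same-strand annotated gene start at or
  downstream of the AUG (distance 0 = the CDS starts exactly there), or
  in `orf_free` mode an open reading frame of ≥ `min_orf_codons`
  (default 50) codons from the AUG.

**Spacing convention.** The package measures spacing from the *end* of
the SD to the A of the AUG by default (`from_sd_end`), with
`from_sd_start` available as a config switch. Under the shipped
descriptor's geometry the end-of-SD distance is structurally confined to
7–10 nt — inside the canonical 5–10 nt ribosome-initiation window —
while the start-of-SD distance is 12–15 nt, entirely outside it. The
end-based measure is therefore the only convention under which the
descriptor's own matches can satisfy the stated window, which is why it
is the default.

Candidates failing any rule are retained with per-rule flags but sort
after all passers; the rank key is (all-pass, gene distance ascending,
hairpin support descending, wobble count descending, start ascending),
with the span tuple as final tiebreak so the order is total and
deterministic. Gene function, which the original workflow ranked by
expert judgment, is carried through as a free-text `product` field,
unranked. The external BLAST curation step is out of scope; annotation
proximity stands in for it.

## Structure verification and mutation design

A thermodynamic folder is deliberately **not** re-implemented. Motif
verification uses a weighted Nussinov maximum-pairing model: pair
weights G:C = 3, A:U = 2, G:U = 1 (integer proxies for relative pair
stability), minimum hairpin loop 3 nt, and a deterministic traceback
(pairing preferred over leaving the right end unpaired; among optimal
pairings the smallest partner index wins). `import_structure()` accepts
dot-bracket output from any external folder for users who run one.
`hairpin_support()` is the fraction of descriptor-implied SD-helix pairs
recovered by the fold of the matched region.

One-time measurement of this model on 100 sampled instances of the
shipped descriptor (the same seeds the regression test runs): mean
support 0.65, median 0.90, 57% of samples at support ≥ 0.8. The distribution is bimodal because a maximum-weight
model has no notion of register: when the sampled flanks allow a longer
or shifted duplex, the global optimum can displace the intended SD
hairpin entirely. The regression tests freeze bounds at that measured
level (mean ≥ 0.6, median ≥ 0.8, fraction ≥ 0.8 of at least 0.5) rather
than asserting near-perfect recovery; a thermodynamic folder hooked in
via `import_structure()` would do better, and a green support test here
establishes only that the stand-in model behaves as measured, not that
it matches RNAfold.

`propose_stabilizing_mutations()` converts every wobble-paired U in the
fourU run to C, turning G•U into G–C. The proposal name encodes
before-bases, 1-based positions *within the matched region*, and
after-bases (e.g. `UU2930CC`); the coordinate origin of the published
mutant names is their reporter construct, which is not available here,
so the package's frame is its own and is stated in the name's
documentation. By construction the edit strictly increases the helix
stability score, drops the wobble count to zero (failing the default
filter), and destroys the `CUUUU` literal so the locus no longer
matches — the computational proxy for the wet-lab observation that such
mutants lose heat induction.

## Assay quantification

The Miller formula is not printed in the source protocols' summaries, so
the package adopts the standard convention

\[ \mathrm{M.U.} = \mathrm{scale} \cdot
   \frac{A_{420} - \mathrm{correction} \cdot A_{550}}
        {t \,[\mathrm{min}] \cdot v \,[\mathrm{mL}] \cdot OD_{600}} \]

with `scale = 1000` and `correction = 1.75`, both configurable. Heat
induction is the **ratio of means** (matching the stated definition;
replicate-wise ratios are available from the raw table), with reference
temperature 25 °C and defaults mirroring the triplicate design at 25/37/
42 °C.

**Uncertainty convention** (left open by the protocols): the SE of an
induction ratio uses first-order propagation with the *relative*
variance pooled across temperatures. With triplicates, a per-temperature
SE has only 2 degrees of freedom and a ±3 SE interval under-covers;
because the noise model is multiplicative with constant CV, every
temperature estimates the same relative variance, and pooling brings
coverage to 97.0% over the 500 seeded trials the acceptance suite runs.

## The synthetic world

`generate_genome()` emulates: an i.i.d. background at configurable GC
content (50% default), planted descriptor instances each followed by an
annotated ORF (60 codons by default, no premature in-frame stop, UAA
terminator) starting at the instance's AUG, and decoy loci — dinucleotide
shuffles, single-base pairing breaks, and SD-randomized copies. Planted
instances are truncated at the AUG codon (legal, since the trailing
positions of the final element are optional) so truth spans stay exact
while the ORF frame is controlled. All randomness flows through one
seeded generator; equal seeds give byte-identical fixtures.
`simulate_assay()` draws A420 lognormally (mean-preserving, CV 10% by
default, n = 3) around values yielding target Miller units at fixed
OD600 0.5, 90 min, 0.02 mL; its default factors (1, 2.4, 4.3) mirror a
strongly heat-induced construct.

What the generator does *not* emulate: genome composition structure
(repeats, skew, coding bias), transcription boundaries, overlapping
features, and any real thermodynamics of melting. A green
plant-and-recover test establishes exhaustive-search correctness and
rule specificity against these decoys — not discovery performance on
real genomes, where the match count and the manual curation burden are
set by genome composition.

## Numerical and degenerate-input choices

* Matches are deduplicated on span tuples; all orderings (matches,
  candidates) end in explicit tiebreaks so reports are byte-identical
  across runs.
* Descriptors admitting empty matches (total minimum span 0) are
  rejected at parse time; sequences shorter than the minimum span yield
  empty results, not errors.
* `classify_construct()` calls a thermometer at max induction ≥ 2.0-fold
  over non-reference temperatures, and additionally requires beating the
  negative control's induction when controls are supplied.
* Scanner subject handling of IUPAC codes is conservative (match `N`
  only, never pair), so ambiguous genome stretches cannot create
  spurious helix support.

## Known limitations

* The Nussinov stand-in has no temperature axis: it verifies hairpin
  geometry, not melting behavior; no free energies, partition functions
  or melting curves are computed.
* Insertion allowances in helices (`a:b` with `b > 0`) are unsupported.
* The scanner is exhaustive and single-threaded; very permissive
  descriptors on large genomes are costly by design (completeness over
  heuristics).
* BLAST-based curation is a stub: precomputed annotation tables stand in
  for database searches.
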