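---
title: "Modelling tandem direct duplications from reversed-ends transposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tandem direct duplications from reversed-ends transposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retdup)
```

## The reaction being modelled

Class II (cut-and-paste) transposons of the hAT superfamily, such as maize
*Ac/Ds*, normally excise as a single element and reinsert elsewhere, leaving
an 8 bp target site duplication (TSD) on each side of the new insertion.
When two elements sit near each other with their termini in *reversed*
orientation — a 3' terminus of one element facing the 5' terminus of the
other across an inter-element segment — the transposase can instead act on
that terminus pair. If the freed termini then insert into the sister
chromatid, the products are two unequal chromatids: one carrying a **tandem
direct duplication** of the segment between the elements and the target
site, the other carrying the **reciprocal deletion**; the inter-element
segment is released as a circle. `retdup` implements this reaction at
single-base resolution and the genome-scanning procedure that recognises the
sequence signature such events leave behind.

`ret_transpose()` takes a progenitor chromatid whose feature table names the
two donor termini and a target site, and returns the three products plus
junction records. Writing the progenitor as
`P = [0,cut3) | circle | [cut5, N)` with a target at `tp` beyond the element
pair (the proximal case; the distal case is the mirror construction):

* duplication product: `P[0, tp+tsd) + P[cut5, N)`
* deletion product: `P[0, cut3) + P[tp, N)`
* circle: `P[cut3, cut5)`

Three exact properties follow and are enforced by tests:

1. **Conservation**: `len(dup) + len(del) + len(circle) = 2N + tsd_len`.
2. **TSD triple equality**: the single target copy is split one-per-junction,
   so the `tsd_len`-mer at the duplication junction, the deletion junction
   and the progenitor target site are identical.
3. **Reciprocality**: the duplication product contains exactly two
   direct-orientation copies of the duplicated unit; the deletion product is
   the progenitor minus the unit and the circle, with one TSD copy retained.

The bridge-forming alternative resolution (`join_mode = "dicentric"`) is
constructed and classified (dicentric + acentric, non-viable) but not
propagated further, since it produces no heritable duplication.

## The detection signature

A duplication formed this way has a recognisable architecture: two
same-family, same-orientation element copies fewer than 100 kb apart, with
homologous sequence flanking **one** terminal end but not the other; the
repeated unit runs exactly from element boundary to element boundary; the
pre-existing element carries a matched two-sided TSD while the RET-joint
element matches that TSD on exactly one side. Non-allelic homologous
recombination (NAHR) between element copies instead leaves *three* element
copies with matched two-sided TSDs on each — the discriminator
`classify_tsd_pattern()` applies.

`scan_genome()` chains the steps: k-mer-seeded search of each library
consensus against both strands; intact/fractured classification from the
matched consensus interval; 100 bp flank extraction in consensus
orientation; pairwise flank comparison within families; one-sided-homology
pairing; repeat validation; TSD classification. The element-trailing
variant (flank homology at the 5'-adjacent side, as produced by
distal-target events and by fractured-element pairs) is handled by the
mirror of the repeat-validation construction: the second unit copy is taken
immediately *preceding* the first element rather than following the second.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `tsd_len` | 8 | bp | hAT-family target site duplication length |
| TIR length | 11 | bp | Ac terminal inverted repeat length; stand-in for families without a published value |
| `k` | 12 | nt | seed length; one clean 12-mer suffices to anchor a hit at 95% identity |
| `min_length` | 100 | bp | fractured copies must retain >100 bp of element sequence |
| `min_identity` | 80 | % | discards chance seed clusters on random background |
| `edge_slack` | 15 | bp | a terminus counts as matched within 15 bp of the consensus end, accommodating small TIR truncations (a 12 bp truncation is observed in practice) |
| `flank_len` | 100 | bp | flank window for homology comparison |
| `max_distance` | 100,000 | bp | maximum inner-edge separation of a candidate pair |
| `flank_min_identity` / `flank_min_cov` | 80% / 0.8 | | "homologous flank" is not quantified in the source procedure (done manually there); these defaults are config-exposed |
| `repeat_min_identity` | 85 | % | algorithmic version of the manual completeness/initiation check |
| `tsd_max_mismatch` | 0 | nt | both documented genomic cases show exact 8/8 TSD matches |
| PCR: 3' window / mismatches / `max_amplicon` | 12 nt / 2 / 6000 bp | | specificity stand-in; 6 kb ceiling makes a template carrying a full 4565 bp element between primers unamplifiable until the element excises |
| probe hybridisation | >= 50 bp at >= 85% | | stringent-wash approximation without hybridisation thermodynamics |

Identity is computed from global alignment (match +1, mismatch −1, gap open
−2, gap extend −1) as matches over alignment columns; `N` never counts as a
match, and TE consensi must be N-free.

## The p1 locus fixture

`build_p1_fixture()` constructs a ~29 kb chromatid modelling the progenitor
allele: p1 exon 3, a 3'-terminal Ac fragment (fAc), the inter-element
segment, a complete 4565 bp Ac, exons 2 and 1, and a proximal flank with the
8 bp target `GCGCTTTA`. The sequence is synthetic, but every diagnostic
dimension is pinned by construction: SalI sites are placed so the probe-15
digest of the progenitor yields hybridising fragments of exactly 5451 bp
(containing fAc), 2693 bp (proximal to Ac) and 1269 bp (twice, flanking p1);
the duplication allele doubles the 2693 bp band; the deletion allele loses
it and shifts the fAc band to ~12 kb (12,009 bp in the fixture — the exact
value depends on flanking sequence, so only "changed and large" is
portable). Real primer sequences (allele-specific primers 1/2, shared
primer 3, outward-facing Ac5/Ac3) are embedded at anchors chosen so the
published presence/absence pattern reproduces exactly: primers 1+2 amplify
the intact target site, 1+Ac5 only the duplication junction, 2+Ac3 only the
deletion junction, and 1+3 nothing until the junction element excises.
A scaled p2 paralog ~4 kb proximal (70 kb in reality) supports the
copy-ratio assay: p2/p1 = 2/1 for progenitor/tester, 2/2 for a duplication
not reaching p2, 3/2 for one spanning it.

Distances in the fixture are compressed relative to the real locus (where
duplications run 8 kb–5.3 Mb); the compression is bounded below by the PCR
ceiling — e.g. the Ac3 site must sit more than `max_amplicon` from primer 2
in the progenitor, which fixes the minimum spacing between Ac and the
target region.

## What the synthetic generator emulates — and what it does not

`generate_benchmark()` plants, on an i.i.d. background (GC 0.47, roughly
maize-like), the four junction archetypes: element-leading RET duplications
(`t1·TE·t1·U·t2·TE·t1·U·t2`), NAHR three-copy decoys with uniformly matched
TSDs, RET structures whose junction element excised to a 1–2 bp footprint,
and ordinary two-sided-TSD insertions. Default study conditions: 2 Mb, 20
RET duplications, 5 decoys, 5 excised junctions, 10 insertions; unit
lengths 100–2000 bp; copy divergence 0–5% (substitutions only, so planted
divergence and measured repeat identity agree within a percentage point);
one event per equal-width slot so loci never interact. Element copies are
planted as exact consensus copies, which is what makes breakpoint-exact
recall a fair requirement; divergence lives in the repeat unit, as in the
observed genomic cases.

The background deliberately contains no repeat families, nested/decayed
element copies, assembly gaps or collapsed near-identical duplications — the
main reasons a real-genome scan under-reports. A passing benchmark
therefore demonstrates correctness of the procedure, not its real-genome
sensitivity. The genome-wide maize scan itself is supported only as
user-supplied input (`scan` on any FASTA, or `read_external_hits()` for
tabular output of an external search tool) and is not part of the tests.

Because the supplementary sequence file with the three genomic archetype
loci is not redistributable here, `build_archetype_loci()` constructs
synthetic stand-ins to the published dimensions (568 bp intact element and
1262/1257 bp repeats at ~96%; 147/148 bp at ~93%; 288/289 bp 3' fragments
of a 904 bp element with 116/118 bp repeats). Divergence between planted
element copies is confined away from their edges so that hit boundaries —
and hence measured repeat lengths — stay exact.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; BED is written
  as-is, GFF3 converted to 1-based closed (zero-width point marks become
  1 bp in GFF3; BED round-trips them exactly).
* The excision footprint model draws uniformly from {1 sub, 2 subs, 1 bp
  del, 2 bp del} at the rejoined junction; a seed is mandatory.
* Overlapping hits keep the higher-identity (then longer) hit; overlapping
  candidate pairs resolve by flank identity then leftmost coordinate; the
  two symmetric pairings of a three-copy locus collapse to one call.
* `ret_transpose()` requires the canonical orientation (3'-terminus element
  left of the 5'-terminus element); mirrored loci are handled by
  reverse-complementing the chromatid, and scanning is strand-symmetric.
* The screen frequency (9 duplications / ~2000 ears = 0.45%) is reported
  with half-up rounding to one decimal, the precision at which such
  frequencies are quoted; banker's rounding would misstate it.
* Whether published repeat lengths include the terminal TSD copies is
  ambiguous, so calls report both `unit_len` (element edge to element edge)
  and `unit_len_excl_tsd`.

## Problem sizes

The test suite runs the simulator oracles on ~200 randomized toy chromatids
(tens of bp each), the fixture assays on the ~29 kb locus model, and the
scanner round trip on the full 2 Mb default benchmark; the whole suite
completes in about two minutes on one CPU. The acceptance script rebuilds
the fixture, reruns proximal RET and the virtual digest, and reports the
junction TSD length, the junction element length and the doubling fragment
size.

## Known limitations

* No inverted-duplication (sister-chromatid-transposition) products,
  multi-event histories per chromatid, inversions or translocations.
* The internal search is k-mer seed-and-extend; heavily decayed copies
  (below ~80% identity) need an external search tool via the adapter.
* PCR and hybridisation models are threshold-based; no melting temperature,
  efficiency or thermodynamics.
* Divergence planting is substitution-only by default; indel-divergent unit
  copies occur in the archetype stand-ins but not in the default benchmark.
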