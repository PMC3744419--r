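# retdup

Sequence-level tools for **transposon-induced tandem direct duplications**:
simulation of reversed-ends transposition (RET) by hAT-family DNA
transposons, and detection of the duplication signature it leaves in
genomes.

Cut-and-paste transposons like maize *Ac/Ds* occasionally misbehave: when a
3′ terminus of one element faces the 5′ terminus of a nearby element, the
transposase can excise the *pair* of termini and insert them into the
sister chromatid. One daughter chromatid then carries a tandem direct
duplication (with an extra element copy at the junction), the other the
reciprocal deletion, and the inter-element segment is lost as a circle. The
hallmark is an 8 bp target site duplication (TSD) split one-copy-per-junction
between the two products, and a diagnostic TSD asymmetry that separates
these duplications from NAHR products (which carry three element copies,
each with matched two-sided TSDs).

For a sister-chromatid pair of length *N* and target position *t*, the
products satisfy exactly:

```
len(dup) + len(del) + len(circle) = 2N + tsd_len
tsd(dup junction) == tsd(del junction) == target 8-mer
```

The package is aimed at people studying structural variation driven by
Class II transposons: it provides the reaction as an executable model
(`ret_transpose()`), a locus fixture reproducing the published diagnostics
of the maize *p1* twinned alleles (`build_p1_fixture()`), a genome scanner
for the RET signature (`scan_genome()`), a synthetic benchmark generator
with exact truth (`generate_benchmark()`), and in-silico assays
(`predict_amplicons()`, `simulate_excision_pcr()`, `virtual_southern()`,
`copy_ratio()`).

## Worked example

```r
library(retdup)

fx  <- build_p1_fixture(seed = 1)          # ~29 kb progenitor locus model
out <- ret_transpose(fx, p1_ret_event(fx, "proximal"))
out
#> <ret_outcome> proximal target: dup 38711 bp, del 18745 bp, circle 620 bp

out$junctions[, c("product", "tsd", "te_terminus", "te_name")]
#>       product      tsd te_terminus te_name
#> 1 duplication GCGCTTTA      5prime      Ac
#> 2    deletion GCGCTTTA      3prime     fAc
```

Both junctions carry one copy of the 8 bp target `GCGCTTTA` — the single
target copy of the progenitor, split between the reciprocal products. The
virtual SalI digest probed with the packaged probe-15 sequence reproduces
the published band pattern (sizes in bp, multiplicity = band intensity):

```r
southern_bands(virtual_southern(fx, probe_seq = probe15_sequence()))
#>    template length multiplicity
#> 4 P1ovov454   5451            1
#> 3 P1ovov454   2693            1
#> 2 P1ovov454   1269            2

southern_bands(virtual_southern(out$duplication_product,
                                probe_seq = probe15_sequence()))
#>        template length multiplicity
#> 3 P1ovov454_dup   5451            1
#> 2 P1ovov454_dup   2693            2    # the duplicated proximal fragment
#> 1 P1ovov454_dup   1269            2
```

Scanning a synthetic benchmark recovers every planted duplication with
breakpoint-exact coordinates and never misclassifies the NAHR decoys:

```r
b   <- generate_benchmark(seed = 1)        # 2 Mb, 40 planted events
rep <- scan_genome(b$genome, b$te_library)
rep
#> <scan_report> 70 hits, 30 candidate pairs, 25 calls (20 ret_consistent, 5 nahr_like)
score_scan(rep, b$manifest)[c("recall", "decoy_ret_calls", "excised_calls")]
#> $recall [1] 1   $decoy_ret_calls [1] 0   $excised_calls [1] 0
```

A thin command-line wrapper is installed at
`system.file("scripts", "retdup", package = "retdup")` with subcommands
`simulate`, `synth`, `scan`, `diagnose` and `bench`.

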