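---
title: "Phasing-aware star-allele calling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing-aware star-allele calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasestar)
```

## The problem

CYP2C19 metabolizes widely prescribed drugs (clopidogrel, proton-pump
inhibitors), and star-allele (`*`-allele) nomenclature is how its genetic
variability reaches the clinic: each named haplotype (`*2`, `*17`, ...) is a
set of variants, the pair of haplotypes an individual carries (the
*diplotype*, e.g. `*1/*17`) maps to a predicted metabolizer phenotype (PM,
IM, NM, RM, UM under CPIC; DPWG lacks RM), and the phenotype drives dosing.

Long-read sequencing adds two things an SNV array cannot give: all variants
in the locus (including novel ones) and read-backed *phase* — which of the
two parental alleles each heterozygous variant sits on, encoded in a VCF as
`|`-separated genotypes grouped into phase sets (PS). Phase matters at the
suballele level: `*2.011` is `*2.001` plus rs4986894 (g.94762608T>C), so
whether rs4986894 is in cis with the `*2` core variant g.94781859G>A decides
between `*1.002/*2.011` and `*1.002 + rs4986894/*2.001`. Callers relying on
population-statistical phasing can and do get this wrong; read-backed phase
resolves it per individual.

`phasestar` formalizes the manual, phasing-aware assignment procedure as a
deterministic algorithm, together with everything needed to exercise it:
nomenclature I/O, VCF ingestion, phasing statistics, variant cataloguing,
phenotype translation, multi-caller concordance scoring, and a synthetic
phased-cohort generator.

## The calling model

**Haplotype reconstruction.** Within a phase block, genotype orientation
(`1|0` vs `0|1` under one PS) fixes the relative strand assignment of its
heterozygous calls. Across blocks, and for unphased heterozygous calls, both
orientations are enumerated — `2^(B-1+U)` strand assignments for `B` blocks
and `U` unphased hets, the first unit pinned so pairs are generated once up
to strand swap. Hom-alt variants sit on both strands. Enumeration is capped
(default 12 free bits); beyond the cap, unphased variants are dropped from
enumeration deterministically (novel variants first, then descending
position), kept as unconfirmed extras, and the call is flagged truncated.

**Strand matching.** For each reconstructed strand, candidate suballeles are
ranked lexicographically by

1. most *core* variants matched (the major allele's defining lesion),
2. most defining variants matched,
3. fewest extra known (in-nomenclature) variants,
4. fewest extra novel variants,
5. natural star-allele name order.

This is a formalization of the "most variants accounted for" principle that
star-allele tools implement implicitly. Under the default
`assume_reference` missing-position policy a suballele is compatible only if
its full defining set is present; `strict_missing` instead retains
candidates whose defining variants fall at positions neither called nor
observed as reference, flagged via `missing_defining` — reproducing the
ranked-ambiguity behaviour of callers that treat absent positions as missing
rather than wildtype. Hom-ref positions are tracked as *observed reference*
precisely so these two policies can be distinguished. The reference allele
(empty defining set) is a universal fallback, so matching never fails.

**Diplotype scoring.** Because lexicographic comparison is
translation-invariant, the best diplotype for a fixed strand assignment is
the per-strand best match; across assignments the diplotype maximizing the
summed score tuple wins. Distinct diplotypes arising from other
phase-consistent assignments are reported as ranked alternatives — with full
phasing there is exactly one assignment and suballele resolution is exact;
removing phase information can only grow the alternatives list. All
tie-breaks are lexicographic; the caller has no randomness and repeated runs
are identical. Output pairs are canonically ordered (natural star order), so
results are invariant under strand swap.

**Novel suballeles.** A strand matched to a known suballele but carrying
extra variants that no catalogued suballele of the same major contains is a
candidate novel minor allele, reported as `"<suballele> + g.<pos><ref>><alt>"`.
The candidate is *confident* only when every heterozygous variant on that
strand is phased within a single phase set; a lone unphased extra is
reported unconfirmed, since its strand assignment is arbitrary.

## Phenotype translation

Major-allele function classes (normal / decreased / no_function / increased
/ unknown) and the function-combination table are shipped as editable TSVs.
The CPIC entries are: no/no → PM; no/anything-else → IM; normal/normal → NM;
normal/increased → RM; increased/increased → UM. Decreased-function rows are
included for generality (mapped to IM against no_function/normal partners,
NM against increased) although no decreased-function CYP2C19 allele occurs
in the bundled data. DPWG lacks the RM category; the bundled default maps
the increased/normal combination to NM and annotates the result as an
"increased-function carrier", since guideline sources state only that RM is
absent, not the remap. Unknown function classes or uncatalogued combinations
yield the explicit category `indeterminate`, never a silent default.

A call is *actionable* when its phenotype differs from NM, either allele has
non-normal function, or the call carries flagged extra variants beyond the
assigned suballeles. The last clause is deliberate: a `*1/*38` NM sample
carrying an extra in-cis nomenclature variant is a finding, and under this
rule exactly the plain all-`*1` samples of the bundled cohort count as
non-actionable (8/37, 21.6%).

## Phasing statistics

The per-sample phasing metric counts a heterozygous call as *phased with a
partner* only when its phase block contains at least two heterozygous calls
— a phased call alone in its block carries no relational information. The
default denominator is heterozygous calls (homozygous calls need no
phasing); since published phrasing often says "variants" without
qualification, an all-calls denominator mode is provided for sensitivity
checks. Zero-het samples report an undefined (NA) fraction, not 0%, and are
excluded-but-counted in cohort summaries. Block spans are
`max(pos + nchar(ref) - 1) - min(pos)` in bp.

## Concordance semantics

Printed diplotype strings are parsed totally (malformed cells are flagged
and counted as disagreements, never dropped): a trailing `(NM)`-style group
is a phenotype annotation, any other parenthesized group containing `/` is a
ranked alternate call (the PharmCat output-list convention). Comparison
levels: `minor_exact` compares full suballele tokens including signed
`+extra` annotations after whitespace and order normalization; `major`
strips suffixes and extras; `any_listed` accepts a match against any ranked
alternate; `phenotype` compares metabolizer categories (printed ones
preferred, translated ones where a function map is supplied). One bundled
manual cell uses a `–variant` subtraction annotation that the source never
explains; it is preserved verbatim and compares as a distinct token at
minor level, which the fixture's printed agreement counts require. The
"fraction of calls identical across all tools" statistic is deliberately not
pinned anywhere: no single counting rule we could verify reproduces the
published 45% figure (nearby rules give 43.2–45.9%), so the package reports
concordance only pairwise against the reference column.

## The synthetic cohort generator

`generate_cohort()` emits the phased multi-sample VCF implied by a list of
diplotype strings: the first allele's variants on strand A (`1|0`), the
second's on strand B (`0|1`), shared variants hom-alt, every heterozygous
call in a single phase set, positions absent from a sample emitted `0|0`
(observed reference). Noise is then applied per sample from a stream keyed
by `(seed, sample_id)` — cohorts are byte-stable and invariant under sample
reordering: phase loss per het (`p_unphase`), phase-set breaks between
consecutive hets (`p_block_split`), position dropout to `./.` (`p_drop`,
which also removes the position from the observed-reference set), Poisson
injection of novel variants from a reserved position range disjoint from all
definition positions, and a uniform per-sample coverage fraction (default
range 0.33–0.96, the spread seen in real capture data) for QC-filter
testing.

What it does **not** emulate: read-level errors, genotyping error,
coverage-dependent dropout structure (dropout is i.i.d. per position),
structural variants and hybrid genes, unnormalized indel representations,
and linkage structure beyond the specified diplotypes. Passing tests on
synthetic cohorts therefore demonstrate the correctness of the calling
logic given a faithful phased VCF, not robustness to upstream calling
artifacts.

## The bundled nomenclature fixture

Published work rarely prints full suballele compositions. The bundled
CYP2C19 table (`cyp2c19_alleles_synthetic.tsv`) encodes the variant-level
relationships that are documented — the `*2` core g.94781859G>A
(rs4244285); `*2.011` = `*2.001` + rs4986894 (g.94762608T>C); g.94775165G>C
shared by `*2.002`/`*2.010`/`*2.012`; g.94781616A>G on `*3.002`
(rs7088784); the `*11` core g.94775507G>A; the `*1` core g.94842866A>G
(rs3758581); the upstream `*17` core rs12248560 — and fills the remaining
suballele-distinguishing positions with synthetic placeholder variants
carrying blank rsids. `*38.001` is included as the reference allele with an
empty defining set (matching real nomenclature, where `*38` is
reference-like), while `*38.003` keeps an explicit defining set so that a
concrete `*38.003` carrier is representable; this is a deliberate
divergence from strict reference-haplotype semantics. The fixture is a
self-contained stand-in, not a copy of any nomenclature release, and the
validator enforces its structural invariants (shared cores per major,
unique defining sets, a unique empty-set reference).

## Numerical and design choices

* Coordinates are 1-based VCF positions throughout; BED-style 0-based
  inputs must be converted at the boundary. Indels are assumed
  left-normalized (the generator only emits normalized records); no
  realignment is performed.
* The CADD impact threshold defaults to strict `> 10` (the Methods-style
  wording) with `>= 10` available, since published phrasings differ; both
  documented high scorers (16.4, 10.4) pass under either mode.
* The QC rule is strictly "less than": a sample at exactly 10% of target
  bases at 30X is retained.
* Multiallelic records are decomposed to per-alternate keys; variant
  identity is `(chrom, pos, ref, alt)` with rsids decorative.
* Enumeration cap, truncation order, and all tie-breaks are deterministic;
  there is no RNG anywhere in the caller.

## Problem sizes

The test suite runs the full 37-sample cohort end to end (seconds),
recovers all 105 unordered suballele pairs constructible from the fixture
under zero noise, cross-checks the caller against a brute-force
strand-assignment/suballele-pair oracle on noisy samples with up to 8
heterozygous variants, and checks monotone degradation of recovery over
15-pair subsamples at 3 unphasing levels and 2 seeds. These sizes keep the
suite fast while covering the fixture's diplotype space exhaustively.

## Known limitations

* No copy-number or hybrid-gene calling (`*36`/`*37`-type events), and no
  statistical phasing — only read-backed phase is consumed.
* The fixture's placeholder variants make absolute positions of
  suballele-distinguishing variants (other than the documented ones)
  synthetic; calls against real PharmVar definitions require loading a real
  table through the same TSV/JSON dialect.
* Annotation (CADD, consequence) is consumed as a table; no VEP execution.
* Coverage summaries are consumed as a table; no BAM processing.
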