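# phasestar

Phasing-aware star-allele (diplotype) assignment for *CYP2C19* from phased
VCF genotypes, with phenotype translation, novel-suballele detection,
phasing statistics, cohort variant characterization, multi-caller
concordance scoring, and a synthetic phased-cohort generator.

## Who this is for

Pharmacogenomics researchers and clinical bioinformaticians working with
long-read (or otherwise read-back-phased) sequencing of pharmacogenes.
Star-allele callers built for array or short-read data rely on population
statistical phasing and routinely disagree at the suballele level; when the
VCF itself carries read-backed phase (``|`` genotypes grouped into `PS`
phase sets), the correct haplotype can be resolved per individual.
`phasestar` implements that phasing-aware assignment as a deterministic,
testable algorithm.

## The core algorithm

Given a phased VCF and a PharmVar-like allele-definition table
(suballeles with defining variant sets, a core subset per major allele,
and a reference allele with an empty set):

1. **Haplotype reconstruction** — within a phase block, genotype
   orientation fixes the relative strand assignment of its heterozygous
   calls; across blocks and for unphased hets both orientations are
   enumerated (`2^(B-1+U)` assignments, pinned up to strand swap, capped
   with deterministic truncation). Hom-alt variants sit on both strands.
2. **Strand matching** — candidate suballeles per strand ranked by
   (max core variants matched, max defining variants matched, fewest extra
   known, fewest extra novel, name). Under the default `assume_reference`
   policy a candidate needs its full defining set on the strand;
   `strict_missing` keeps candidates with defining variants at unassayed
   positions, flagged.
3. **Diplotype selection** — the diplotype maximizing the summed strand
   scores is primary; other phase-consistent assignments become ranked
   alternatives. With complete phasing, suballele resolution is exact:
   rs4986894 in cis with the `*2` core variant yields `*1.002/*2.011`, not
   `*1.002 + rs4986894/*2.001`.
4. **Novel suballeles** — a strand matched to a known suballele but
   carrying phased extras that no sibling suballele contains is reported as
   a candidate novel minor allele (e.g. `*38.003 + g.94781616A>G`).
5. **Phenotype** — major-allele function classes combine through a CPIC (or
   DPWG) rule table into PM/IM/NM/RM/UM, with an explicit `indeterminate`
   for unknown combinations.

See `vignettes/phasestar-methods.Rmd` for the full model, policies and
design rationale.

## Worked example

Simulate one sample carrying `*17.001` in trans with `*38.003` plus an
in-cis extra variant, then call it back:

```r
library(phasestar)
tab <- cyp2c19_table()                      # bundled simplified nomenclature
g   <- generate_cohort(table2_cohort_spec(tab, seed = 1))
cs  <- read_phased_vcf(g$vcf)

call <- call_diplotype(cs$S15, tab, region = cyp2c19_region())
call
#> <diplotype_call> S15: *17.001/*38.003 + g.94781616A>G (major *17/*38)

detect_novel_suballeles(call, tab)
#>   sample_id suballele          extras              descriptor confident
#> 1       S15   *38.003 10:94781616:A:G *38.003 + g.94781616A>G      TRUE

assign_phenotype(format(call, "major"), load_function_map())
#>   diplotype phenotype guideline actionable note
#> 1   *17/*38        RM      CPIC       TRUE <NA>

phasing_stats(restrict_to_region(cs$S15, cyp2c19_region()))
#> <phasing_stats> S15: 4/4 phased with a partner (100.0%), 1 block(s)
```

The call resolves the suballeles exactly (the sample is fully phased), the
in-cis extra g.94781616A>G — catalogued only under `*3.002` — is flagged as
a confident candidate novel minor allele of `*38`, and the `*17/*38`
diplotype translates to a Rapid Metabolizer.

Concordance between call columns uses the bundled 37-sample comparison
table:

```r
t2 <- table2_calls()
agreement(t2$manual, t2$aldy, "major", sample_ids = t2$sample,
          label = "manual vs Aldy")
#> <concordance> manual vs Aldy [major]: 30/37 agree (81.1%)
```

## Repository layout

- `R/` — implementation (nomenclature I/O, VCF ingestion, phasing metrics,
  variant catalog, star caller, phenotype translation, concordance,
  synthetic cohorts, pipeline orchestration)
- `inst/extdata/` — bundled fixtures: simplified CYP2C19 allele table
  (synthetic placeholders documented therein), 37-sample comparison
  columns, function map and phenotype rule table
- `tests/testthat/` — unit, property and acceptance suites, including an
  independent brute-force oracle for the caller
- `vignettes/phasestar-methods.Rmd` — methods and design notes
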