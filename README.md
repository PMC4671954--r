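# cernadel

Deletion-wide competing-endogenous-RNA (ceRNA) screening for interstitial
deletion syndromes, modelled on the 5q- myelodysplastic syndrome.

Hemizygous deletion halves the transcript output of a whole gene block.
Beyond direct haploinsufficiency, those lost transcripts also stop
sequestering their miRNAs: the freed ("released") miRNAs can act *in
trans* on targets outside the deletion. `cernadel` turns that idea into a
tested four-stage screen:

1. **Haploinsufficiency screen** — per in-region gene, a pooled-variance
   two-sided Student's t-test (df = n₁ + n₂ − 2), case vs control, from a
   raw expression matrix or directly from published (mean, SD, n) summary
   rows; a gene is called haploinsufficient when p < 0.05 *and* its
   expression is reduced.
2. **Released-miRNA ranking** — predicted target sites pass a four-way
   consensus filter (3'UTR, seed ≥ 7 nt from miRNA position 1, p ≤ 0.05
   in miRWalk, miRanda, RNA22 and TargetScan), collapse to one hit per
   (miRNA, gene) pair, and each miRNA is ranked by its count of distinct
   haploinsufficient targets; miRNAs with ≥ 5 are selected.
3. **ceRNA nomination** — the genes targeted by **all** selected miRNAs,
   excluding the deleted region, are the candidate ceRNAs.
4. **Validation** — each candidate is retested with the same t engine and
   called `DOWN` / `UP` / `NS` (direction unconstrained), with a
   low-expression annotation for `NS` calls near the noise floor.

A seeded synthetic-cohort generator with planted deletion effects,
released miRNAs and ceRNA genes makes every stage benchmarkable without
any external database, and the study's printed per-gene tables ship as
plain-text fixtures (with misprinted cells corrected via the SE = SD/√n
identity and the originals retained in a provenance column).

## Worked example

The numbered scripts under `analysis/` run the whole study; the same
calls work interactively:

```r
library(cernadel)

res <- run_cerna_pipeline(region            = fixture_region(),
                          target_records    = fixture_target_sites(),
                          summary_table     = fixture_table1(),
                          validation_summary = fixture_table2())

length(res$haplo_genes)        # 16
res$ranking$selected           # 9 miRNAs, each targeting >= 5 haplo genes
res$candidates                 # genes hit by all 9, outside the region
res$report[, c("gene_id", "p_value", "call")]
```

which prints

```
cerna_candidates: 4 candidate(s) targeted by all 9 selected miRNAs
  DCX, GRAMD1B, HIPK2, SLC1A2

  gene_id     p_value call
1     DCX 0.185436283   NS
2 GRAMD1B 0.002454273 DOWN
3   HIPK2 0.045488662   UP
4  SLC1A2 0.604392395   NS
```

Sixteen of the 41 testable in-region genes are significantly reduced in
the deleted samples (none is significantly increased — consistent with
hemizygous loss). Nine miRNAs each target at least five of them and are
taken as released. Exactly four genes outside the region are predicted
targets of all nine; on validation, GRAMD1B is significantly down and
HIPK2 significantly up (p = 0.00245 and 0.04549), while DCX and SLC1A2
do not move and sit at the bottom of the intensity scale. The packaged
target wiring is synthetic (the original prediction-database snapshot is
not redistributable), so the 9-miRNA / 4-gene counts are properties of
the shipped fixture; the statistics are recomputed from the printed
group summaries.

`analysis/05_synthetic_benchmark.R` scores the pipeline against the
generator's ground truth over 50 seeded cohorts (released-miRNA and
ceRNA precision/recall, all 1.000 at default effect sizes) and checks
type-I calibration under a null configuration (~0.057 observed at
nominal 0.05).

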