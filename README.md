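# crossphos

Cross-species conservation screening of phosphosite antibody epitopes.

Phospho-specific antibodies detect a protein only when a given Ser/Thr/Tyr
residue is phosphorylated. Commercial collections target mammalian
proteins almost exclusively, yet the immunogen is a short contiguous
peptide (the phosphosite ±7 residues), so an antibody can cross-react with
an orthologous protein in another species when that peptide is conserved.
`crossphos` screens a whole phosphosite catalog for such candidates: it is
written for model-organism researchers hunting usable phospho-reagents and
for anyone curating antibody cross-reactivity predictions.

## Method

For each catalog site with flanking peptide *p* (15-mer, site at the
centre), the pipeline:

1. **anchors** *p* on the current sequence of its claimed protein
   (rescuing outdated accessions through the gene symbol, taking the
   longest matching isoform);
2. **resolves** the record to a gene id and **expands** it to
   target-species orthologs with confidence rank ≥ `min_rank`
   (high > moderate > low);
3. **aligns** the source protein to every target isoform with
   Needleman–Wunsch/Gotoh global alignment (affine gaps, BLOSUM62,
   open −10 / extend −0.5, end gaps penalised, pinned tie-breaks);
4. **scores** every window of length L ∈ {6,…,11} spanning the site:
   a window qualifies when all aligned positions are identical, or — under
   the relaxed rule — when exactly one position carries a conservative
   substitution at distance ≥ 2 from the site. Windows touching alignment
   gaps are disqualified. Per site×isoform the report carries

   * `identity_run` — the longest contiguous identical stretch through
     the site within the ±7 neighbourhood,
   * `best_strict` / `best_relaxed` — the largest qualifying window
     length under each rule (0 if none),
   * `qualifies_at_6` … `qualifies_at_11` — the monotone qualification
     flags,

   and a summary counts qualifying sites/genes per cutoff.

The 6–11 range is calibrated on 12 antibodies with validated fly
cross-reactivity, whose conserved regions span 6–15 residues
(`validated_epitope_pairs()`).

## Worked example

Score the validated epitope pairs (peptide-only mode — no proteome
needed):

```r
library(crossphos)
library(dplyr)

evaluate_peptide_pairs(validated_epitope_pairs()) |>
  select(source_gene, target_gene, identity_run, best_strict, best_relaxed)
#> # A tibble: 12 × 5
#>    source_gene target_gene identity_run best_strict best_relaxed
#>    <chr>       <chr>              <int>       <int>        <int>
#>  1 AKT1        Akt1                   6           6            6
#>  2 PRKAA1      AMPKalpha             14          11           11
#>  3 MAPK10      bsk                   11          11           11
#>  4 MAPK10      bsk                   13          11           11
#>  5 EIF2S1      eIF2alpha             15          11           11
#>  6 MAPK12      p38a                   6           6            6
#>  7 MAPK12      p38a                   6           6            6
#>  8 MAPK1       rl                    15          11           11
#>  9 MAPK1       rl                    15          11           11
#> 10 RPS6KB1     S6k                    8           8           10
#> 11 EIF4EBP1    Thor                   6           6            8
#> 12 EIF4EBP1    Thor                   7           7           11
```

`identity_run` is the conserved contiguous region through each
phosphosite: e.g. the AKT1 epitope shares a 6-residue identical stretch
with fly Akt1 (the shortest validated case), while the MAPK1 windows are
identical over all 15 positions. `best_strict` caps at 11 because 11 is
the largest scanned window. Where `best_relaxed` exceeds `best_strict`
(S6k, the two 4E-BP/Thor sites) a single conservative substitution away
from the site extends the qualifying window.

Run the full pipeline on a synthetic bundle with planted outcomes:

```r
b <- generate_bundle(
  plant_spec(c(0, 6, 8, 11), conservative_sub = c(FALSE, FALSE, TRUE, FALSE)),
  seed = 42
)
run <- run_pipeline(write_bundle(b, tempfile())$config)
#> records_read=4
#> anchored=4
#> gene_resolved=4
#> ortholog_mapped=4
#> aligned=4
#> qualifying_sites=3
run$summary
#> # A tibble: 6 × 4
#>   cutoff n_sites n_source_genes n_target_genes
#>    <int>   <int>          <int>          <int>
#> 1      6       3              3              3
#> 2      7       2              2              2
#> 3      8       2              2              2
#> 4      9       1              1              1
#> 5     10       1              1              1
#> 6     11       1              1              1
```

The level-0 plant (mutated site) never qualifies; the level-6, -8 and -11
plants qualify exactly up to their planted cutoffs. Real runs point a flat
key-value config at a phosphosite catalog, two proteome FASTA files, alias
maps and an ortholog table; see `?pipeline_config` and the shipped CLI
(`inst/exec/crossphos run --config <file>`).

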