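---
title: "Predicting cross-species reactivity of phosphosite antibodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cross-species reactivity of phosphosite antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossphos)
library(dplyr)
```

## The problem

Phospho-specific antibodies recognise a protein only when a particular
serine, threonine or tyrosine is phosphorylated. They are raised against a
short phosphopeptide immunogen, which makes them expensive to produce, and
commercial collections overwhelmingly target human, mouse and rat proteins.
Model-organism communities (fly, worm, fish, frog) have almost none.

Because the immunogen is a short contiguous peptide, an antibody raised
against a mammalian phosphosite has a fair chance of detecting the
orthologous protein in another species *if the peptide around the site is
conserved*. Antibodies with experimentally validated cross-reactivity on
*Drosophila* orthologs show conserved identical stretches through the site
as short as 6 residues and up to the full ±7 window. `crossphos` turns that
observation into a screen: given a phosphosite catalog with ±7-residue
flanking peptides, two proteomes, and a ranked ortholog table, it predicts
which catalog antibodies are plausible cross-reactive reagents in the
target species.

## The pipeline

Five stages, all deterministic:

1. **Site anchoring.** Each catalog row claims a residue and position on a
   protein accession, with the 15-character ±7 flanking peptide (`_`-padded
   at protein termini). The unpadded core peptide is searched in the
   current sequence of the claimed accession. If an occurrence places the
   phosphosite exactly at the claimed coordinate the site anchors
   *directly*; if the peptide occurs at exactly one place but the implied
   coordinate differs, the peptide wins (*position_shifted*) — the peptide
   is the actual immunogen, while coordinates drift between sequence
   releases. Records whose accession is stale fall back to a gene-symbol
   rescue: every protein of the symbol's gene is scanned, and among
   matching candidates the longest wins (ties by accession). Peptides
   occurring more than once in the selected protein fail as ambiguous —
   a guessed anchor would silently corrupt every downstream window.
2. **Gene resolution.** Accession first, then symbol, case-insensitively,
   against an alias→gene map; aliases mapping to two genes refuse to
   resolve rather than guess.
3. **Ortholog expansion.** A DIOPT-style pair table with confidence ranks
   (`high` > `moderate` > `low`); only pairs at or above `min_rank`
   (default `moderate`) pass, and one-to-many orthology is kept — every
   passing ortholog is evaluated. An optional paralog table with identical
   semantics can widen the expansion (off by default).
4. **Global alignment.** The anchored source protein is aligned against
   every isoform of each mapped target gene (Needleman–Wunsch/Gotoh,
   affine gaps, end gaps penalised). Evaluating all isoforms is deliberate:
   a conserved site present on several isoforms of different lengths
   predicts multiple bands on a Western blot.
5. **Window conservation.** For each cutoff L in 6–11, every length-L
   source window containing the site is projected through the alignment
   and tested; the report records the best qualifying length under strict
   identity and under a one-conservative-substitution relaxation, plus the
   contiguous identical run through the site, and a per-cutoff summary
   counts qualifying sites and genes.

## The conservation rules

A window *qualifies strictly* when every aligned position is identical.
The *relaxed* rule admits at most one conservative substitution, and only
at distance ≥ 2 from the phosphosite: the site itself must match (it is
the residue the phospho-specificity reads), and its immediate neighbours
are kept exact because they dominate the epitope's core. "Distance ≥ 2"
is the literal reading of "not right next to" the target residue.

What counts as a conservative replacement is a design decision, since no
single definition is canonical. The default is the classic
physicochemical classes {I,L,V,M}, {F,W,Y}, {K,R,H}, {D,E}, {S,T}, {N,Q},
{A,G}; a BLOSUM62-positive predicate is available via
`similarity_groups("blosum62_positive")`. Both are symmetric and
irreflexive. Results at strict identity are unaffected by this choice, and
both statistics are always reported side by side.

Windows are enumerated on the source coordinate system and must be
gap-free in both alignment rows; a window touching any gap column is
disqualified rather than re-spliced, because an epitope is a contiguous
peptide and a gap breaks contiguity. The contiguous-identity run is
computed over the ±7 aligned neighbourhood of the site and truncates at
the first gap column on either side. A site aligned to a gap scores zero
everywhere.

The 6–11 cutoff range is anchored by the validated cross-reactive
antibodies: the shortest conserved region among them is 6 residues.

```{r golden}
evaluate_peptide_pairs(validated_epitope_pairs()) |>
  select(source_gene, target_gene, identity_run, best_strict, reported_run)
```

## Alignment parameters

The method's downstream statistic is identity within short windows, so it
is robust to any reasonable protein scoring scheme; the scheme is pinned
only for reproducibility. Defaults: BLOSUM62, gap open −10, gap extend
−0.5 — the de-facto global-alignment default. A gap of length *k* costs
`gap_open + (k − 1) * gap_extend` (the first gap column carries the open
penalty), and a gap in the other row always opens anew. Traceback
tie-breaks are pinned — match state over gap-in-target over gap-in-source,
both for the final state and for every predecessor — so alignments are
bit-reproducible. Residues absent from the matrix (e.g. `U`) score at the
matrix minimum instead of failing. Empty sequences are a precondition
error; anchoring failures, by contrast, are data (tallied reasons), since
they are expected in real catalogs.

Coordinates everywhere in the R interface are 1-based (the centre of a
15-mer is position 8), matching R and Bioconductor convention.

## The synthetic generator

Real inputs for this screen are large external releases (a phosphosite
catalog, proteomes, an ortholog database), so correctness is demonstrated
by *parameter recovery on planted data*. `generate_bundle()` builds a
catalog, two proteomes, identifier maps and a ranked ortholog table in
which every site has a designed outcome:

* a planted *level* ℓ builds an identity span of length ℓ through the
  site, bounded on both sides by non-conservative mismatches, inside
  otherwise identical random context — so the best qualifying window is
  exactly ℓ (or 0 below the smallest cutoff);
* `conservative_sub` plants reach ℓ only through one in-group substitution
  at distance ≥ 2, separating the strict and relaxed statistics;
* `break_adjacency` plants put the conservative substitution at distance
  1, immediately outside an identical run of length ℓ: an implementation
  ignoring the adjacency rule reports ℓ + 1, the correct one reports ℓ.
  Such plants are refused at level 11, where the violating window would
  exceed the largest cutoff and demonstrate nothing;
* `stale_accession` plants write an outdated accession into the catalog,
  forcing the gene-symbol rescue path end-to-end.

Expected outcomes are recorded from the construction itself (direct
positional enumeration on the planted sequences), not from the pipeline,
so recovery tests compare two independent routes. Random context is
re-drawn whenever it would create a second occurrence of a site's core
peptide, protecting the ambiguity contract from flaky collisions. Bundles
are byte-deterministic under their seed.

What the generator does **not** emulate: insertions/deletions near planted
sites (alignment gaps are exercised by dedicated unit fixtures instead),
realistic amino-acid composition or homology structure, many-to-many
ortholog webs, or catalog dialect quirks beyond the standard one
(preamble banners, lowercase site residue, `_` padding, multi-antibody
cells). Passing recovery therefore validates the machinery — parsing,
anchoring, mapping, alignment, window logic — under controlled truth, not
the biological error rate on real proteomes.

Validation problem sizes: recovery runs use ~50 planted sites on ~75–110
residue proteins (one or two isoforms per target gene), the alignment
oracle enumerates every global alignment for a few thousand random pairs
up to length 6 over a 4-letter alphabet, and the anchoring round-trip
plants 1,000 random sites including termini. These sizes keep the whole
suite under a minute while covering every code path; the pipeline itself
scales to real proteomes (alignment is the only super-linear step and is
cached per protein pair).

```{r recovery}
b <- generate_bundle(
  plant_spec(c(0, 6, 8, 11), conservative_sub = c(FALSE, FALSE, TRUE, FALSE)),
  seed = 42
)
dir <- tempfile()
run <- run_pipeline(write_bundle(b, dir)$config, quiet = TRUE)
run$report |>
  select(source_gene, site_label, identity_run, best_strict, best_relaxed)
b$expected |>
  select(gene_symbol, level, expected_best_strict, expected_best_relaxed)
```

## Counting conventions

The per-cutoff summary collapses isoforms to genes: `n_sites` counts
distinct catalog sites (source organism × gene × site label) with at
least one qualifying site×isoform row, and `n_source_genes` /
`n_target_genes` count genes carrying such a site. Counts are monotone
non-increasing in the cutoff by construction (a qualifying length-L+1
window always contains a qualifying length-L window). Whether published
per-cutoff gene counts used the strict or the relaxed rule — and which
isoform mode — is not always stated in the field, so both statistics are
always emitted and both isoform modes are available (`all` for scoring,
`longest` for the per-gene convention).

## Known limitations

* Sequence conservation is necessary but not sufficient for
  cross-reactivity: epitope accessibility, neighbouring modifications and
  antibody-specific behaviour are outside the model. Predictions are
  screening candidates, not validations.
* The relaxed rule admits exactly one substitution; multiple conservative
  replacements within an otherwise perfect window never qualify.
* Anchoring requires an exact core-peptide match (cores shorter than 4
  residues after unpadding are rejected as unanchorable); heavily diverged
  or heavily edited catalog entries fail into the tally rather than being
  fuzzily matched.
* Dual-site antibodies are evaluated per catalog site; no merging
  semantics are attempted.
* The screen is deterministic; there is no statistical model and no
  p-value — the output is a qualification table, not an inference.
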