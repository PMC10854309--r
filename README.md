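# clonotrace

Clonal lineage tracing of paired single-cell TCR and expression data
across matched tissue compartments, such as brain parenchyma and
leptomeninges in neurodegenerative disease.

Every T cell carries a heritable receptor sequence, so the paired
alpha/beta TCR acts as a natural lineage barcode: cells in two tissues
with the identical receptor are progeny of one ancestral clone.
`clonotrace` turns that observation into an analysis pipeline:

* **Ingest** — reads 10x `filtered_contig_annotations.csv` and AIRR
  Rearrangement TSVs, keeps cells with exactly one productive TRA and
  one productive TRB chain, and reports a per-sample pairing audit
  (kept / missing-chain / multi-chain).
* **Clonotyping** — calls clones by strict field-wise VDJC gene +
  CDR3 *nucleotide* identity on both chains (synonymous CDR3 variants
  are distinct clones), and classifies expansion as singleton /
  expanded / hyperexpanded (≥ 5% of the sample).
* **Diversity strata** — Shannon entropy (nats) per sample, optional
  rarefaction, and within-disease stratification into Superexpanded /
  Expanded around the group mean (median for configured groups), with
  ANOVA + Holm-adjusted pairwise tests between disease groups.
* **Lineage tracing** — flags meningeal clones found in the matched
  brain repertoire by exact identity, summarises what fraction of
  shared clones is expanded (clone-wise and cell-wise), and quantifies
  abundance-weighted overlap with the bounded Morisita-Horn index.
* **CDR3 homology** — Levenshtein distance matrix over the beta-chain
  CDR3s of clones with ≥ 10 cells, tagged per sample, reporting
  cross-sample near-identical pairs.
* **Phenotype link** — MatrixMarket reader, QC (≥ 200 features,
  ≤ 10% mitochondrial, genes in ≥ 3 cells, iterated to a fixed point),
  log-normalisation, and Wilcoxon rank-sum differential expression with
  Benjamini-Hochberg adjustment between clonal categories.
* **Synthetic cohorts** — a seed-deterministic generator with known
  ground truth (zipf clone sizes, size-coupled tissue sharing, planted
  marker genes) plus plain-text fixture writers, so the whole pipeline
  is testable offline.

See the vignette (`vignettes/clonal-lineage-tracing.Rmd`) for the
model, parameter choices and limitations.

## Worked example

Simulate a small two-patient cohort, call clones, and trace patient
P01's meningeal clones into the matched brain repertoire:

```r
library(clonotrace)

params <- sim_params(n_patients = 2, diseases = c(ALS = -0.6, LOAD = 0.3),
                     cells_per_tissue = 120, n_genes = 40, seed = 7)
sim <- simulate_repertoires(params)
cc <- call_clones(sim$cells)

men <- cc$repertoires[["MEN_P01"]]
brn <- cc$repertoires[["BRN_P01"]]
men
#> repertoire 'MEN_P01' (P01, meninges, ALS): 120 cells, 7 clones

round(c(entropy = shannon_entropy(men),
        top_clone = top_clone_fraction(men),
        morisita = morisita_overlap(men, brn)), 4)
#>   entropy top_clone  morisita
#>    1.1631    0.5500    0.9933

head(classify_expansion(men), 4)
#>   clone_id count  frequency     expansion
#> 1   C00008     5 0.04166667      expanded
#> 2   C00010    66 0.55000000 hyperexpanded
#> 3   C00025     4 0.03333333      expanded
#> 4   C00033     3 0.02500000      expanded

flags <- flag_shared_clones(men, brn)
summarize_shared_expansion(men, flags, classify_expansion(men))
#>   patient_id n_meningeal_cells n_meningeal_singleton_cells n_shared_clones
#> 1        P01               120                           1               5
#>   n_shared_clones_expanded_in_meninges fraction_shared_expanded_clonewise
#> 1                                    5                                  1
#>   fraction_shared_expanded_cellwise
#> 1                                 1
```

This ALS patient's meningeal repertoire is highly concentrated (one
clone holds 55% of cells, entropy 1.16 nats) and all five brain-shared
clones are expanded — the pattern the lineage-tracing statistics are
designed to surface.

For an end-to-end run over written fixture files (ingest through
differential expression, with a reproducible manifest):

```r
co <- simulate_cohort(sim_params(seed = 1))
write_fixtures(co, "fixtures")
paths <- list.files("fixtures/contigs_10x", full.names = TRUE)
names(paths) <- sub("\\.csv$", "", basename(paths))
run_pipeline(run_config(contigs = paths,
                        metadata = "fixtures/metadata.tsv",
                        expression = "fixtures/expression",
                        out_dir = "out", seed = 1))
```

A thin command-line front-end with `simulate` and `run` verbs is
installed at `inst/cli/clonotrace.R`.

## Tests

```r
testthat::test_dir("tests/testthat", package = "clonotrace",
                   load_package = "installed")
```

The suite property-tests each stage (conservation and permutation
invariance of clone calling, entropy closed forms, Morisita-Horn
identities on random count vectors, Levenshtein metric axioms against
independent oracles, DE calibration under the generator's null,
byte-identical pipeline reruns).

## License

MIT — see `LICENSE`.
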