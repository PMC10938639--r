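# pfastriage

In silico triage of per- and polyfluoroalkyl substances (PFASs) against
ten nuclear receptors (AR, ERA, ERB, GR, PR, PPARA, PPARD, PPARG, MR,
RXRA), for computational toxicologists and cheminformaticians who need a
reproducible, auditable pipeline around their docking and
machine-learning engines.

A virtual-screening campaign for endocrine-disrupting PFASs produces
per-chemical docking scores and MM-GBSA binding free energies (kcal/mol,
more negative = stronger) plus activity-model labels. `pfastriage`
implements everything around those engines:

* **Curation** — inclusion filters for a raw SMILES/SDF library (must
  parse, must contain a perfluorinated CF2/CF3 unit, must carry ≥ 3
  fluorines; duplicates removed by InChIKey) with a full audit trail;
  nothing is silently dropped.
* **Triage** — a candidate is *shortlisted* when both scores lie within
  10% of the best reference-ligand value
  (`x ≤ 0.9 · x_ref_best`, both metrics conjunctively); its binder
  strength comes from the percent change against the reference mean,
  `pc = 100 (x − x̄_ref) / x̄_ref`, averaged over the two metrics:
  strong if > 0, moderate in (−10, 0], weak ≤ −10.
* **Consensus calling** — shortlisted chemicals at the eight receptors
  with activity models become actives only when the model labels them
  agonist / antagonist / agonist–antagonist / active; MR and PPARA
  (no models) are called on the shortlist alone. Per-receptor summary
  tables partition the actives by call type.
* **Taxonomy** — an ordered SMARTS-rule hierarchy (shipped as editable
  YAML) assigns primary/secondary PFAS classes: side-chain aromatics,
  PFCAs/PFSAs, the FASA family, fluorotelomers, sulfonyl fluorides,
  other aliphatics.
* **Chemical space** — ECFP4 fingerprints and a deterministic batch
  Kohonen self-organizing map with activity overlays.
* **Interaction fingerprints** — residue-level hydrophobic-contact and
  hydrogen-bond bits from PDB complexes, compared by Tanimoto
  similarity.
* **Synthetic data** — a seeded generator that emulates every upstream
  input with planted ground truth, so the whole pipeline is testable
  offline.

See the methods vignette (`vignettes/pfas-triage-methods.Rmd`) for the
model details and design rationale.

## Worked example

```r
library(pfastriage)

cfg <- synth_config(seed = 1, n_chemicals = 200, decoy_fraction = 0.25)
lib <- generate_pfas_library(cfg)
rec <- apply_inclusion_filters(lib$entries)
curation_audit(rec)
#>              reason   n
#> 1              none 150
#> 2       unparseable   0
#> 3 no_perfluoro_unit  25
#> 4 too_few_fluorines  13
#> 5         duplicate  12
```

150 of 200 entries survive curation; each excluded entry carries exactly
one reason, and the counts sum to the library size. Triaging synthetic
score tables against the reference ligands, gated by the activity labels:

```r
st  <- generate_score_tables(cfg, rec$source_id[rec$included])
ml  <- generate_ml_labels(st$truth, ml_error_rate = 0, seed = 1)
calls <- triage_calls(st$candidates, compute_reference_stats(st$references), ml)
head(summarize_counts(calls)$by_receptor, 4)
#>   receptor n_ago_ant n_antagonist n_agonist n_active n_total_active
#> 1       AR         7            7         8        0             22
#> 2      ERA         7            7         8        0             22
#> 3      ERB         7            7         8        0             22
#> 4       GR         7            7         8        0             22
```

Each row partitions a receptor's predicted actives by call type; the
total is the row sum. Classifying the curated library:

```r
head(class_distribution(classify_pfas(rec)), 5)
#>                   primary_class secondary_class  n
#> 1              Other_aliphatics          Others 39
#> 2                         PFAAs           PFCAs 39
#> 3          Side_chain_aromatics          Others 21
#> 4    FASA_based_PFAA_precursors           FASAs 15
#> 5 Fluorotelomer_PFAA_precursors           FTOHs 15
```

The full pipeline — curation → taxonomy → triage → summaries → map —
runs from a YAML config and writes CSV artifacts plus a hashed manifest:

```r
run_pipeline("run.yaml", "results/")
```

or from a shell via the thin wrapper
`Rscript inst/scripts/pfas-triage.R --config run.yaml --out results/`.

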