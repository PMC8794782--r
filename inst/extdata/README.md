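# Bundled fixtures

- `candidate_gene_flags.tsv` — curated scorecard inputs for eight positional
  candidate genes of four mouse metabolic-syndrome QTL (Gatlgq, Gatq1,
  Bwq26, Gatq2), used as a regression fixture for the prioritization
  decision tree. Category flags follow the published variant-annotation
  descriptions of these genes; the `de_any` flags follow the published
  adjusted expression p-values; the `kegg` flags are reconstructed (the
  original per-gene pathway list is not public) as the unique assignment
  consistent with the published gene scores under category-once scoring,
  and `expected_score` records those published scores.
- `demo_config.yaml` — a small end-to-end configuration for
  `run_pipeline()` on fully synthetic data.
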