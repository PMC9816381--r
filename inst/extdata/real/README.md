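# Real-data inputs (user-supplied; none are shipped)

The package's toy pipeline runs fully offline. Reproducing the published
per-domain identity/RMSD table, the GluN2B→GluN2A mapping checks and the
database-wide concordance figures additionally needs the experimental
structures and curated tables, which must be fetched by the user and placed
in this directory:

- `6ira.cif` — human GluN1/GluN2A diheteromeric NMDAR structure
  (https://www.rcsb.org/structure/6IRA)
- `6whr.cif` — rat GluN1/GluN2B diheteromeric NMDAR structure
  (https://www.rcsb.org/structure/6WHR)
- `canonical.fasta` — canonical human sequences named `GluN1`, `GluN2A`,
  `GluN2B` (UniProt Q05586, Q12879, Q13224), plus `GluN2B_rat` (Q00960)
  for renumbering the rat construct
- `domains.json` — OPM-derived domain ranges in the schema of
  `../domains_synthetic_example.json` (canonical numbering, 1-based
  inclusive, ATD split into ATD1/ATD2 sublobes; LBD and TMD discontinuous)
- `variants.tsv` — variant annotation table
  (`gene  hgvs_p  pathogenicity  functional`, tab-separated, `.` = missing)

When present, `tests/testthat/test-acceptance.R` and the vignette's
real-data section pick them up automatically; when absent, the toy-scale
checks still run and the real-data checks report failure rather than
silently passing.
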