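# Study data drop-in directory

The package's data-dependent acceptance checks recompute the published
cohort results from the original deposited tables. Those tables are not
redistributed with the package; to run the checks, download the study's
supplementary material and analysis sources from its online repository and
place the following plain-text files here:

- `normalized_expression.tsv` — the deposited normalized miRNA
  quantification table, reshaped to samples as rows: first column
  `sample_id`, one column per miRNA assay, values on the relative
  expression scale (2^-dCq).
- `samples.tsv` — columns `sample_id` and `group` with the cohort labels
  (`HT` / `non-HT`).
- `raw_cq.tsv` — the raw Cq export, samples as rows, first column
  `sample_id`, blank cells for "not detected".
- `assay_roles.tsv` — columns `assay_id` and `role`
  (`target` / `reference` / `hemolysis_marker` / `spike_in`) marking the
  three reference miRNAs, the miR-451a hemolysis marker and the UniSp
  spike-ins.

Without these files the corresponding tests in
`tests/testthat/test-acceptance.R` report failure with a message pointing
here; every other test is self-contained.
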