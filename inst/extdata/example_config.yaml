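# Example pipeline configuration; paths are relative to the run directory.
inputs:
  week0: fixtures/species_week0.tsv
  week16: fixtures/species_week16.tsv
  markers0: fixtures/markers_week0.tsv
  markers16: fixtures/markers_week16.tsv
  meta: fixtures/samples.tsv
  casecohort: fixtures/casecohort.tsv
output_dir: results
seed: 1
missingness_threshold: 0.75
retain_min: 9
folds: 10
train_fraction: 0.8
fdr_q: 0.05
stages:
  diet_effects: true
  enr: true
  casecohort: true
markers: [ldl]
cox_covariates: [sex, waist, smoking]
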