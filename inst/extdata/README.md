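# Bundled data files

- `ija1121_conditions.tsv` — chemostat growth conditions for
  *B. megaterium* DSM319 and its derivative strains (MS941, WH320, WH323):
  measured specific growth rate (`observed`, 1/h) and glucose/acetate
  uptake rates (mmol/gDW/h) used as medium bounds. Column headers use the
  generic exchange ids `EX_glc` / `EX_ac`; rename them to the exchange ids
  of the model you validate against before calling
  `predicted_vs_observed()`.
- The genome-scale SBML model itself (`iJA1121.xml`) is distributed as the
  publication's supplementary dataset and is not bundled; place it in this
  directory to enable the genome-scale validation paths.
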