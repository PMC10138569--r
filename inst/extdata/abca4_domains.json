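{
  "comment": "Approximate ABCA4 domain boundaries (author/UniProt residue numbering). Boundaries are not published to residue precision; these ranges follow the canonical ECD1-TMD1-NBD1-R1-ECD2-TMD2-NBD2-R2 domain order of the full-length transporter and place every residue discussed in the reference cohort in its expected domain. Treat as approximate.",
  "IH1":  [1, 23],
  "TMD1": [[24, 43], [646, 855]],
  "ECD1": [44, 645],
  "NBD1": [856, 1344],
  "R1":   [1345, 1374],
  "TMD2": [[1375, 1397], [1672, 1895]],
  "ECD2": [1398, 1671],
  "NBD2": [1896, 2158],
  "R2":   [2159, 2273],
  "substrate_codes": ["NRPE", "RET", "LIG"]
}
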