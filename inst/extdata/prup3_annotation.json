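{
  "accession": "Q9LED1",
  "note": "Synthetic verified reconstruction of the 91-residue mature Pru p 3 chain (Pru p 3.0102 numbering frame). Gated by the boundary self-checks below at load time.",
  "length": 91,
  "numbering_origin": 1,
  "epitopes": ["A11-G20", "I31-T40", "G71-K80"],
  "disulphides": [[3, 50], [13, 27], [28, 73], [48, 87]],
  "disulphide_note": "Canonical plant nsLTP1 pairing C1-C6, C2-C3, C4-C7, C5-C8.",
  "boundary_checks": ["I1-A26", "I1-N29", "C50-Y79", "L51-V61", "Q53-K72",
                      "S55-K72", "A66-K91", "N86-K91"],
  "phosphoserines": [55, 57, 82]
}
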