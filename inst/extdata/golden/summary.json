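{
  "genes_total": 30,
  "genes_selected": 27,
  "pct_selected": 90,
  "eisa": {
    "n_tested": 27,
    "n_called": 9,
    "pct_called": 33.3
  },
  "de": {
    "n_genes": 27,
    "n_de": 7,
    "pct_de": 25.9,
    "up_in_young": 2,
    "up_in_expanded": 5
  },
  "overlap_eisa_de": {
    "n_eisa": 9,
    "n_de": 7,
    "n_overlap": 6,
    "pct_eisa_also_de": 66.7,
    "overlap_up_in_young": 2,
    "overlap_up_in_expanded": 4
  },
  "cross_species": {
    "n_called_a": 9,
    "n_called_b": 5,
    "n_pairs": 30,
    "n_shared_pairs": 3,
    "n_shared_genes_a": 3
  }
}
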