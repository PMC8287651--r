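# Bundled data files

- `wbc_synthetic.data` — **synthetic** stand-in for the classic Wisconsin
  breast-cancer table, generated with `gspsvm::synth_binary()` (seed 683,
  separation 5, noise SD 2) and post-edited so exactly 16 of its 699
  records carry a `"?"` token in the bare-nuclei slot (column 7 of the
  raw file). Structure matches the documented original — comma-delimited,
  ID column, nine ordinal attributes in [1,10], 2/4 class coding — but
  the values are not clinical data.
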