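# Synthetic alternative utility bundle for sensitivity analysis.
# Stands in for an alternative published utility source (SF-36-derived
# rather than EQ-5D-derived); values here are constructed, not published.
# Apply with: load_parameters(this_file) or perturb() on utilities.by_cd4.
utilities:
  by_cd4:
    le50: 0.760
    c51_100: 0.800
    c101_200: 0.830
    gt200: 0.880
  by_oi:
    bacterial: 0.561
    fungal: 0.652
    protozoal: 0.652
    viral: 0.561
    other: 0.561
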