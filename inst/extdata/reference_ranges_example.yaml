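# EXAMPLE blood reference ranges (synthetic illustration mirroring typical
# Dutch hospital intervals).  These are documentation/example values only:
# every application must substitute the ranges of the laboratory that
# analysed the samples.  Units follow the panel columns:
# vitamin B6 nmol/L (whole blood), folate nmol/L, vitamin B12 pmol/L,
# 25(OH) vitamin D nmol/L, haemoglobin mmol/L, ferritin ug/L.
ranges:
  vitb6_nmol_l:
    any: {low: 35, high: 110}
  folate_nmol_l:
    any: {low: 10, high: 45}
  vitb12_pmol_l:
    any: {low: 150, high: 650}
  vitd_nmol_l:
    any: {low: 50, high: 250}
  hb_mmol_l:
    male: {low: 8.5, high: 11.0}
    female: {low: 7.5, high: 10.0}
  ferritin_ug_l:
    male: {low: 25, high: 250}
    female: {low: 20, high: 150}
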