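# Recommended dietary allowances used to scale the 0-10 micronutrient and
# protein compliance scores (score = 10 * min(intake/RDA, 1)).
# Values follow adult Dutch reference intakes; configuration data.
rda:
  vitb6_mg:     {value: 1.5,  unit: mg/day}
  folate_eq_ug: {value: 300,  unit: ug/day}
  vitb12_ug:    {value: 2.8,  unit: ug/day}
  vitd_ug:      {value: 10,   unit: ug/day}
  iron_mg:      {value: 11,   unit: mg/day}
  protein_g:    {value: 0.8,  unit: g/kg/day, per_kg: true}
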