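# DHD2015-index component definitions: 16 components, each scored 0-10,
# total 0-160.  Cut-offs reproduce the Dutch 2015 dietary-guideline values
# (vegetables 200 g/d, fruit 200 g/d, wholegrain 90 g/d, ...); they are
# configuration data and can be overridden wholesale.
#
# kinds:
#   adequacy   10 * min(intake/threshold, 1)           more is better, capped
#   moderation 10 at <= lower, 0 at >= upper, linear   less is better
#   optimum    0 at <= low0, 10 on [opt_low, opt_high], 0 at >= high0
#   ratio      10 * min(value/threshold, 1) on a derived soft:solid fat
#              ratio; no solid fat at all counts as full compliance
#   binary     10 if intake <= cutoff else 0
# basis: amount    -> intake in g/day   (weight * freq/7 * amount)
#        frequency -> intake in occasions/week (weight * freq)
components:
  - {id: vegetables,     label: "Vegetables",                            kind: adequacy,   basis: amount,    threshold: 200}
  - {id: fruits,         label: "Fruits",                                kind: adequacy,   basis: amount,    threshold: 200}
  - {id: wholegrain,     label: "Wholegrain products",                   kind: adequacy,   basis: amount,    threshold: 90}
  - {id: legumes,        label: "Legumes",                               kind: adequacy,   basis: amount,    threshold: 10}
  - {id: nuts,           label: "Nuts",                                  kind: adequacy,   basis: amount,    threshold: 15}
  - {id: dairy,          label: "Dairy",                                 kind: optimum,    basis: amount,    low0: 0, opt_low: 300, opt_high: 450, high0: 750}
  - {id: fish,           label: "Fish",                                  kind: adequacy,   basis: amount,    threshold: 15}
  - {id: tea,            label: "Tea",                                   kind: adequacy,   basis: amount,    threshold: 450}
  - {id: fats_oils,      label: "Fats and oils",                         kind: ratio,      basis: amount,    threshold: 13}
  - {id: coffee,         label: "Coffee",                                kind: binary,     basis: frequency, cutoff: 0}
  - {id: red_meat,       label: "Red meat",                              kind: moderation, basis: amount,    lower: 45, upper: 100}
  - {id: processed_meat, label: "Processed meat",                        kind: moderation, basis: amount,    lower: 0, upper: 50}
  - {id: sweet_drinks,   label: "Sweetened beverages and fruit juices",  kind: moderation, basis: amount,    lower: 0, upper: 250}
  - {id: alcohol,        label: "Alcohol",                               kind: moderation, basis: amount,    lower: 10, upper: 30}
  - {id: salt,           label: "Salt",                                  kind: moderation, basis: amount,    lower: 6, upper: 12}
  - {id: unhealthy,      label: "Unhealthy foods",                       kind: moderation, basis: frequency, lower: 3, upper: 10}
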