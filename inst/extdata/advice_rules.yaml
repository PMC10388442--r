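# Rule-based dietary advice templates.  Content is configuration data:
# wording here is illustrative, not the production tool's text.  Each
# template has an omnivore variant and, where the suggestion differs for
# vegetarians, a vegetarian variant (vegetarians fall back to the
# omnivore text otherwise; flexitarians receive the omnivore variant).
diet_threshold: 8   # component / nutrient scores below this trigger advice

components:
  vegetables:     {omnivore: "Aim for at least 200 g of vegetables per day."}
  fruits:         {omnivore: "Aim for at least 200 g of fruit per day."}
  wholegrain:     {omnivore: "Choose wholegrain bread, pasta and cereals."}
  legumes:        {omnivore: "Eat legumes (beans, lentils) at least weekly."}
  nuts:           {omnivore: "Eat a small handful of unsalted nuts daily."}
  dairy:          {omnivore: "Take a few portions of dairy, such as milk or yoghurt, per day.",
                   vegetarian: "Take a few portions of dairy per day; fortified soy drink also counts."}
  fish:           {omnivore: "Eat fish weekly, preferably fatty fish.",
                   vegetarian: "Consider algae-based omega-3 sources instead of fish."}
  tea:            {omnivore: "Drink three cups of green or black tea daily."}
  fats_oils:      {omnivore: "Replace butter and hard margarine with soft margarine or oil."}
  coffee:         {omnivore: "Choose filtered coffee over unfiltered."}
  red_meat:       {omnivore: "Limit red meat to modest portions.",
                   vegetarian: "Keep using plant-based alternatives to red meat."}
  processed_meat: {omnivore: "Limit processed meat as much as possible.",
                   vegetarian: "Keep avoiding processed meat."}
  sweet_drinks:   {omnivore: "Limit sugary drinks and fruit juice; drink water or tea."}
  alcohol:        {omnivore: "Do not drink alcohol, or no more than one glass a day."}
  salt:           {omnivore: "Use little added salt and few ready-made products."}
  unhealthy:      {omnivore: "Limit snacks, sweets and fast food to a few times per week."}

nutrients:
  vitb6_mg:     {omnivore: "Increase vitamin B6 intake: fish, meat, potatoes, bananas.",
                 vegetarian: "Increase vitamin B6 intake: bananas, potatoes, legumes, nuts."}
  folate_eq_ug: {omnivore: "Increase folate intake: green vegetables, legumes, wholegrains."}
  vitb12_ug:    {omnivore: "Increase vitamin B12 intake: fish, meat, dairy, eggs.",
                 vegetarian: "Increase vitamin B12 intake: dairy, eggs or fortified products."}
  vitd_ug:      {omnivore: "Increase vitamin D intake: fatty fish and fortified margarine.",
                 vegetarian: "Increase vitamin D intake: fortified margarine; consider supplementation in winter."}
  iron_mg:      {omnivore: "Increase iron intake: red meat, wholegrains, legumes.",
                 vegetarian: "Increase iron intake: legumes, wholegrains, nuts; combine with vitamin-C-rich foods."}
  protein_g:    {omnivore: "Increase protein intake: dairy, fish, meat, legumes.",
                 vegetarian: "Increase protein intake: dairy, eggs, legumes, soy products."}

analytes:
  vitb6_nmol_l:
    nutrient: vitb6_mg
    below: {omnivore: "Blood vitamin B6 is below the reference range; improve dietary vitamin B6 intake."}
    above: {omnivore: "Blood vitamin B6 is above the reference range; review supplement use - high-dose vitamin B6 can be harmful."}
  folate_nmol_l:
    nutrient: folate_eq_ug
    below: {omnivore: "Blood folate is below the reference range; improve dietary folate intake."}
    above: {omnivore: "Blood folate is above the reference range; review supplement use."}
  vitb12_pmol_l:
    nutrient: vitb12_ug
    below: {omnivore: "Blood vitamin B12 is below the reference range; improve dietary vitamin B12 intake.",
            vegetarian: "Blood vitamin B12 is below the reference range; as a vegetarian, use fortified products or discuss supplementation."}
    above: {omnivore: "Blood vitamin B12 is above the reference range; review supplement use."}
  vitd_nmol_l:
    nutrient: vitd_ug
    below: {omnivore: "Blood vitamin D is below the reference range; improve intake and consider safe sun exposure."}
    above: {omnivore: "Blood vitamin D is above the reference range; review supplement use."}
  hb_mmol_l:
    nutrient: iron_mg
    below: {omnivore: "Haemoglobin is below the reference range; improve dietary iron intake.",
            vegetarian: "Haemoglobin is below the reference range; improve plant-based iron intake and combine with vitamin C."}
    above: {omnivore: "Haemoglobin is above the reference range; discuss with a physician."}
  ferritin_ug_l:
    nutrient: iron_mg
    below: {omnivore: "Ferritin is below the reference range: iron stores are depleted; improve dietary iron intake.",
            vegetarian: "Ferritin is below the reference range; improve plant-based iron intake and combine with vitamin C."}
    above: {omnivore: "Ferritin is above the reference range; review supplement use and discuss with a physician."}
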