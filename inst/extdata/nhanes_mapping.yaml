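# Example column mapping for a day-1 total-nutrient export in the style of
# the NHANES DR1TOT files (exported to delimited text). Source variables are
# already in the canonical units except where a factor says otherwise.
columns:
  SEQN:     {target: subject_id}
  DR1TKCAL: {target: energy_kcal}
  DR1TCARB: {target: carbohydrate_g}
  DR1TPROT: {target: protein_g}
  DR1TTFAT: {target: fat_total_g}
  DR1TSFAT: {target: fat_sat_g}
  DR1TFIBE: {target: fiber_g}
  DR1TSUGR_ADDED: {target: added_sugar_g}
  DR1TSODI: {target: sodium_mg}
  DR1TPOTA: {target: potassium_mg}
  DR1TCALC: {target: calcium_mg}
  DR1TMAGN: {target: magnesium_mg}
  DR1TIRON: {target: iron_mg}
  DR1TFF:   {target: folate_food_ug}
  DR1TVARA: {target: vit_a_ug_rae}
  DR1TVD:   {target: vit_d_ug}
  DR1TATOC: {target: vit_e_mg}
  DR1TVC:   {target: vit_c_mg}
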