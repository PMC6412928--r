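# Synthetic diet archetypes. Everything in this file is synthetic: the bands
# were designed once, in breakpoint-anchored coordinates, to emulate cohorts
# of known diet quality; no archetype is transcribed from any real menu or
# survey table.
#
# Band endpoints are "m*X" expressions where X is a breakpoint anchor of the
# nutrient's piecewise score (A, B, C, D for adequacy; B, C for moderation)
# and m a non-negative multiplier; "0" is allowed. A day's amount is drawn
# uniformly inside the band (Gaussian-copula correlation across nutrients
# when `correlation` is present), then multiplied by a lognormal day-to-day
# jitter with coefficient of variation `noise_cv`. Percent-of-energy
# nutrients are sampled on the percent scale and converted to grams with the
# day's sampled energy. `energy_band` is in multiples of the profile's EER.
#
# `default` is the band applied to every nutrient not listed explicitly;
# `adequacy`/`moderation` defaults split by shape.
archetypes:
  plateau:
    description: Every nutrient inside its healthy range, energy within 15% of EER.
    noise_cv: 0.0
    energy_band: ["0.87", "1.13"]
    default:
      adequacy: ["B", "C"]
      moderation: ["0", "B"]
  deficient:
    description: All adequacy nutrients at or below half their reference; energy at EER.
    noise_cv: 0.0
    energy_band: ["1.0", "1.0"]
    default:
      adequacy: ["0", "A"]
      moderation: ["0", "0.5*B"]
  excess:
    description: Everything past the zero-score ceiling; energy far above EER.
    noise_cv: 0.0
    energy_band: ["1.5", "1.8"]
    default:
      adequacy: ["D", "1.5*D"]
      moderation: ["C", "2*C"]
  nhanes_like:
    description: >
      Synthetic typical-US cohort: shortfalls in fiber, potassium, folate,
      vitamins A/D/E, excess sodium and added sugars, macronutrients mostly
      in range. Bands were set once so that the cohort mean total for the
      default female 31-50 profile lands in 0.40-0.55. Energy is kept inside
      the plausible range so the contrast with exemplary diets reflects
      nutrient quality, not energy.
    noise_cv: 0.15
    energy_band: ["0.85", "1.15"]
    default:
      adequacy: ["B", "C"]
      moderation: ["0", "B"]
    bands:
      carbohydrate: ["0.8*B", "C"]
      protein: ["0.9*B", "0.8*C"]
      fat_total: ["B", "1.6*C"]
      fat_sat: ["0.5*B", "1.4*B"]
      added_sugar: ["B", "2*B"]
      sodium: ["0.75*B", "1.75*B"]
      fiber: ["0.3*B", "0.9*B"]
      potassium: ["0.4*B", "0.8*B"]
      calcium: ["0.4*B", "1.2*B"]
      magnesium: ["0.4*B", "1.2*B"]
      iron: ["0.3*B", "1.1*B"]
      folate_food: ["0.2*B", "0.85*B"]
      vit_a: ["0.1*B", "0.9*B"]
      vit_c: ["0", "1.4*B"]
      vit_d: ["0", "0.7*B"]
      vit_e: ["0.1*B", "0.85*B"]
    correlation:
      clusters:
        - nutrients: [potassium, magnesium, folate_food, fiber]
          rho: 0.6
        - nutrients: [vit_a, vit_d, calcium]
          rho: 0.5
  myplate_like:
    description: >
      Synthetic exemplary-menu archetype (not a transcription of any
      published menu): vitamins and minerals mostly at 100-175% of
      reference, vitamin C well above requirements, vitamin D low, vitamin E
      slightly short, moderation nutrients at or below their limits,
      macronutrients mid-range, energy close to 2000 kcal for the default
      profile.
    noise_cv: 0.12
    energy_band: ["0.95", "1.05"]
    default:
      adequacy: ["B", "1.75*B"]
      moderation: ["0.6*B", "B"]
    bands:
      carbohydrate: ["1.1*B", "0.85*C"]
      protein: ["1.5*B", "2*B"]
      fat_total: ["1.4*B", "0.95*C"]
      vit_c: ["2*B", "2.8*B"]
      vit_d: ["0.3*B", "0.55*B"]
      vit_e: ["0.75*B", "0.95*B"]
  dash_like:
    description: >
      Synthetic exemplary-menu archetype with tighter day-to-day control
      than myplate_like and no vitamin E shortfall; vitamin D remains low.
    noise_cv: 0.05
    energy_band: ["0.97", "1.03"]
    default:
      adequacy: ["B", "1.75*B"]
      moderation: ["0.6*B", "B"]
    bands:
      carbohydrate: ["1.1*B", "0.85*C"]
      protein: ["1.5*B", "2*B"]
      fat_total: ["1.4*B", "0.95*C"]
      vit_c: ["2*B", "2.8*B"]
      vit_d: ["0.3*B", "0.55*B"]
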