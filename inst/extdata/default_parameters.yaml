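traits:
  dairy_cattle:
    mature_female:
      body_weight: 480.0
      weight_gain: 0.0
      milk_yield: 5500.0
      milk_fat: 3.5
      wool_yield: 0.0
      pregnancy_fraction: 0.67
      DE: 65.0
      Ym: 6.0
      feeding_situation: stall
    young:
      body_weight: 220.0
      weight_gain: 0.5
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 0.0
      pregnancy_fraction: 0.0
      DE: 65.0
      Ym: 6.0
      feeding_situation: stall
    other:
      body_weight: 400.0
      weight_gain: 0.0
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 0.0
      pregnancy_fraction: 0.0
      DE: 65.0
      Ym: 6.0
      feeding_situation: stall
  nondairy_cattle:
    mature_female:
      body_weight: 380.0
      weight_gain: 0.0
      milk_yield: 500.0
      milk_fat: 4.0
      wool_yield: 0.0
      pregnancy_fraction: 0.67
      DE: 60.0
      Ym: 6.5
      feeding_situation: pasture
    young:
      body_weight: 200.0
      weight_gain: 0.4
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 0.0
      pregnancy_fraction: 0.0
      DE: 60.0
      Ym: 6.5
      feeding_situation: pasture
    other:
      body_weight: 350.0
      weight_gain: 0.0
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 0.0
      pregnancy_fraction: 0.0
      DE: 60.0
      Ym: 6.5
      feeding_situation: pasture
  buffalo:
    mature_female:
      body_weight: 420.0
      weight_gain: 0.0
      milk_yield: 400.0
      milk_fat: 6.5
      wool_yield: 0.0
      pregnancy_fraction: 0.6
      DE: 55.0
      Ym: 6.5
      feeding_situation: pasture
    young:
      body_weight: 230.0
      weight_gain: 0.35
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 0.0
      pregnancy_fraction: 0.0
      DE: 55.0
      Ym: 6.5
      feeding_situation: pasture
    other:
      body_weight: 380.0
      weight_gain: 0.0
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 0.0
      pregnancy_fraction: 0.0
      DE: 55.0
      Ym: 6.5
      feeding_situation: pasture
  sheep:
    mature_female:
      body_weight: 45.0
      weight_gain: 0.0
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 1.5
      pregnancy_fraction: 0.8
      DE: 60.0
      Ym: 6.5
      feeding_situation: pasture
    other:
      body_weight: 35.0
      weight_gain: 0.0
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 1.0
      pregnancy_fraction: 0.0
      DE: 60.0
      Ym: 5.5
      feeding_situation: pasture
  goat:
    mature_female:
      body_weight: 38.0
      weight_gain: 0.0
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 0.35
      pregnancy_fraction: 0.8
      DE: 60.0
      Ym: 6.5
      feeding_situation: pasture
    other:
      body_weight: 30.0
      weight_gain: 0.0
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 0.25
      pregnancy_fraction: 0.0
      DE: 60.0
      Ym: 5.5
      feeding_situation: pasture
  swine:
    whole_herd:
      body_weight: 90.0
      weight_gain: 0.0
      milk_yield: 0.0
      milk_fat: 0.0
      wool_yield: 0.0
      pregnancy_fraction: 0.0
      DE: 75.0
      Ym: 0.6
      feeding_situation: stall
energy:
  cf:
    dairy_cattle:
      mature_female: 0.386
      young: 0.322
      other: 0.322
    nondairy_cattle:
      mature_female: 0.386
      young: 0.322
      other: 0.322
    buffalo:
      mature_female: 0.386
      young: 0.322
      other: 0.322
    sheep:
      mature_female: 0.236
      other: 0.217
    goat:
      mature_female: 0.236
      other: 0.217
    swine:
      whole_herd: 0.197
  ca:
    stall: 0.0
    pasture: 0.17
    grazing_large_area: 0.36
  cp:
    dairy_cattle: 0.1
    nondairy_cattle: 0.1
    buffalo: 0.1
    sheep: 0.077
    goat: 0.077
    swine: 0.1
  c_gender: 1.0
  ev_wool: 24.0
  others_grow: no
manure:
  dairy_cattle:
    vs_rate: 8.8
    B0: 0.13
    system_fractions:
      liquid_slurry: 0.25
      solid_storage: 0.45
      daily_spread: 0.1
      pasture: 0.1
      anaerobic_digester: 0.1
  nondairy_cattle:
    vs_rate: 7.4
    B0: 0.1
    system_fractions:
      solid_storage: 0.5
      dry_lot: 0.15
      pasture: 0.25
      daily_spread: 0.1
  buffalo:
    vs_rate: 9.1
    B0: 0.1
    system_fractions:
      solid_storage: 0.45
      pasture: 0.35
      daily_spread: 0.2
  sheep:
    vs_rate: 8.2
    B0: 0.13
    system_fractions:
      pasture: 0.7
      solid_storage: 0.3
  goat:
    vs_rate: 9.0
    B0: 0.13
    system_fractions:
      pasture: 0.7
      solid_storage: 0.3
  swine:
    vs_rate: 5.4
    B0: 0.29
    system_fractions:
      liquid_slurry: 0.35
      solid_storage: 0.3
      lagoon: 0.1
      anaerobic_digester: 0.15
      other: 0.1
mcf:
  pasture:
    cool: 1.0
    temperate: 1.5
    warm: 2.0
  daily_spread:
    cool: 0.1
    temperate: 0.5
    warm: 1.0
  solid_storage:
    cool: 2.0
    temperate: 4.0
    warm: 5.0
  dry_lot:
    cool: 1.0
    temperate: 1.5
    warm: 2.0
  liquid_slurry:
    cool: 17.0
    temperate: 35.0
    warm: 55.0
  anaerobic_digester:
    cool: 1.0
    temperate: 1.5
    warm: 2.0
  lagoon:
    cool: 60.0
    temperate: 73.0
    warm: 80.0
  other:
    cool: 3.0
    temperate: 5.0
    warm: 8.0
lifespans:
  dairy_cattle:
    stock: 12.0
    slaughtered: 6.0
  nondairy_cattle:
    stock: 12.0
    slaughtered: 6.0
  buffalo:
    stock: 12.0
    slaughtered: 6.0
  sheep:
    stock: 5.6
    slaughtered: 3.0
  goat:
    stock: 5.6
    slaughtered: 3.0
  swine:
    stock: 10.0
    slaughtered: 6.0
  camel:
    stock: 12.0
    slaughtered: 6.0
  horse:
    stock: 12.0
    slaughtered: 6.0
  donkey:
    stock: 12.0
    slaughtered: 6.0
  mule:
    stock: 12.0
    slaughtered: 6.0
  poultry:
    stock: 6.0
    slaughtered: 2.0
  rabbit:
    stock: 6.0
    slaughtered: 3.0
tier1_efs:
  camel:
    enteric: 46.0
    manure: 1.92
  horse:
    enteric: 18.0
    manure: 1.64
  donkey:
    enteric: 10.0
    manure: 0.9
  mule:
    enteric: 10.0
    manure: 0.9
  poultry:
    enteric: 0.0
    manure: 0.02
  rabbit:
    enteric: 0.254
    manure: 0.08
cvs:
  dairy_cattle:
    ef: 0.15
    activity: 0.1
  nondairy_cattle:
    ef: 0.15
    activity: 0.1
  buffalo:
    ef: 0.2
    activity: 0.1
  sheep:
    ef: 0.2
    activity: 0.1
  goat:
    ef: 0.2
    activity: 0.1
  swine:
    ef: 0.2
    activity: 0.1
  camel:
    ef: 0.25
    activity: 0.15
  horse:
    ef: 0.25
    activity: 0.15
  donkey:
    ef: 0.25
    activity: 0.15
  mule:
    ef: 0.25
    activity: 0.15
  poultry:
    ef: 0.25
    activity: 0.15
  rabbit:
    ef: 0.25
    activity: 0.15
subclass_shares:
  dairy_cattle:
    mature_female: 0.45
    young: 0.25
    other: 0.3
  nondairy_cattle:
    mature_female: 0.45
    young: 0.25
    other: 0.3
  buffalo:
    mature_female: 0.45
    young: 0.25
    other: 0.3
  sheep:
    mature_female: 0.6
    other: 0.4
  goat:
    mature_female: 0.6
    other: 0.4
gapfill:
  carcass_weight:
    dairy_cattle: 150.0
    nondairy_cattle: 150.0
    buffalo: 160.0
    sheep: 15.0
    goat: 12.0
    swine: 77.0
    camel: 200.0
    horse: 150.0
    donkey: 90.0
    mule: 100.0
    poultry: 1.5
    rabbit: 1.2
constants:
  methane_energy_mj_per_kg: 55.65
  methane_density_kg_per_m3: 0.67
  dairy_regression:
    a: 30.8
    b: 0.2
    c: 53.6
  swine_enteric_ef: 1.0
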