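# Default descriptor-curation configuration.
#
# synonym_map : free-text descriptor -> canonical descriptor (lowercase)
# category_map: canonical descriptor -> semantic category
# merge_map   : sparse/closely-related category -> broad category
# priority    : final (post-merge) categories, highest priority first;
#               when a compound's descriptors span several categories the
#               earliest listed category wins
# polarity    : final category -> positive/negative aroma contribution
#
# The whole file is user-editable: the mapping is data, not code.

synonym_map:
  fruit: fruity
  fruits: fruity
  odourless: odorless
  odour-less: odorless
  "no odor": odorless
  grass: grassy
  herbaceous: herbal
  flowery: floral
  blossom: floral
  butter: buttery
  creamy: buttery
  milky: dairy
  lemony: lemon
  caramellic: caramel
  vanilla-like: vanilla
  sulfury: sulfurous
  solventy: solvent
  plasticky: plastic
  mouldy: moldy

category_map:
  fruity: Fruity
  apple: Fruity
  pear: Fruity
  banana: Fruity
  berry: Fruity
  peach: Fruity
  apricot: Fruity
  pineapple: Fruity
  melon: Fruity
  tropical: Fruity
  citrus: Citrus
  lemon: Citrus
  orange: Citrus
  lime: Citrus
  grapefruit: Citrus
  bergamot: Citrus
  floral: Floral
  rose: Floral
  jasmine: Floral
  violet: Floral
  lavender: Floral
  honey: Floral
  sweet: Sweet/Vanilla/Caramel
  vanilla: Sweet/Vanilla/Caramel
  caramel: Sweet/Vanilla/Caramel
  buttery: Dairy/Buttery
  dairy: Dairy/Buttery
  cheesy: Dairy/Buttery
  green: Green/Herbal
  grassy: Green/Herbal
  leafy: Green/Herbal
  leaf: Green/Herbal
  herbal: Green/Herbal
  minty: Green/Herbal
  cooling: Green/Herbal
  nutty: Nutty/Roasted
  roasted: Nutty/Roasted
  toasted: Nutty/Roasted
  coffee: Nutty/Roasted
  cocoa: Nutty/Roasted
  woody: Woody/Spicy
  spicy: Woody/Spicy
  clove: Woody/Spicy
  cedar: Woody/Spicy
  earthy: Earthy/Musty
  musty: Earthy/Musty
  moldy: Earthy/Musty
  mushroom: Earthy/Musty
  sulfurous: Sulfurous
  garlic: Sulfurous
  onion: Sulfurous
  cabbage: Sulfurous
  rancid: Rancid/Sweaty/Animalic
  sweaty: Rancid/Sweaty/Animalic
  animalic: Rancid/Sweaty/Animalic
  fecal: Rancid/Sweaty/Animalic
  chemical: Chemical/Solvent/Plastic
  solvent: Chemical/Solvent/Plastic
  plastic: Chemical/Solvent/Plastic
  gasoline: Chemical/Solvent/Plastic
  medicinal: Chemical/Solvent/Plastic
  pungent: Chemical/Solvent/Plastic
  sour: Chemical/Solvent/Plastic
  odorless: Odorless

merge_map:
  Dairy/Buttery: Sweet/Vanilla/Caramel
  Rancid/Sweaty/Animalic: Off-flavor
  Chemical/Solvent/Plastic: Off-flavor

priority:
  - Fruity
  - Citrus
  - Floral
  - Sweet/Vanilla/Caramel
  - Nutty/Roasted
  - Woody/Spicy
  - Green/Herbal
  - Earthy/Musty
  - Sulfurous
  - Off-flavor
  - Odorless

polarity:
  Fruity: positive
  Citrus: positive
  Floral: positive
  Sweet/Vanilla/Caramel: positive
  Nutty/Roasted: positive
  Woody/Spicy: positive
  Green/Herbal: negative
  Earthy/Musty: negative
  Sulfurous: negative
  Off-flavor: negative
  Odorless: negative
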