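[
  {
    "drug_id": "methadone",
    "name": "Methadone",
    "synonyms": ["methadone hydrochloride"],
    "brand_names": ["Dolophine"],
    "known_indications": ["CD001", "CD002", "CD003", "CD004"],
    "known_side_effects": ["CD006", "CD007", "CD021", "CD022"],
    "in_indication_resource": true,
    "in_side_effect_resource": true
  },
  {
    "drug_id": "amitriptyline",
    "name": "Elavil",
    "synonyms": ["amitriptyline"],
    "brand_names": [],
    "known_indications": ["CD009", "CD010", "CD011", "CD012", "CD005", "CD013"],
    "known_side_effects": [],
    "in_indication_resource": true,
    "in_side_effect_resource": false
  },
  {
    "drug_id": "spironolactone",
    "name": "Spironolactone",
    "synonyms": [],
    "brand_names": ["Aldactone"],
    "known_indications": ["CD017", "CD018", "CD019"],
    "known_side_effects": ["CD020", "CD022", "CD021", "CD006", "CD023"],
    "in_indication_resource": true,
    "in_side_effect_resource": true
  },
  {
    "drug_id": "atomoxetine",
    "name": "Strattera",
    "synonyms": ["atomoxetine"],
    "brand_names": [],
    "known_indications": ["CD015"],
    "known_side_effects": [],
    "in_indication_resource": true,
    "in_side_effect_resource": false
  },
  {
    "drug_id": "vilazodone",
    "name": "Viibryd",
    "synonyms": ["vilazodone"],
    "brand_names": [],
    "known_indications": ["CD009"],
    "known_side_effects": [],
    "in_indication_resource": true,
    "in_side_effect_resource": false
  }
]
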