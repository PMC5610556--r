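{
  "key_id": "tonganum_group",
  "title": "Identification key to Indian species of the Tetramorium tonganum group (workers)",
  "notes": [
    "T. tonganum itself is excluded from the Indian checklist (its Indian records are misidentified T. salvatum) but is retained in this key because the species is very widespread in tropical Asia and future identifications may encounter it.",
    "The printed key labels its leads over five numbered points while resolving to four decision points; the structural encoding uses 4 couplets and preserves the printed numbering in the lead texts."
  ],
  "characters": [
    {"id": "propodeal_armament", "kind": "categorical",
     "states": ["unarmed", "armed"],
     "description": "Propodeal armament: fully unarmed without teeth or spines, versus armed with teeth or spines",
     "figure": "Fig. 22A, B"},
    {"id": "petiole_node_enlarged_convex", "kind": "boolean",
     "description": "Petiolar node in profile appearing enlarged and conspicuously elongated and convex",
     "figure": "Fig. 22C"},
    {"id": "petiole_node_profile", "kind": "categorical",
     "states": ["low_longer_than_high", "higher_than_long"],
     "description": "Petiolar node in profile: low and appearing longer than high, versus clearly higher and appearing higher than long",
     "figure": "Fig. 22D-F"},
    {"id": "peduncle_shape", "kind": "categorical",
     "states": ["long_curved", "short_straight"],
     "description": "Peduncle of the petiole in profile: long and curved, versus short and straight",
     "figure": "Fig. 22E, F"}
  ],
  "couplets": [
    {"number": 1, "leads": [
      {"text": "Propodeum unarmed without teeth or spines",
       "predicate": {"char": "propodeal_armament", "eq": "unarmed"},
       "terminal": "krishnani"},
      {"text": "Propodeum armed with teeth or spines",
       "predicate": {"char": "propodeal_armament", "eq": "armed"},
       "goto": 2}
    ]},
    {"number": 2, "leads": [
      {"text": "In profile petiolar node appearing enlarged and conspicuously elongated and convex",
       "predicate": {"char": "petiole_node_enlarged_convex", "eq": true},
       "terminal": "barryi"},
      {"text": "In profile petiolar node not appearing enlarged and significantly less elongated and convex",
       "predicate": {"char": "petiole_node_enlarged_convex", "eq": false},
       "goto": 3}
    ]},
    {"number": 3, "leads": [
      {"text": "In profile petiolar node low and appearing longer than high",
       "predicate": {"char": "petiole_node_profile", "eq": "low_longer_than_high"},
       "terminal": "christiei"},
      {"text": "In profile petiolar node clearly higher and appearing higher than long",
       "predicate": {"char": "petiole_node_profile", "eq": "higher_than_long"},
       "goto": 4}
    ]},
    {"number": 4, "leads": [
      {"text": "In profile peduncle of petiole long and curved",
       "predicate": {"char": "peduncle_shape", "eq": "long_curved"},
       "terminal": "tonganum"},
      {"text": "In profile peduncle of petiole short and straight",
       "predicate": {"char": "peduncle_shape", "eq": "short_straight"},
       "terminal": "salvatum"}
    ]}
  ]
}
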