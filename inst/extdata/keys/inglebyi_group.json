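{
  "key_id": "inglebyi_group",
  "title": "Identification key to Indian species of the Tetramorium inglebyi group (workers)",
  "notes": [
    "Couplet 4 contrasts relative spine length nested within the 'relatively longer' branch of couplet 2; since one ordinal spine character cannot serve both contrasts, the presence of a large anteroventral peduncular lamella (listed in the same leads) is authoritative at couplet 4 and the spine contrast is retained in the lead text only.",
    "Documented numeric gap: couplet 2 leaves propodeal spines of intermediate relative length unrouted."
  ],
  "characters": [
    {"id": "eye_length_vs_scape_width", "kind": "categorical",
     "states": ["longer", "shorter"],
     "description": "Eye length relative to the maximum width of the antennal scape",
     "figure": "Fig. 13A-E"},
    {"id": "propodeal_spines_relative", "kind": "categorical",
     "states": ["shorter", "intermediate", "longer"],
     "description": "Relative length of the propodeal spines as contrasted at couplet 2; 'intermediate' records states satisfying neither lead",
     "figure": "Fig. 13F, G"},
    {"id": "petiole_dorsum_proportion", "kind": "categorical",
     "states": ["broader_than_long", "as_long_or_longer"],
     "description": "Proportion of the dorsum of the petiolar node in dorsal view",
     "figure": "Fig. 13H, I"},
    {"id": "procoxal_sculpture", "kind": "categorical",
     "states": ["completely_reticulate_punctate", "not_completely"],
     "description": "Sculpture of the procoxae",
     "figure": "Fig. 13F, G"},
    {"id": "petiole_node_profile_shape", "kind": "categorical",
     "states": ["higher_thinner", "thicker_compact"],
     "description": "Appearance of the petiolar node in profile at couplet 3",
     "figure": "Fig. 14A, B"},
    {"id": "promesonotal_sculpture", "kind": "categorical",
     "states": ["reticulate_rugose", "longitudinally_rugulose"],
     "description": "Sculpture on the dorsum of the promesonotum",
     "figure": "Fig. 14C, D"},
    {"id": "peduncle_anteroventral_lamella", "kind": "boolean",
     "description": "Peduncle of the petiole with a large anteroventral lamella in profile",
     "figure": "Fig. 14E, F"}
  ],
  "couplets": [
    {"number": 1, "leads": [
      {"text": "Eyes large, always longer than maximum width of antennal scapes",
       "predicate": {"char": "eye_length_vs_scape_width", "eq": "longer"},
       "terminal": "inglebyi"},
      {"text": "Eyes much smaller than above, always shorter than maximum width of antennal scapes",
       "predicate": {"char": "eye_length_vs_scape_width", "eq": "shorter"},
       "goto": 2}
    ]},
    {"number": 2, "leads": [
      {"text": "Propodeal spines relatively shorter; dorsum of petiolar node in dorsal view conspicuously much broader than long; procoxae never completely reticulate-punctate",
       "predicate": {"char": "propodeal_spines_relative", "eq": "shorter"},
       "advisory": {"all": [{"char": "petiole_dorsum_proportion", "eq": "broader_than_long"},
                            {"char": "procoxal_sculpture", "eq": "not_completely"}]},
       "goto": 3},
      {"text": "Propodeal spines relatively longer; dorsum of petiolar node in dorsal view about as long as broad or clearly longer than broad; procoxae completely reticulate-punctate",
       "predicate": {"char": "propodeal_spines_relative", "eq": "longer"},
       "advisory": {"all": [{"char": "petiole_dorsum_proportion", "eq": "as_long_or_longer"},
                            {"char": "procoxal_sculpture", "eq": "completely_reticulate_punctate"}]},
       "goto": 4}
    ]},
    {"number": 3, "leads": [
      {"text": "In profile petiolar node appearing higher and thinner; dorsum of promesonotum reticulate-rugose; first gastral tergite unsculptured, smooth and shiny",
       "predicate": {"char": "petiole_node_profile_shape", "eq": "higher_thinner"},
       "advisory": {"char": "promesonotal_sculpture", "eq": "reticulate_rugose"},
       "terminal": "elisabethae"},
      {"text": "In profile petiolar node appearing thicker and more compact; dorsum of promesonotum longitudinally rugulose; base of first gastral tergite longitudinally rugulose",
       "predicate": {"char": "petiole_node_profile_shape", "eq": "thicker_compact"},
       "advisory": {"char": "promesonotal_sculpture", "eq": "longitudinally_rugulose"},
       "terminal": "triangulatum"}
    ]},
    {"number": 4, "leads": [
      {"text": "Propodeum with comparatively longer spines; in profile peduncle of petiole with large anteroventral lamella; shape of petiolar node narrowing from base to apex and dorsum convex",
       "predicate": {"char": "peduncle_anteroventral_lamella", "eq": true},
       "terminal": "myops"},
      {"text": "Propodeum with comparatively shorter spines; in profile peduncle of petiole without large anteroventral lamella; shape of petiolar node appearing square and dorsum straight",
       "predicate": {"char": "peduncle_anteroventral_lamella", "eq": false},
       "terminal": "jarawa"}
    ]}
  ]
}
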