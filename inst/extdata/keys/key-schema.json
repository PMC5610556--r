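{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "tetrakey/key-schema.json",
  "title": "Dichotomous key file",
  "type": "object",
  "required": ["key_id", "title", "characters", "couplets"],
  "additionalProperties": true,
  "properties": {
    "key_id": {"type": "string", "minLength": 1},
    "title": {"type": "string"},
    "notes": {"type": "array", "items": {"type": "string"}},
    "characters": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "kind", "description"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "kind": {"enum": ["categorical", "boolean", "count", "quantitative"]},
          "states": {"type": "array", "items": {"type": "string"}, "minItems": 1},
          "domain": {"type": "array", "items": {"type": "number"}, "minItems": 2, "maxItems": 2},
          "description": {"type": "string"},
          "figure": {"type": "string"}
        },
        "allOf": [
          {"if": {"properties": {"kind": {"const": "categorical"}}},
           "then": {"required": ["states"]}},
          {"if": {"properties": {"kind": {"enum": ["count", "quantitative"]}}},
           "then": {"required": ["domain"]}}
        ]
      }
    },
    "couplets": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["number", "leads"],
        "properties": {
          "number": {"type": "integer", "minimum": 1},
          "leads": {
            "type": "array",
            "minItems": 2,
            "maxItems": 2,
            "items": {
              "type": "object",
              "required": ["text", "predicate"],
              "properties": {
                "text": {"type": "string", "minLength": 1},
                "predicate": {"$ref": "#/definitions/predicate"},
                "advisory": {"$ref": "#/definitions/predicate"},
                "goto": {"type": "integer", "minimum": 1},
                "terminal": {"type": "string", "minLength": 1}
              },
              "oneOf": [{"required": ["goto"]}, {"required": ["terminal"]}]
            }
          }
        }
      }
    }
  },
  "definitions": {
    "predicate": {
      "type": "object",
      "oneOf": [
        {"required": ["char", "eq"]},
        {"required": ["char", "in"],
         "properties": {"in": {"type": "array", "minItems": 1}}},
        {"required": ["char", "le"], "properties": {"le": {"type": "number"}}},
        {"required": ["char", "ge"], "properties": {"ge": {"type": "number"}}},
        {"required": ["char", "lt"], "properties": {"lt": {"type": "number"}}},
        {"required": ["char", "gt"], "properties": {"gt": {"type": "number"}}},
        {"required": ["all"],
         "properties": {"all": {"type": "array", "items": {"$ref": "#/definitions/predicate"}, "minItems": 1}}},
        {"required": ["any"],
         "properties": {"any": {"type": "array", "items": {"$ref": "#/definitions/predicate"}, "minItems": 1}}},
        {"required": ["not"], "properties": {"not": {"$ref": "#/definitions/predicate"}}}
      ],
      "properties": {"char": {"type": "string", "minLength": 1}}
    }
  }
}
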