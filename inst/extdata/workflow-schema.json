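{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "rivulet workflow",
  "type": "object",
  "required": ["nodes"],
  "properties": {
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "category", "operator"],
        "properties": {
          "id": {"type": "string"},
          "category": {
            "enum": ["source", "combinator", "transform", "condition",
                     "sink", "property", "nested"]
          },
          "operator": {"type": "string"},
          "params": {"type": "object"},
          "properties": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["from", "to"],
        "properties": {
          "from": {"type": "string"},
          "to": {"type": "string"},
          "slot": {"type": "integer", "minimum": 0}
        }
      }
    },
    "groups": {
      "type": "object",
      "additionalProperties": {"$ref": "#"}
    }
  }
}
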