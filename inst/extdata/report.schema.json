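{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "funset merged analysis report",
  "type": "object",
  "required": ["dataset", "alpha", "enrichment"],
  "properties": {
    "dataset": {
      "type": "object",
      "required": ["name", "species", "n_l1", "n_l2"],
      "properties": {
        "name": {"type": "string"},
        "species": {"type": "string"},
        "n_l1": {"type": "integer", "minimum": 1},
        "n_l2": {"type": "integer", "minimum": 1}
      }
    },
    "alpha": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
    "enrichment": {
      "type": "object",
      "additionalProperties": {
        "type": "array",
        "maxItems": 10,
        "items": {
          "type": "object",
          "required": ["term_id", "term_name", "k", "n", "K", "N",
                       "p_raw", "p_adj", "genes"],
          "properties": {
            "term_id": {"type": "string"},
            "k": {"type": "integer", "minimum": 1},
            "p_raw": {"type": "number", "minimum": 0, "maximum": 1},
            "p_adj": {"type": "number", "minimum": 0, "maximum": 1},
            "genes": {"type": "array", "items": {"type": "string"}}
          }
        }
      }
    },
    "literature": {
      "type": ["array", "null"],
      "maxItems": 10,
      "items": {
        "type": "object",
        "required": ["doc_id", "title", "score_raw", "score_norm",
                     "n_shared", "shared_genes"]
      }
    },
    "experiments": {"type": ["object", "null"]}
  }
}
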