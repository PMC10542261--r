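{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "herbmars-dataset.schema.json",
  "title": "herbmars evidence dataset",
  "description": "Evidence dossiers for candidate herbal quality-control markers: plants with indications, per-compound bioactivities, concentration reports, reference-standard listings, assay methods, regulatory limits and optional recorded rubric scores. Schema version 1.0.",
  "type": "object",
  "required": ["schema_version", "plants", "compounds"],
  "properties": {
    "schema_version": { "type": "string" },
    "plants": { "type": "array", "items": { "$ref": "#/definitions/plant" } },
    "compounds": { "type": "array", "items": { "$ref": "#/definitions/compound" } },
    "limits": { "type": "array", "items": { "$ref": "#/definitions/limit" } }
  },
  "definitions": {
    "plant": {
      "type": "object",
      "required": ["botanical_name", "part_used"],
      "properties": {
        "botanical_name": { "type": "string", "minLength": 1 },
        "family": { "type": "string" },
        "source": { "enum": ["wild", "cultivated", "both"] },
        "part_used": { "type": "array", "items": { "type": "string" }, "minItems": 1 },
        "dosage_forms": { "type": "array", "items": { "type": "string" } },
        "indications": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["condition", "symptoms"],
            "properties": {
              "condition": { "type": "string" },
              "symptoms": {
                "type": "array",
                "items": { "type": "string" },
                "uniqueItems": true
              }
            }
          }
        }
      }
    },
    "compound": {
      "type": "object",
      "required": ["compound_id", "name", "plant", "documented_constituent",
                   "concentration"],
      "properties": {
        "compound_id": { "type": "string", "minLength": 1 },
        "name": { "type": "string", "minLength": 1 },
        "plant": {
          "type": "string",
          "description": "botanical_name of a plant in this document"
        },
        "documented_constituent": { "type": "boolean" },
        "activities": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["activity_name"],
            "properties": {
              "activity_name": { "type": "string" },
              "symptoms_addressed": { "type": "array", "items": { "type": "string" } },
              "relevant_to_indication": { "type": "boolean" },
              "mechanism": { "type": "string" },
              "citations": { "type": "array", "items": { "type": "string" } }
            }
          }
        },
        "concentration": {
          "type": "object",
          "required": ["raw_text", "determined"],
          "properties": {
            "raw_text": { "type": "string" },
            "determined": { "type": "boolean" },
            "low": { "type": "number", "minimum": 0 },
            "high": { "type": "number", "minimum": 0 },
            "unit": { "enum": ["percent_w_w", "mg_per_g", "ppm"] },
            "basis": { "type": "string" }
          },
          "description": "if determined: low <= high and unit present; otherwise low/high/unit/basis absent"
        },
        "standards": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["vendor", "pack_value", "pack_unit", "price_eur"],
            "properties": {
              "vendor": { "type": "string" },
              "grade": { "type": "string" },
              "pack_value": { "type": "number", "exclusiveMinimum": 0 },
              "pack_unit": { "enum": ["mg", "mL", "g"] },
              "price_eur": { "type": "number", "exclusiveMinimum": 0 }
            }
          }
        },
        "methods": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["technique"],
            "properties": {
              "technique": { "type": "string", "minLength": 1 },
              "matrix": { "type": "string" },
              "citation": { "type": "string" }
            }
          }
        },
        "toxic": { "type": "boolean" },
        "negative_marker_limits": {
          "type": "array",
          "items": { "$ref": "#/definitions/limit" }
        },
        "recorded_components": {
          "type": "object",
          "required": ["a", "b", "c", "d", "e", "f"],
          "properties": {
            "a": { "type": "integer", "minimum": 0, "maximum": 1 },
            "b": { "type": "integer", "minimum": 0, "maximum": 3 },
            "c": { "type": "integer", "minimum": 0, "maximum": 1 },
            "d": { "type": "integer", "minimum": 0, "maximum": 1 },
            "e": { "type": "integer", "minimum": 0, "maximum": 1 },
            "f": { "type": "integer", "minimum": 0, "maximum": 1 }
          },
          "description": "scores as printed in a source table, kept verbatim for auditing (may be internally inconsistent)"
        },
        "recorded_total": { "type": "integer", "minimum": 0, "maximum": 8 }
      }
    },
    "limit": {
      "type": "object",
      "required": ["authority", "analyte", "limit_ppm"],
      "properties": {
        "authority": { "type": "string" },
        "analyte": { "type": "string" },
        "limit_ppm": { "type": "number", "minimum": 0 },
        "direction": { "enum": ["maximum"] }
      }
    }
  }
}
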