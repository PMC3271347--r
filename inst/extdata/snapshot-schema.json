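{
  "$comment": "Interchange schema for PathCompare database snapshots. Informal JSON-schema document; the authoritative validation is performed by readSnapshot().",
  "schema_version": "1.0",
  "type": "object",
  "required": ["name"],
  "properties": {
    "schema_version": {"type": "string", "const": "1.0"},
    "name": {"type": "string", "minLength": 1},
    "genes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["local_id"],
        "properties": {
          "local_id": {"type": "string"},
          "gene_id": {"type": "string", "pattern": "^[0-9]+$"}
        }
      }
    },
    "metabolites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["local_id", "names"],
        "properties": {
          "local_id": {"type": "string"},
          "names": {"type": "array", "items": {"type": "string"}, "minItems": 1},
          "formula": {"type": "string"},
          "charge": {"type": "integer"},
          "compartment": {"type": "string"},
          "ids": {
            "type": "object",
            "properties": {
              "kegg_compound": {"type": "string", "pattern": "^[A-Z][0-9]{5}$"},
              "kegg_glycan": {"type": "string", "pattern": "^G[0-9]{5}$"},
              "chebi": {"type": "string", "pattern": "^(CHEBI:)?[0-9]+$"},
              "pubchem_compound": {"type": "string", "pattern": "^[0-9]+$"},
              "cas": {"type": "string", "pattern": "^[0-9]{2,7}-[0-9]{2}-[0-9]$"}
            }
          },
          "is_generic": {"type": "boolean"},
          "is_protein": {"type": "boolean"},
          "instance_ids": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["local_id", "side_a", "side_b"],
        "properties": {
          "local_id": {"type": "string"},
          "side_a": {"$ref": "#/definitions/side"},
          "side_b": {"$ref": "#/definitions/side"},
          "reversible": {"type": "boolean"},
          "genes": {"type": "array", "items": {"type": "string"}},
          "ecs": {
            "type": "array",
            "items": {"type": "string", "pattern": "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"}
          },
          "pathways": {"type": "array", "items": {"type": "string"}},
          "is_set_reaction": {"type": "boolean"}
        }
      }
    },
    "pathways": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["local_id", "name"],
        "properties": {
          "local_id": {"type": "string"},
          "name": {"type": "string"},
          "category": {
            "enum": ["amino acid metabolism", "carbohydrate metabolism",
                     "energy metabolism", "glycan biosynthesis and metabolism",
                     "lipid metabolism", "metabolism of cofactors and vitamins",
                     "metabolism of secondary metabolites",
                     "nucleotide metabolism",
                     "xenobiotics biodegradation and metabolism",
                     "miscellaneous", "transport"]
          }
        }
      }
    }
  },
  "definitions": {
    "side": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["metabolite"],
        "properties": {
          "metabolite": {"type": "string"},
          "coefficient": {"type": "number", "exclusiveMinimum": 0}
        }
      }
    }
  }
}
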