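{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "graftflow coronary network",
  "description": "Serialised coronary_network: 1D vessel segments joined at junctions, lumped stenosis elements, three-element Windkessel terminals with intramyocardial back-pressure, inflow attachments driven by the aortic waveform, grafting-target markers and global haemodynamic settings. Units: cm, s, mmHg, ml/min at this interface.",
  "type": "object",
  "required": ["format", "version", "segments", "terminals", "inflows", "globals"],
  "properties": {
    "format": {"const": "graftflow-network"},
    "version": {"type": "string"},
    "segments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "length_cm", "radius_prox_cm", "radius_dist_cm",
                     "beta_mmHg_cm", "territory"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "length_cm": {"type": "number", "exclusiveMinimum": 0},
          "radius_prox_cm": {"type": "number", "exclusiveMinimum": 0},
          "radius_dist_cm": {"type": "number", "exclusiveMinimum": 0},
          "beta_mmHg_cm": {"type": "number", "exclusiveMinimum": 0},
          "gamma_ext": {"type": "number", "minimum": 0, "maximum": 1},
          "territory": {"enum": ["LAD", "CIRC", "RCA", "graft", "systemic"]}
        }
      }
    },
    "junctions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["junction", "segment", "end"],
        "properties": {
          "junction": {"type": "string"},
          "segment": {"type": "string"},
          "end": {"enum": ["proximal", "distal"]}
        }
      }
    },
    "stenoses": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "host_segment", "position_cm", "percent_diameter",
                     "lesion_length_cm"],
        "properties": {
          "id": {"type": "string"},
          "host_segment": {"type": "string"},
          "position_cm": {"type": "number", "exclusiveMinimum": 0},
          "percent_diameter": {"type": "number", "minimum": 0,
                               "exclusiveMaximum": 100},
          "lesion_length_cm": {"type": "number", "exclusiveMinimum": 0},
          "K_v": {"type": ["number", "null"]},
          "K_t": {"type": "number", "minimum": 0},
          "K_u": {"type": "number", "minimum": 0}
        }
      }
    },
    "terminals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "segment", "R1", "R2", "C"],
        "properties": {
          "id": {"type": "string"},
          "segment": {"type": "string"},
          "R1": {"type": "number", "exclusiveMinimum": 0},
          "R2": {"type": "number", "exclusiveMinimum": 0},
          "C": {"type": "number", "exclusiveMinimum": 0},
          "territory": {"type": "string"},
          "gamma_im": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "inflows": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["segment", "end"],
        "properties": {
          "segment": {"type": "string"},
          "end": {"enum": ["proximal", "distal"]}
        }
      }
    },
    "markers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["site", "segment", "position_cm"],
        "properties": {
          "site": {"type": "string"},
          "segment": {"type": "string"},
          "position_cm": {"type": "number", "minimum": 0}
        }
      }
    },
    "grafts": {"type": "array"},
    "globals": {
      "type": "object",
      "required": ["aortic", "lv", "heart_rate", "period"],
      "properties": {
        "aortic": {"$ref": "#/$defs/waveform"},
        "lv": {"$ref": "#/$defs/waveform"},
        "heart_rate": {"type": "number", "exclusiveMinimum": 0},
        "period": {"type": "number", "exclusiveMinimum": 0},
        "cardiac_output_l_min": {"type": "number", "exclusiveMinimum": 0},
        "myocardial_fraction": {"type": "number", "exclusiveMinimum": 0,
                                "exclusiveMaximum": 0.1},
        "total_arterial_compliance_ml_mmHg": {"type": "number",
                                              "exclusiveMinimum": 0},
        "territory_split": {"type": "object"},
        "reference_pressure_mmHg": {"type": "number"}
      }
    }
  },
  "$defs": {
    "waveform": {
      "type": "object",
      "required": ["t_s", "p_mmHg", "period"],
      "properties": {
        "t_s": {"type": "array", "items": {"type": "number"}},
        "p_mmHg": {"type": "array", "items": {"type": "number"}},
        "period": {"type": "number", "exclusiveMinimum": 0}
      }
    }
  }
}
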