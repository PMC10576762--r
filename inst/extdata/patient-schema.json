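{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "coroflow patient record",
  "description": "Per-patient calibration inputs for the coronary lumped-parameter model. Lengths in cm, pressures in mmHg, flows in L/min, resistances in mmHg/(L/min), volumes in ml, heart rate in beats/min.",
  "type": "object",
  "required": ["patient_id", "anomaly_side", "aorta", "left_ca", "right_ca", "cardiac", "states"],
  "properties": {
    "patient_id": {"type": "string"},
    "anomaly_side": {"enum": ["left", "right"]},
    "aorta": {
      "type": "array", "minItems": 3, "maxItems": 3,
      "items": {
        "type": "object",
        "required": ["site", "mean_diameter", "length"],
        "properties": {
          "site": {"enum": ["annulus", "sinus_sinotubular", "proximal_ascending"]},
          "mean_diameter": {"type": "number", "exclusiveMinimum": 0},
          "length": {"type": "number", "exclusiveMinimum": 0},
          "wall_thickness": {"type": "number", "exclusiveMinimum": 0, "default": 0.3}
        }
      }
    },
    "left_ca": {"$ref": "#/$defs/coronary_branch"},
    "right_ca": {"$ref": "#/$defs/coronary_branch"},
    "cardiac": {
      "type": "object",
      "required": ["stroke_volume"],
      "properties": {
        "stroke_volume": {"type": "number", "exclusiveMinimum": 0},
        "end_diastolic_volume": {"type": "number"},
        "end_systolic_volume": {"type": "number"},
        "ejection_fraction": {"type": "number"}
      }
    },
    "states": {
      "type": "object",
      "required": ["rest", "hyperemia"],
      "properties": {
        "rest": {"$ref": "#/$defs/hemodynamic_state"},
        "hyperemia": {"$ref": "#/$defs/hemodynamic_state"}
      }
    }
  },
  "$defs": {
    "coronary_branch": {
      "type": "object",
      "required": ["anomalous", "segments"],
      "properties": {
        "anomalous": {"type": "boolean"},
        "segments": {
          "type": "array", "minItems": 2, "maxItems": 3,
          "items": {
            "type": "object",
            "required": ["position", "semi_axis_max", "semi_axis_min", "length"],
            "properties": {
              "position": {"enum": ["ostial_intramural", "proximal", "distal"]},
              "semi_axis_max": {"type": "number", "exclusiveMinimum": 0},
              "semi_axis_min": {"type": "number", "exclusiveMinimum": 0},
              "length": {"type": "number", "exclusiveMinimum": 0},
              "wall_thickness": {"type": "number", "exclusiveMinimum": 0, "default": 0.03}
            }
          }
        }
      }
    },
    "hemodynamic_state": {
      "type": "object",
      "required": ["heart_rate", "systolic_pressure", "diastolic_pressure", "R_total_left", "R_total_right"],
      "properties": {
        "heart_rate": {"type": "number", "exclusiveMinimum": 0},
        "systolic_pressure": {"type": "number", "exclusiveMinimum": 0},
        "diastolic_pressure": {"type": "number", "exclusiveMinimum": 0},
        "R_total_left": {"type": "number", "exclusiveMinimum": 0},
        "R_total_right": {"type": "number", "exclusiveMinimum": 0},
        "cbf_invivo_left": {"type": "number"},
        "cbf_invivo_right": {"type": "number"}
      }
    }
  }
}
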