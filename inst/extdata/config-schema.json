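{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "bubblegrid figure configuration",
  "description": "YAML/JSON configuration accepted by the bubblegrid CLI --config flag. Command-line flags override config values.",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "color": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "vmax": {
          "type": "number",
          "exclusiveMinimum": 0,
          "description": "Half-range of the symmetric diverging colour scale, in effect-estimate units. Default: max |estimate| over non-missing values."
        },
        "palette": {
          "type": "array",
          "items": { "type": "string", "pattern": "^#[0-9A-Fa-f]{6}$" },
          "minItems": 3,
          "description": "Odd number of colours, low to high; the middle entry is the zero colour. Default: blue-white-red."
        }
      }
    },
    "size": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "cap": {
          "type": "number",
          "exclusiveMinimum": 0,
          "description": "Cap on -log10(P) for bubble sizing; omitted = no cap (observed maximum bounds the scale)."
        },
        "rmin": { "type": "number", "exclusiveMinimum": 0, "default": 0.08 },
        "rmax": { "type": "number", "exclusiveMinimum": 0, "default": 0.42 },
        "transform": {
          "enum": ["area", "radius"],
          "default": "area",
          "description": "area: bubble area linear in the capped score; radius: radius linear."
        }
      }
    },
    "style": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "pitch": { "type": "number", "default": 1 },
        "font": { "type": "number", "default": 0.32 },
        "title_font": { "type": "number", "default": 0.42 },
        "unit_px": { "type": "number", "default": 24 },
        "max_label": { "type": "integer", "default": 38 },
        "na_dot": { "type": "boolean", "default": false }
      }
    }
  }
}
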