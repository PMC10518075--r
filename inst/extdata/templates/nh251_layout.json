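{
  "canvas": [33.95, 33.99],
  "placements": [
    {
      "grid": "Lipoprotein subclasses",
      "x": 0.3,
      "y": 0.3
    },
    {
      "grid": "Lipoprotein particle sizes",
      "x": 19.42,
      "y": 0.3
    },
    {
      "grid": "Apolipoproteins",
      "x": 19.42,
      "y": 7.35
    },
    {
      "grid": "Cholesterol",
      "x": 19.42,
      "y": 18.39
    },
    {
      "grid": "Other lipids",
      "x": 25.72,
      "y": 0.3
    },
    {
      "grid": "Fatty acids",
      "x": 25.72,
      "y": 13.35
    },
    {
      "grid": "Glycolysis",
      "x": 0.3,
      "y": 19.84
    },
    {
      "grid": "Ketone bodies",
      "x": 3.93,
      "y": 19.84
    },
    {
      "grid": "Fluid balance & inflammation",
      "x": 9.06,
      "y": 19.84
    },
    {
      "grid": "Amino acids",
      "x": 15.59,
      "y": 19.84
    }
  ],
  "legend": {
    "x": 25.72,
    "y": 28.39
  },
  "footnote": "*Ratios are to total fatty acids except where specified"
}
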