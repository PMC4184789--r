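{
  "fractionation_models": [
    {
      "name": "kim-aragonite",
      "a": 17.88,
      "b": -31.14,
      "valid_T_range_K": [273.15, 313.15],
      "note": "inorganic aragonite synthesis, 1000 ln alpha = a*1000/T + b"
    },
    {
      "name": "geffen-plaice",
      "a": 16.75,
      "b": -27.09,
      "valid_T_range_K": [284.15, 290.15],
      "note": "juvenile-fish rearing relation; representative stand-in coefficients of the published biogenic-aragonite type (see package docs)"
    }
  ],
  "mixing_relations": [
    {
      "name": "northsea-mixing",
      "slope": 0.29,
      "intercept": -9.85,
      "region": "North Sea",
      "note": "basin-wide bottom/surface water d18O-salinity regression"
    },
    {
      "name": "natl-mixing",
      "slope": 0.55,
      "intercept": -18.98,
      "region": "North Atlantic",
      "note": "regional open-ocean d18O-salinity fit"
    }
  ]
}
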