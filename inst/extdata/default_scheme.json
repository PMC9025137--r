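{
  "name": "default-myoglobin-standin",
  "description": "Reduced stand-in myoglobin oxidation scheme (NOT the published 22-reaction scheme). Units: myoglobin forms are fractions summing to 1; O2 in mol m-3; k_ref at 20 degC -- oxygenation in m3 mol-1 s-1, all others s-1. Constants derived in tools/tune_default_scheme.R.",
  "species": [
    {
      "name": "Mb",
      "role": "myoglobin-form",
      "diffusive": false
    },
    {
      "name": "MbO2",
      "role": "myoglobin-form",
      "diffusive": false
    },
    {
      "name": "MMb",
      "role": "myoglobin-form",
      "diffusive": false
    },
    {
      "name": "O2",
      "role": "dissolved-gas",
      "diffusive": true
    }
  ],
  "reactions": [
    {
      "name": "oxygenation",
      "reactants": {
        "Mb": 1,
        "O2": 1
      },
      "products": {
        "MbO2": 1
      },
      "k_ref": 0.0527759
    },
    {
      "name": "deoxygenation",
      "reactants": {
        "MbO2": 1
      },
      "products": {
        "Mb": 1,
        "O2": 1
      },
      "k_ref": 0.00119625
    },
    {
      "name": "autoxidation-deoxy",
      "reactants": {
        "Mb": 1
      },
      "products": {
        "MMb": 1
      },
      "k_ref": 1.94523e-06
    },
    {
      "name": "autoxidation-oxy",
      "reactants": {
        "MbO2": 1
      },
      "products": {
        "MMb": 1
      },
      "k_ref": 7.60837e-07
    },
    {
      "name": "reduction",
      "reactants": {
        "MMb": 1
      },
      "products": {
        "Mb": 1
      },
      "k_ref": 1.47328e-07
    }
  ],
  "T_ref_C": 20,
  "D_O2_m2_s": 1e-10,
  "Ea_kJ_mol": 32.5,
  "o2_solubility_mol_m3_per_pct": 0.017
}
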