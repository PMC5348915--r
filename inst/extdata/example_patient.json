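{
  "patient": {
    "age": 57,
    "sex": "female",
    "height": 166,
    "weight": 61,
    "systolic_pressure": 139,
    "diastolic_pressure": 80,
    "hematocrit": 36,
    "plasma_protein": 6.8,
    "hypertension": true,
    "diabetes": false,
    "avf_arm": "left"
  },
  "dus": {
    "arterial_diameters": {
      "brachial-artery-mid": 4.2,
      "brachial-artery-elbow": 4.0,
      "radial-artery-mid": 2.4,
      "radial-artery-distal": 2.2,
      "ulnar-artery-mid": 2.4,
      "ulnar-artery-distal": 2.2,
      "subclavian-artery": 7.0
    },
    "venous_diameters": {
      "cephalic-vein-wrist": 2.2,
      "cephalic-vein-forearm": 2.6,
      "cephalic-vein-upper": 3.0,
      "cephalic-arch": 3.2,
      "cubital-vein": 3.5,
      "basilic-vein": 3.6,
      "subclavian-vein": 8.5
    },
    "tav": {
      "brachial": 14,
      "radial": 8,
      "ulnar": 7
    }
  },
  "avf": {
    "location": "brachio-cephalic",
    "kind": "end-to-side"
  }
}
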