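{
  "name": "AtNPC default scaffold composition",
  "comment": "Per-asymmetric-unit nucleoporin composition of the A. thaliana NPC scaffold. Species joined by '|' are alternatives modelled as one placement. The speculative NR placement of NUP93A/B and the unmodelled NR outer Y-complex head-to-tail bridge are shipped disabled.",
  "symmetry_order": 8,
  "homologue_map": { "HOS1": "ELYS" },
  "rings": {
    "CR": [
      { "species": "NUP160",        "copies": 1, "subcomplex": "Y-complex" },
      { "species": "NUP85",         "copies": 1, "subcomplex": "Y-complex" },
      { "species": "SEH1",          "copies": 1, "subcomplex": "Y-complex" },
      { "species": "NUP43",         "copies": 1, "subcomplex": "Y-complex" },
      { "species": "NUP96",         "copies": 1, "subcomplex": "Y-complex" },
      { "species": "SEC13A|SEC13B", "copies": 1, "subcomplex": "Y-complex" },
      { "species": "NUP107",        "copies": 1, "subcomplex": "Y-complex" },
      { "species": "NUP133",        "copies": 1, "subcomplex": "Y-complex" },
      { "species": "HOS1",          "copies": 1, "subcomplex": "Y-complex" },
      { "species": "NUP214",        "copies": 1, "subcomplex": "NUP214-complex" },
      { "species": "NUP88",         "copies": 1, "subcomplex": "NUP214-complex" },
      { "species": "NUP62",         "copies": 1, "subcomplex": "NUP214-complex" },
      { "species": "NUP205",        "copies": 2, "subcomplex": "NUP205-NUP93" },
      { "species": "NUP93A|NUP93B", "copies": 2, "subcomplex": "NUP205-NUP93" }
    ],
    "IR": [
      { "species": "NUP155",        "copies": 4, "subcomplex": "connector" },
      { "species": "NUP205",        "copies": 2, "subcomplex": "IR-core" },
      { "species": "NUP93A|NUP93B", "copies": 2, "subcomplex": "IR-core" },
      { "species": "NUP35",         "copies": 2, "subcomplex": "IR-core" },
      { "species": "NDC1",          "copies": 2, "subcomplex": "IR-core" },
      { "species": "ALADIN",        "copies": 2, "subcomplex": "IR-core" },
      { "species": "NUP54",         "copies": 4, "subcomplex": "NUP62-complex" },
      { "species": "NUP58",         "copies": 4, "subcomplex": "NUP62-complex" },
      { "species": "NUP62",         "copies": 4, "subcomplex": "NUP62-complex" }
    ],
    "NR": [
      { "species": "NUP160",        "copies": 2, "subcomplex": "Y-complex" },
      { "species": "NUP85",         "copies": 2, "subcomplex": "Y-complex" },
      { "species": "SEH1",          "copies": 2, "subcomplex": "Y-complex" },
      { "species": "NUP43",         "copies": 2, "subcomplex": "Y-complex" },
      { "species": "NUP96",         "copies": 2, "subcomplex": "Y-complex" },
      { "species": "SEC13A|SEC13B", "copies": 2, "subcomplex": "Y-complex" },
      { "species": "NUP107",        "copies": 2, "subcomplex": "Y-complex" },
      { "species": "NUP133",        "copies": 2, "subcomplex": "Y-complex" },
      { "species": "HOS1",          "copies": 2, "subcomplex": "Y-complex" },
      { "species": "NUP205",        "copies": 1, "subcomplex": "NUP205-NUP93" },
      { "species": "NUP93A|NUP93B", "copies": 1, "subcomplex": "NUP205-NUP93" }
    ]
  },
  "optional": [
    {
      "ring": "NR", "species": "NUP133", "copies": 1,
      "subcomplex": "Y-outer-bridge", "enabled": false,
      "note": "Density possibly matching a NUP133 beta-propeller at the outer Y-complex head-to-tail contact; disabled by default because the interaction is not predicted."
    },
    {
      "ring": "NR", "species": "NUP93A|NUP93B", "copies": 1,
      "subcomplex": "NR-speculative", "enabled": false,
      "note": "Speculative alternative NR position of NUP93A/B; excluded from the default model."
    }
  ]
}
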