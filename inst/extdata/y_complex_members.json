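{
  "comment": "Y-complex (coat nucleoporin complex) membership by organism. SEC13A/SEC13B are one placement (SEC13).",
  "arabidopsis": ["NUP160", "NUP85", "NUP43", "SEH1", "NUP96", "SEC13",
                  "NUP107", "NUP133", "HOS1"],
  "human": ["NUP160", "NUP85", "NUP43", "SEH1", "NUP96", "SEC13",
            "NUP107", "NUP133", "ELYS", "NUP37"],
  "homologue_map": { "HOS1": "ELYS" }
}
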