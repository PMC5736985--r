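{
  "description": "Peptidase family sets flagged by each criterion of the three-way expansion screen over 19 arthropod genomes (focal species Rhodnius prolixus): Mann-Whitney hematophagous vs non-hematophagous, Kruskal-Wallis across taxonomic groups, and the percentile-90 rule.",
  "hema": ["C2", "M17", "M41", "A28", "C64/C85"],
  "taxa": ["A22", "C1", "C13", "C40", "C69", "C86", "M12B", "M17", "M19", "M38", "M79", "M87", "S1", "S10", "S24", "S28", "S33", "S54", "S60", "S72"],
  "p90": ["A1", "C2", "M17", "M74", "N6", "S24", "S29"]
}
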