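{
  "description": "Archetype feature map for A1 aspartic peptidases: human pepsin A, renin and cathepsin D. Feature positions (cysteines, conserved prolines, proline-loop windows, glycosylation triad) use each archetype's own residue numbering. Subsite entries give, for each substrate-binding position (Schechter-Berger S4..S2'), the residue carried by each archetype; their `coord` values are a SYNTHETIC shared coordinate layout (sequential indices, with the two positions shared between S1' and S2' reusing the same coordinate) for queries pre-aligned to this map, not positions in any deposited structure. Users with real archetype alignments should supply their own map in this schema.",
  "synthetic_coordinates": true,
  "archetypes": ["pepsin", "renin", "cathepsinD"],
  "features": {
    "pepsin": {
      "catalytic_positions": [32, 215],
      "catalytic_residues": ["D", "E"],
      "cysteine_positions": [107, 112, 268, 272, 311, 344],
      "first_proline": 85,
      "proline_loop_window": [354, 355, 356],
      "glyc_triad_positions": [126, 245, 249],
      "glyc_triad_residues": ["T", "R", "E"]
    },
    "renin": {
      "catalytic_positions": [38, 226],
      "catalytic_residues": ["D", "E"],
      "cysteine_positions": [117, 124, 283, 287, 325, 362],
      "first_proline": 95,
      "proline_loop_window": [372, 373, 374],
      "glyc_triad_positions": [141, 260, 264],
      "glyc_triad_residues": ["N", "N", "T"]
    },
    "cathepsinD": {
      "catalytic_positions": [33, 231],
      "catalytic_residues": ["D", "E"],
      "cysteine_positions": [110, 117, 286, 290, 329, 366],
      "first_proline": 88,
      "proline_loop_window": [376, 377, 378],
      "glyc_triad_positions": [134, 263, 267],
      "glyc_triad_residues": ["N", "N", "K"]
    }
  },
  "subsites": {
    "S4": [
      {"coord": 1, "pepsin": "M", "renin": "T", "cathepsinD": "A"},
      {"coord": 2, "pepsin": "S", "renin": "S", "cathepsinD": "S"},
      {"coord": 3, "pepsin": "L", "renin": "Y", "cathepsinD": "L"}
    ],
    "S3": [
      {"coord": 4, "pepsin": "E", "renin": "Q", "cathepsinD": "Q"},
      {"coord": 5, "pepsin": "T", "renin": "T", "cathepsinD": "S"},
      {"coord": 6, "pepsin": "F", "renin": "P", "cathepsinD": "T"},
      {"coord": 7, "pepsin": "L", "renin": "F", "cathepsinD": "F"},
      {"coord": 8, "pepsin": "F", "renin": "F", "cathepsinD": "F"},
      {"coord": 9, "pepsin": "G", "renin": "G", "cathepsinD": "G"},
      {"coord": 10, "pepsin": "T", "renin": "A", "cathepsinD": "T"},
      {"coord": 11, "pepsin": "S", "renin": "S", "cathepsinD": "S"}
    ],
    "S2": [
      {"coord": 12, "pepsin": "Y", "renin": "Y", "cathepsinD": "Y"},
      {"coord": 13, "pepsin": "G", "renin": "S", "cathepsinD": "G"},
      {"coord": 14, "pepsin": "T", "renin": "T", "cathepsinD": "S"},
      {"coord": 15, "pepsin": "G", "renin": "G", "cathepsinD": "G"},
      {"coord": 16, "pepsin": "T", "renin": "A", "cathepsinD": "T"},
      {"coord": 17, "pepsin": "T", "renin": "S", "cathepsinD": "V"},
      {"coord": 18, "pepsin": "Q", "renin": "H", "cathepsinD": "M"},
      {"coord": 19, "pepsin": "M", "renin": "M", "cathepsinD": "M"},
      {"coord": 20, "pepsin": "I", "renin": "A", "cathepsinD": "I"}
    ],
    "S1": [
      {"coord": 21, "pepsin": "V", "renin": "V", "cathepsinD": "V"},
      {"coord": 22, "pepsin": "D", "renin": "D", "cathepsinD": "D"},
      {"coord": 23, "pepsin": "G", "renin": "G", "cathepsinD": "G"},
      {"coord": 24, "pepsin": "T", "renin": "R", "cathepsinD": "H"},
      {"coord": 25, "pepsin": "Y", "renin": "Y", "cathepsinD": "Y"},
      {"coord": 26, "pepsin": "L", "renin": "F", "cathepsinD": "F"},
      {"coord": 27, "pepsin": "F", "renin": "F", "cathepsinD": "F"},
      {"coord": 28, "pepsin": "I", "renin": "V", "cathepsinD": "I"},
      {"coord": 29, "pepsin": "D", "renin": "D", "cathepsinD": "D"}
    ],
    "S1p": [
      {"coord": 30, "pepsin": "G", "renin": "G", "cathepsinD": "G"},
      {"coord": 31, "pepsin": "S", "renin": "S", "cathepsinD": "S"},
      {"coord": 32, "pepsin": "T", "renin": "R", "cathepsinD": "H"},
      {"coord": 33, "pepsin": "Y", "renin": "Y", "cathepsinD": "Y"},
      {"coord": 34, "pepsin": "T", "renin": "A", "cathepsinD": "T"}
    ],
    "S2p": [
      {"coord": 32, "pepsin": "T", "renin": "R", "cathepsinD": "H"},
      {"coord": 33, "pepsin": "Y", "renin": "Y", "cathepsinD": "Y"},
      {"coord": 35, "pepsin": "G", "renin": "S", "cathepsinD": "G"},
      {"coord": 36, "pepsin": "Y", "renin": "V", "cathepsinD": "Y"},
      {"coord": 37, "pepsin": "L", "renin": "I", "cathepsinD": "I"}
    ]
  }
}
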