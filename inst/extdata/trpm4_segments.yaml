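# Curated topology segment map for the human TRPM4 channel (UniProt
# Q8TD43 numbering, matching the author numbering of the tetrameric
# cryo-EM model). Boundaries are approximate, derived from the deposited
# structure annotation; edit freely — all contact counts are reported
# relative to the segment map actually supplied. M1042 is assigned to S6
# (the S6/TRP-helix boundary is placed after it).
segments:
  - {name: "MHR1/2", start: 1, end: 395, region: cytoplasmic}
  - {name: "MHR3", start: 396, end: 588, region: cytoplasmic}
  - {name: "MHR4", start: 589, end: 775, region: cytoplasmic}
  - {name: "Pre-S1", start: 776, end: 784, region: cytoplasmic}
  - {name: "S1", start: 785, end: 812, region: transmembrane_extracellular}
  - {name: "S2", start: 818, end: 844, region: transmembrane_extracellular}
  - {name: "S2-S3 linker", start: 845, end: 859, region: cytoplasmic}
  - {name: "S3", start: 860, end: 884, region: transmembrane_extracellular}
  - {name: "S4", start: 890, end: 911, region: transmembrane_extracellular}
  - {name: "S4-S5 linker", start: 912, end: 927, region: cytoplasmic}
  - {name: "S5", start: 928, end: 955, region: transmembrane_extracellular}
  - {name: "P1", start: 956, end: 972, region: transmembrane_extracellular}
  - {name: "P2", start: 973, end: 990, region: transmembrane_extracellular}
  - {name: "S6", start: 991, end: 1044, region: transmembrane_extracellular}
  - {name: "TRP helix", start: 1045, end: 1070, region: cytoplasmic}
  - {name: "CTD", start: 1071, end: 1214, region: cytoplasmic}
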