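# Deleterious thresholds for 22 pathogenicity predictors (dbNSFP-style
# score columns). direction: damaging_if_greater means score > threshold
# is called Damaging; damaging_if_less means score < threshold.
# Tools that also report categories carry a categorical_map.
ClinPred:
  direction: damaging_if_greater
  threshold: 0.6
VEST4:
  direction: damaging_if_greater
  threshold: 0.65
MCap:
  direction: damaging_if_greater
  threshold: 0.05
REVEL:
  direction: damaging_if_greater
  threshold: 0.45
PrimateAI:
  direction: damaging_if_greater
  threshold: 0.6
MVP:
  direction: damaging_if_greater
  threshold: 0.7
MetaSVM:
  direction: damaging_if_greater
  threshold: 0.0
MetaLR:
  direction: damaging_if_greater
  threshold: 0.4
LIST.S2:
  direction: damaging_if_greater
  threshold: 0.85
DEOGEN2:
  direction: damaging_if_greater
  threshold: 0.4
FATHMM:
  direction: damaging_if_less
  threshold: -1.0
PPH_HDIV:
  direction: damaging_if_greater
  threshold: 0.45
  categorical_map:
    probably damaging: Damaging
    possibly damaging: Damaging
    benign: Tolerated
    D: Damaging
    P: Damaging
    B: Tolerated
CADD:
  direction: damaging_if_greater
  threshold: 3.0
PPH_HVAR:
  direction: damaging_if_greater
  threshold: 0.45
  categorical_map:
    probably damaging: Damaging
    possibly damaging: Damaging
    benign: Tolerated
    D: Damaging
    P: Damaging
    B: Tolerated
SIFT4G:
  direction: damaging_if_less
  threshold: 0.05
DANN:
  direction: damaging_if_greater
  threshold: 0.99
SIFT:
  direction: damaging_if_less
  threshold: 0.0045
PROVEAN:
  direction: damaging_if_less
  threshold: -1.5
MutationAssessor:
  direction: damaging_if_greater
  threshold: 1.7
  categorical_map:
    H: Damaging
    M: Damaging
    L: Tolerated
    N: Tolerated
LRT:
  direction: damaging_if_less
  threshold: 0.0001
MutationTaster:
  direction: damaging_if_greater
  threshold: 1.0
  categorical_map:
    A: Damaging
    D: Damaging
    N: Tolerated
    P: Tolerated
GenoCanyon:
  direction: damaging_if_greater
  threshold: 0.7
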