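# Shipped 691-column feature layout: 38 base annotations (110 columns after
# one-hot expansion) plus 581 combination columns pairing the Consequence,
# oAA and nAA categoricals with positional, conservation and regulatory
# numerics. Combination rules are transcribed from the published composite
# name families (SN_PhyloP, NS_relCDSpos, nAA_*_Grantham, ...); entries not
# resolvable from those name patterns are omitted rather than guessed.
features:
- name: Consequence
  type: categorical
  categories:
  - UP
  - DN
  - U5
  - U3
  - S
  - SN
  - NS
  - NC
  - IG
  - I
  - CS
  - SL
  - SG
  - O
  default: IG
  other: O
  combo_label: category
- name: oAA
  type: categorical
  categories:
  - A
  - C
  - D
  - E
  - F
  - G
  - H
  - I
  - K
  - L
  - M
  - 'N'
  - P
  - Q
  - R
  - S
  - T
  - V
  - W
  - 'Y'
  - '*'
- name: nAA
  type: categorical
  categories:
  - A
  - C
  - D
  - E
  - F
  - G
  - H
  - I
  - K
  - L
  - M
  - 'N'
  - P
  - Q
  - R
  - S
  - T
  - V
  - W
  - 'Y'
  - '*'
- name: ChromState
  type: categorical
  categories:
  - E1
  - E2
  - E3
  - E4
  - E5
  - E6
  - E7
  - E8
  - E9
- name: RepeatFamily
  type: categorical
  categories:
  - LINE
  - LTR
  - DNA
  - RC
  - Helitron
  - Simple_repeat
  - Low_complexity
  - Satellite
  - rRNA
  - snRNA
  - tRNA
  - Unknown
- name: Grantham
  type: numeric
  default: 0.0
- name: CDSpos
  type: numeric
  default: 0.0
- name: relCDSpos
  type: numeric
  default: 0.0
- name: protPos
  type: numeric
  default: 0.0
- name: relProtPos
  type: numeric
  default: 0.0
- name: cDNApos
  type: numeric
  default: 0.0
- name: relcDNApos
  type: numeric
  default: 0.0
- name: minDistTSS
  type: numeric
  default: 0.0
- name: minDistTSE
  type: numeric
  default: 0.0
- name: spliceDist
  type: numeric
  default: 0.0
- name: cdsDist
  type: numeric
  default: 0.0
- name: GC
  type: numeric
  default: 0.0
- name: CpG
  type: numeric
  default: 0.0
- name: PhyloP
  type: numeric
  default: 0.0
- name: PhyloP124
  type: numeric
  default: 0.0
- name: PhyloPAll
  type: numeric
  default: 0.0
- name: PhastCons
  type: numeric
  default: 0.0
- name: PhastCons124
  type: numeric
  default: 0.0
- name: PhastConsAll
  type: numeric
  default: 0.0
- name: GerpRS
  type: numeric
  default: 0.0
- name: GerpRSAll
  type: numeric
  default: 0.0
- name: GerpN
  type: numeric
  default: 0.0
- name: GerpNAll
  type: numeric
  default: 0.0
- name: mgw
  type: numeric
  default: 0.0
- name: roll
  type: numeric
  default: 0.0
- name: helT
  type: numeric
  default: 0.0
- name: proT
  type: numeric
  default: 0.0
- name: ep
  type: numeric
  default: 0.0
- name: ReMapDensity
  type: numeric
  default: 0.0
- name: TFBS
  type: numeric
  default: 0.0
- name: CRM
  type: numeric
  default: 0.0
- name: miRNA
  type: numeric
  default: 0.0
- name: inCDS
  type: numeric
  default: 0.0
combinations:
- categorical: Consequence
  numeric: Grantham
- categorical: Consequence
  numeric: CDSpos
- categorical: Consequence
  numeric: relCDSpos
- categorical: Consequence
  numeric: protPos
- categorical: Consequence
  numeric: relProtPos
- categorical: Consequence
  numeric: cDNApos
- categorical: Consequence
  numeric: relcDNApos
- categorical: Consequence
  numeric: minDistTSS
- categorical: Consequence
  numeric: minDistTSE
- categorical: Consequence
  numeric: spliceDist
- categorical: Consequence
  numeric: cdsDist
- categorical: Consequence
  numeric: PhyloP
- categorical: Consequence
  numeric: PhyloP124
- categorical: Consequence
  numeric: PhyloPAll
- categorical: Consequence
  numeric: PhastCons
- categorical: Consequence
  numeric: PhastCons124
- categorical: Consequence
  numeric: PhastConsAll
- categorical: Consequence
  numeric: GerpRS
- categorical: Consequence
  numeric: GerpRSAll
- categorical: Consequence
  numeric: GerpN
- categorical: Consequence
  numeric: GerpNAll
- categorical: Consequence
  numeric: ReMapDensity
- categorical: Consequence
  numeric: helT
- categorical: Consequence
  numeric: proT
- categorical: Consequence
  numeric: roll
- categorical: oAA
  numeric: Grantham
- categorical: oAA
  numeric: relProtPos
- categorical: oAA
  numeric: PhyloP
- categorical: oAA
  numeric: PhastCons
- categorical: oAA
  numeric: GerpRS
- categorical: nAA
  numeric: Grantham
- categorical: nAA
  numeric: relProtPos
- categorical: nAA
  numeric: PhyloP
- categorical: nAA
  numeric: PhastCons
- categorical: nAA
  numeric: GerpRS
- categorical: nAA
  numeric: relCDSpos
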