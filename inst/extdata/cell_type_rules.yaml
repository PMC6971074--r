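# Default nine cell-type rule table for the inflammatory infiltrate.
# Reconstructed from the published phenotype definitions; rules are data,
# not code -- replace this file to change the classification.
#
# A rule matches a phenocluster when every required_positive marker is
# expressed at high level in >= 1/3 of the cluster's cells and every
# required_negative marker in < 1/3. Highest matching priority wins.
#
# Notes on two reconstructions:
#  - Histiocyte ("CD163 and/or CD68 positive, CD16-negative") is split
#    across the Histiocyte (CD163+ CD16-) and Phagocyte (CD68+ CD163-
#    CD16-) rules, whose union covers the published and/or wording.
#  - MonoMac_undefined ("absence or spotty presence of several monocytic
#    lineage markers") cannot be expressed as fixed positive/negative
#    requirements; it is the lowest-priority CD45+ fallback excluding the
#    lymphoid lineages.
rules:
  - type_name: CD8_T
    required_positive: [CD45, CD3, CD8]
    required_negative: []
    priority: 100
  - type_name: CD4_T
    required_positive: [CD45, CD3, CD4]
    required_negative: []
    priority: 99
  - type_name: NK
    required_positive: [CD45, GranzymeB, Granulysin]
    required_negative: [CD3]
    priority: 98
  - type_name: B
    required_positive: [CD45, CD20]
    required_negative: []
    priority: 97
  - type_name: TAM
    required_positive: [CD16, CD68, CD163]
    required_negative: []
    priority: 96
  - type_name: Histiocyte
    required_positive: [CD163]
    required_negative: [CD16]
    priority: 95
  - type_name: Phagocyte
    required_positive: [CD68]
    required_negative: [CD163, CD16]
    priority: 94
  - type_name: InflammatoryMonocyte
    required_positive: [LYZ, VISTA]
    required_negative: [CD68, CD163]
    priority: 93
  - type_name: MonoMac_undefined
    required_positive: [CD45]
    required_negative: [CD3, CD20, GranzymeB]
    priority: 1
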