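# Default weighting scenarios for the motif ranking score.
# w1: topological pair (degree + betweenness, halved in the score)
# w2: disease-pathway membership   w3: gene-prioritization score
# w4: mean |log2 fold change|
scenarios:
  - {id: S01_uniform,   w1: 1, w2: 1, w3: 1, w4: 1}
  - {id: S02_topo2,     w1: 2, w2: 1, w3: 1, w4: 1}
  - {id: S03_dp2,       w1: 1, w2: 2, w3: 1, w4: 1}
  - {id: S04_gp2,       w1: 1, w2: 1, w3: 2, w4: 1}
  - {id: S05_fc2,       w1: 1, w2: 1, w3: 1, w4: 2}
  - {id: S06_topo_only, w1: 1, w2: 0, w3: 0, w4: 0}
  - {id: S07_dp_only,   w1: 0, w2: 1, w3: 0, w4: 0}
  - {id: S08_gp_only,   w1: 0, w2: 0, w3: 1, w4: 0}
  - {id: S09_fc_only,   w1: 0, w2: 0, w3: 0, w4: 1}
  - {id: S10_topo_dp,   w1: 2, w2: 2, w3: 1, w4: 1}
  - {id: S11_topo_fc,   w1: 2, w2: 1, w3: 1, w4: 2}
  - {id: S12_dp_gp,     w1: 1, w2: 2, w3: 2, w4: 1}
  - {id: S13_gp_fc,     w1: 1, w2: 1, w3: 2, w4: 2}
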