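# Template hierarchical gating scheme for the six-class leukocyte-like
# population: a debris keep-gate on the FSC/BSC plane followed by ordered
# rectangular assign-gates (basophils, monocytes, stem-like cells,
# lymphocytes, neutrophils, eosinophils) on synthetic scatter features.
# Coordinates are in raw (linear) scalar units of the simulated channels.
gating:
  scheme:
    - action: keep
      gate: {name: not_debris, x_feature: fsc_area, y_feature: bsc,
             xlim: [40, 2000], ylim: [5, 2000]}
    - action: assign
      class: basophil
      gate: {name: baso, x_feature: fsc_area, y_feature: bsc,
             xlim: [120, 260], ylim: [180, 420]}
    - action: assign
      class: monocyte
      gate: {name: mono, x_feature: fsc_area, y_feature: bsc,
             xlim: [380, 900], ylim: [60, 260]}
    - action: assign
      class: hsc
      gate: {name: hsc, x_feature: fsc_area, y_feature: bsc,
             xlim: [110, 240], ylim: [30, 120]}
    - action: assign
      class: lymphocyte
      gate: {name: lymph, x_feature: fsc_area, y_feature: bsc,
             xlim: [40, 170], ylim: [5, 90]}
    - action: assign
      class: neutrophil
      gate: {name: neut, x_feature: fsc_area, y_feature: bsc,
             xlim: [200, 520], ylim: [90, 320]}
    - action: assign
      class: eosinophil
      gate: {name: eos, x_feature: fsc_area, y_feature: bsc,
             xlim: [220, 560], ylim: [250, 700]}
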