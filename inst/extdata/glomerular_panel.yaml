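# 10-antibody, 3-cycle MxIF panel for glomerular cell typing.
# expected_segments: canonical cell-type tags each target marks inside the
# glomerular tuft (empty for extraglomerular / vascular targets).
panel:
  - target: "Collagen IV a1/2"
    cell_structures: "Tubular basement membrane, mesangial matrix, and glomerular capsule"
    cycle: 1
    fluorophore: "Cy5"
    conjugation: indirect
    expected_segments: [mesangial]
  - target: "Collagen IV a5"
    cell_structures: "Glomerular basement membrane, glomerular capsule, and collecting duct and distal convoluted tubule basement membrane"
    cycle: 1
    fluorophore: "Cy3"
    conjugation: indirect
    expected_segments: [basement_membrane]
  - target: "Tensin"
    cell_structures: "Mesangial cells and vascular smooth muscle cells"
    cycle: 1
    fluorophore: "AF 488"
    conjugation: indirect
    expected_segments: [mesangial]
  - target: "Podocalyxin"
    cell_structures: "Podocyte cytoplasm and plasma membrane"
    cycle: 2
    fluorophore: "AF 488"
    conjugation: direct
    expected_segments: [podocyte]
  - target: "Fibronectin"
    cell_structures: "Mesangial matrix and muscularized vessel walls"
    cycle: 2
    fluorophore: "AF 594"
    conjugation: direct
    expected_segments: [mesangial]
  - target: "CD31"
    cell_structures: "Endothelial cells"
    cycle: 2
    fluorophore: "AF 647"
    conjugation: direct
    expected_segments: [endothelial]
  - target: "Synaptopodin"
    cell_structures: "Podocyte cytoplasm and plasma membrane"
    cycle: 2
    fluorophore: "Cy7"
    conjugation: direct
    expected_segments: [podocyte]
  - target: "Nestin"
    cell_structures: "Podocyte cytoplasm"
    cycle: 3
    fluorophore: "AF 488"
    conjugation: direct
    expected_segments: [podocyte]
  - target: "aSMA"
    cell_structures: "Vascular smooth muscle cells"
    cycle: 3
    fluorophore: "AF 594"
    conjugation: direct
    expected_segments: []
  - target: "AQP1"
    cell_structures: "Proximal tubules"
    cycle: 3
    fluorophore: "AF 647"
    conjugation: direct
    expected_segments: []
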