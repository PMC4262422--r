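epitopes:
  - name: "4C1"
    description: >-
      Cross-reactive 4C1 monoclonal-antibody binding surface of group 1
      mite allergens; 14 residues in Der f 1 mature coordinates.
    positions: [14, 16, 18, 19, 21, 156, 157, 159, 181, 182, 186, 199, 202, 204]
    residues: ["E", "D", "R", "S", "R", "G", "R", "I", "T", "Q", "Y", "D", "Y", "Y"]
  - name: "Ca"
    description: >-
      Calcium-coordination epitope; 4 residues in Der f 1 mature
      coordinates.
    positions: [57, 58, 60, 92]
    residues: ["D", "L", "E", "E"]
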