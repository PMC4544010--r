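# 2360-cell three-marker fixture: Nanog plus the lineage markers Crabp2
# (ectoderm) and T/Brachyury (mesendoderm). Cutoffs: Nanog 30, Crabp2 30,
# T 50 transcripts/cell. 138 cells are Nanog(-); 25 of them (18%) express a
# lineage marker, including exactly 2 cells positive for BOTH Crabp2 and T.
# Marker-positive levels follow the observed scales: tens of transcripts for
# Crabp2, hundreds for T.
name: fig4b
kind: fish
seed: 8842
genes: [Nanog, Crabp2, T]
cutoffs: {Nanog: 30, Crabp2: 30, T: 50}
classes:
  - class_name: NanogPos
    n_cells: 2222
    guard_margin: 0.2
    per_gene_dist:
      Nanog:  {family: lognormal-rounded, location: 160, shape: 0.45, side: "+"}
      Crabp2: {family: negative-binomial, location: 2, dispersion: 0.5, side: "-"}
      T:      {family: negative-binomial, location: 2, dispersion: 0.5, side: "-"}
  - class_name: NanogNeg.noMarker
    n_cells: 113
    guard_margin: 0.2
    per_gene_dist:
      Nanog:  {family: negative-binomial, location: 5, dispersion: 0.5, side: "-"}
      Crabp2: {family: negative-binomial, location: 2, dispersion: 0.5, side: "-"}
      T:      {family: negative-binomial, location: 2, dispersion: 0.5, side: "-"}
  - class_name: NanogNeg.Crabp2Pos
    n_cells: 14
    guard_margin: 0.2
    per_gene_dist:
      Nanog:  {family: negative-binomial, location: 5, dispersion: 0.5, side: "-"}
      Crabp2: {family: lognormal-rounded, location: 70, shape: 0.35, side: "+"}
      T:      {family: negative-binomial, location: 2, dispersion: 0.5, side: "-"}
  - class_name: NanogNeg.TPos
    n_cells: 9
    guard_margin: 0.2
    per_gene_dist:
      Nanog:  {family: negative-binomial, location: 5, dispersion: 0.5, side: "-"}
      Crabp2: {family: negative-binomial, location: 2, dispersion: 0.5, side: "-"}
      T:      {family: lognormal-rounded, location: 250, shape: 0.40, side: "+"}
  - class_name: NanogNeg.Crabp2Pos.TPos
    n_cells: 2
    guard_margin: 0.2
    per_gene_dist:
      Nanog:  {family: negative-binomial, location: 5, dispersion: 0.5, side: "-"}
      Crabp2: {family: lognormal-rounded, location: 70, shape: 0.35, side: "+"}
      T:      {family: lognormal-rounded, location: 250, shape: 0.40, side: "+"}
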