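# 764-cell mesoderm-coexpression fixture: Tbx6, T and Oct4. Cutoffs:
# Tbx6 10, T 50, Oct4 80 transcripts/cell. Exactly 7 cells are T(+), and the
# 2 Tbx6(+) cells are a subset of them; all lineage-marker-positive cells
# are Oct4(-), matching the observation that Tbx6(+) cells have exited the
# Oct4-maintaining state.
name: fig4c
kind: fish
seed: 8843
genes: [Tbx6, T, Oct4]
cutoffs: {Tbx6: 10, T: 50, Oct4: 80}
classes:
  - class_name: Main.Oct4Pos
    n_cells: 757
    guard_margin: 0.2
    per_gene_dist:
      Tbx6: {family: negative-binomial, location: 1, dispersion: 0.5, side: "-"}
      T:    {family: negative-binomial, location: 2, dispersion: 0.5, side: "-"}
      Oct4: {family: lognormal-rounded, location: 380, shape: 0.40, side: "+"}
  - class_name: TPos.Oct4Neg
    n_cells: 5
    guard_margin: 0.2
    per_gene_dist:
      Tbx6: {family: negative-binomial, location: 1, dispersion: 0.5, side: "-"}
      T:    {family: lognormal-rounded, location: 250, shape: 0.40, side: "+"}
      Oct4: {family: negative-binomial, location: 18, dispersion: 0.4, side: "-"}
  - class_name: Tbx6Pos.TPos.Oct4Neg
    n_cells: 2
    guard_margin: 0.2
    per_gene_dist:
      Tbx6: {family: lognormal-rounded, location: 40, shape: 0.35, side: "+"}
      T:    {family: lognormal-rounded, location: 250, shape: 0.40, side: "+"}
      Oct4: {family: negative-binomial, location: 18, dispersion: 0.4, side: "-"}
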