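# 1189-cell two-marker fixture: nested Nanog/Oct4 subpopulations.
# Composition encodes the printed summary: 1129 Nanog(+)Oct4(+) cells,
# 60 Nanog(-) of which 44 are also Oct4(-). Cutoffs: Nanog 30, Oct4 80
# transcripts/cell. Within-class count distributions are synthetic plumbing
# (guarded so thresholding recovers the latent classes exactly); only the
# class sizes and cutoffs carry meaning.
name: fig4a
kind: fish
seed: 8841
genes: [Nanog, Oct4]
cutoffs: {Nanog: 30, Oct4: 80}
classes:
  - class_name: NanogPos.Oct4Pos
    n_cells: 1129
    guard_margin: 0.2
    per_gene_dist:
      Nanog: {family: lognormal-rounded, location: 160, shape: 0.45, side: "+"}
      Oct4:  {family: lognormal-rounded, location: 380, shape: 0.40, side: "+"}
  - class_name: NanogNeg.Oct4Pos
    n_cells: 16
    guard_margin: 0.2
    per_gene_dist:
      Nanog: {family: negative-binomial, location: 6, dispersion: 0.5, side: "-"}
      Oct4:  {family: lognormal-rounded, location: 320, shape: 0.40, side: "+"}
  - class_name: NanogNeg.Oct4Neg
    n_cells: 44
    guard_margin: 0.2
    per_gene_dist:
      Nanog: {family: negative-binomial, location: 5, dispersion: 0.5, side: "-"}
      Oct4:  {family: negative-binomial, location: 18, dispersion: 0.4, side: "-"}
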