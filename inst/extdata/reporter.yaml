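# 2000-cell reporter-infidelity fixture: endogenous Nanog mRNA vs the VNP
# reporter transcript. Each Nanog-mRNA(+) cell is a reporter false negative
# with probability 0.5 (its VNP count is redrawn below the VNP cutoff while
# its Nanog count is untouched). The base mix (1333 Nanog(+) : 667 Nanog(-))
# represents a Nanog-low-enriched imaging sample and makes the implied
# composition of the VNP(-) pool 50% Nanog-mRNA(+).
name: reporter
kind: reporter
seed: 8844
n_cells: 2000
fn_fraction: 0.5
mrna_gene: Nanog
reporter_gene: VNP
fn_reporter_dist: {family: negative-binomial, location: 4, dispersion: 0.5}
base_classes:
  name: reporter-base
  seed: 8844
  genes: [Nanog, VNP]
  cutoffs: {Nanog: 30, VNP: 30}
  classes:
    - class_name: NanogPos
      n_cells: 1333
      guard_margin: 0.2
      per_gene_dist:
        Nanog: {family: lognormal-rounded, location: 160, shape: 0.45, side: "+"}
        VNP:   {family: lognormal-rounded, location: 120, shape: 0.45, side: "+"}
    - class_name: NanogNeg
      n_cells: 667
      guard_margin: 0.2
      per_gene_dist:
        Nanog: {family: negative-binomial, location: 5, dispersion: 0.5, side: "-"}
        VNP:   {family: negative-binomial, location: 4, dispersion: 0.5, side: "-"}
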