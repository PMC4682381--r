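# Regenerates inst/extdata/default_potential.tsv: a small pairwise
# potential trained on a fixed set of synthetic fixture dimers. Run from
# the package root.
devtools::load_all(".")
specs <- lapply(1:10, function(i) {
  dimer_spec(n_residues = 26, n_interface = 10,
             interface_polar_frac = 0.5, surface_polar_frac = 0.55,
             charged_frac = 0.2, n_hbonds = 2, n_salt_bridges = 2,
             seed = 1000 + i)
})
fixtures <- lapply(specs, function(s) build_dimer(s)$complex)
pot <- train_potential(fixtures)
write_potential(pot, "inst/extdata/default_potential.tsv")
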