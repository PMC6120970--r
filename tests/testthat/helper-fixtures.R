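# shared fixtures: pressure-basis kinetics and leaves for the two
# reference preparations, built from the packaged parameter sets
tobacco_k <- function() resolve_to_pressure(genotype_kinetics("tobacco-WT"))
cyls_k <- function() resolve_to_pressure(genotype_kinetics("CyLS"))
tobacco_leaf <- function() leaf_parameters(E = 21.9)
cyls_leaf <- function(E = 2.1) leaf_parameters(E = E)

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# noiseless Michaelis-Menten series on a given grid
mm_series <- function(Vmax, Km, S) {
  assay_dataset(S, Vmax * S / (Km + S))
}
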