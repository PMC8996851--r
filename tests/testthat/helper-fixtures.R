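# Shared fixtures for the suite. All synthetic; nothing is read from disk
# except the package's own bundled extdata.

hsg_mmkm <- function() mmkm_params()          # 0.32, 3.9, 0.172, 0.0615
hsg_z0 <- function() saturation_parameter(0.32, 3.9, 0.0615)

# synthetic X-ray reference used throughout the tests (the published
# reference coefficients are not available)
test_ref <- function() reference_radiation(0.3, 0.0615)

ref_lq <- function(ref) lq_coefficients(ref$alpha_ref, ref$beta_ref)

# small random but valid coefficient table
random_table <- function(n_ions = 3, n_energy = 5) {
  ions <- sample(supported_ions(), n_ions)
  per <- lapply(ions, function(nm) {
    e <- sort(runif(n_energy, 0.1, 400))
    while (any(diff(e) <= 0)) e <- sort(runif(n_energy, 0.1, 400))
    data.frame(energy = e,
               alpha = runif(n_energy, 0, 2),
               beta = runif(n_energy, 0, 0.2))
  })
  names(per) <- ions
  survival_table(per, model = "synthetic", cell_line = "test")
}

# tiny deterministic two-ion table for actor tests
toy_table <- function() {
  survival_table(list(
    carbon = data.frame(energy = c(0.1, 400), alpha = c(0.2, 0.2),
                        beta = c(0.05, 0.05)),
    helium = data.frame(energy = c(0.1, 400), alpha = c(0.1, 0.3),
                        beta = c(0.05, 0.05))
  ), model = "toy", cell_line = "test")
}

# direct (two-pass, batch) evaluation of the Kanai mixing rule on a record
# data.frame: the independent oracle for the streaming accumulator
batch_mix <- function(records, table) {
  co <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    k <- interpolate_coefficients(table, records$ion[i], records$E[i])
    c(alpha = k$alpha, beta = k$beta)
  }))
  out <- lapply(split(seq_len(nrow(records)), records$voxel), function(idx) {
    f <- records$edep[idx] / sum(records$edep[idx])
    c(edep = sum(records$edep[idx]),
      alpha = sum(f * co[idx, "alpha"]),
      beta = sum(f * co[idx, "beta"]))
  })
  out[order(as.integer(names(out)))]
}
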