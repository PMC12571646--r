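# Small hand-built ensembles with exactly known PPII content.

# every residue of every chain at fixed (phi, psi) in every frame
constant_ensemble <- function(n_frames, n_chains, n_res, phi, psi, dt_ns = 1) {
  ens <- tidyr::expand_grid(
    frame = seq_len(n_frames),
    chain = sprintf("chain_%d", seq_len(n_chains)),
    residue_index = seq_len(n_res)
  )
  ens$time_ns <- ens$frame * dt_ns
  ens$residue_name <- "G"
  ens$phi_deg <- phi
  ens$psi_deg <- psi
  ens[, c("frame", "time_ns", "chain", "residue_index", "residue_name", "phi_deg", "psi_deg")]
}

# angles chosen per (frame, residue) by a vectorized rule returning TRUE
# (inside the default window) or FALSE (far outside)
rule_ensemble <- function(n_frames, n_chains, n_res, inside_rule, dt_ns = 1) {
  ens <- constant_ensemble(n_frames, n_chains, n_res, 0, 0, dt_ns)
  inside <- inside_rule(ens$frame, ens$chain, ens$residue_index)
  ens$phi_deg <- ifelse(inside, -75, 60)
  ens$psi_deg <- ifelse(inside, 150, -60)
  ens
}
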