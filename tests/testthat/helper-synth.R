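# shared small fixtures, built in code

small_grid <- function(n = 10) depth_grid(n_layers = n)

# drainage + VN retentions used across tests (b = 7 s/mm^2 presets)
b7_retentions <- function() {
  comps <- preset_compartments()
  list(vein = vn_attenuation(7, comps$vein),
       cap = vn_attenuation(7, comps$capillary))
}

# block covariance: r within the first `k` channels, identity elsewhere
block_cov <- function(n_ch, k, r) {
  S <- diag(n_ch)
  S[seq_len(k), seq_len(k)] <- r
  diag(S) <- 1
  S
}
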