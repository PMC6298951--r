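# shared fixtures, built in code at load time (cheap; reused across files)
fix_axis <- freq_axis(200, 20000, 64)
fix_hrtf <- synth_hrtf(hrtf_params(seed = 42), axis = fix_axis)
fix_obs <- observer(fix_hrtf)

# a noiseless, flat-prior observer with uniform weights: the veridical limit
fix_obs_ideal <- observer(fix_hrtf, weights = rep(1, length(fix_axis)),
                          sigma_prior = 1e6, sensory_noise_sd = 0,
                          internal_noise_sd = 0)

# tiny hand-made template set on a 3-band axis for exact correlation checks
toy_templates <- function(rows, f = c(4000, 6000, 9000)) {
  structure(list(elevations = seq(0, by = 10, length.out = nrow(rows)),
                 axis = structure(f, class = "freq_axis"),
                 gain_db = rows, params = NULL),
            class = "hrtf_set")
}
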