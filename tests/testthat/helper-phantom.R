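# shared fixtures, generated in code

TE12 <- te_schedule_12()

# a homogeneous rectangular phantom with one region
box_phantom <- function(decay, dims = c(10, 10, 10), angle = 0,
                        noise = "gaussian", snr = 35, seed = 1, coeff = 0) {
  phantom_spec(
    dims, c(0.25, 0.25, 0.4),
    list(region_spec(1L, list(type = "band",
                              x_mm = c(0, dims[1] * 0.25),
                              y_mm = c(0, dims[2] * 0.25)),
                     decay, anisotropy_rate_coeff = coeff)),
    fiber_angle_deg = angle, noise_model = noise,
    snr_first_echo = snr, seed = seed)
}

table2_roi1_0 <- function() bi_params(56.14, 43.86, 1.34, 4.50)
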