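# Shared fixtures: noise-free ground truths, standard parameter sets, and
# constructed angle-moment curves with known neutral-zone widths.

sls_fixture <- function() sls_params(k_maxwell = 0.5, k_parallel = 1.0,
                                     tau = 100)

prony_fixture <- function() prony_params(k_inf = 1.0, k = c(0.3, 0.2),
                                         tau = c(10, 1000))

# Kelvin-solid truth with no NZ, no noise, no angle gain: the pure
# mechanical model, for oracle and limit-case checks
clean_truth <- function(params) {
  ground_truth_spec(params, nz_width = 0, nz_slope = 0,
                    stiffness_angle_gain = 0,
                    force_noise_sd = 0, angle_noise_sd = 0)
}

# piecewise-linear curve: slope `soft` up to `nz`, then slope `stiff`
nz_curve <- function(nz, soft = 0.05, stiff = 1.0, a_max = 25,
                     bin = 0.25) {
  a <- seq(0, a_max, by = bin)
  m <- ifelse(a <= nz, soft * a, soft * nz + (a - nz) * stiff)
  data.frame(angle = a, moment = m)
}

# short noiseless synthetic protocol used across modules
quick_protocol <- function(fraction = 0.6, hold = 60, FR = 50,
                           force_rate = 1000)
  protocol_spec(FR_angle = FR, target_fraction_FR = fraction,
                hold_duration = hold, force_rate_hz = force_rate)

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
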