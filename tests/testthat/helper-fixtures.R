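# Shared fixtures, all generated in code.

# uniformly rotating unwrapped phase at frequency f Hz
linear_phase <- function(f, duration, fs, phi0 = 0, kind = "phase") {
  phase_series(phi0 + 2 * pi * f * (0:(round(duration * fs) - 1)) / fs,
               fs = fs, kind = kind)
}

# the pinned parameter-recovery configuration:
# dphi1/dt = 2*pi*1.1 + 0.4 sin(phi2) + xi (sd 0.1), driver at 0.25 Hz
recovery_pair <- function(seed, duration = 600, fs = 50, coef = 0.4,
                          noise = 0.1, driver_noise = 0.1) {
  sp1 <- oscillator_spec(2 * pi * 1.1,
                         list(coupling_term(0, 1, "sin", coef)),
                         noise = noise)
  sp2 <- oscillator_spec(2 * pi * 0.25, noise = driver_noise)
  simulate_phase_pair(sp1, sp2, duration, fs, seed = seed)
}

# small protocol for pipeline tests: 4 stages x 150 s keeps 2-3 windows
# per stage
short_protocol <- function() {
  protocol_spec(duration_s = rep(150, 4))
}

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
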