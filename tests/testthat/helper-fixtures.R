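# Shared fixtures: temp-file writers and reference parameter sets.

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# The sensor's characterised photophysics: tau_D = 0.33 ms, tau_DR = 3.5 ms,
# J = 3.22591e15 M^-1 cm^-1 nm^4, kappa2 = 2/3, n = 1.4.
sensor_params <- function() {
  fret_parameters(J = 3.22591e15, tau_D = 0.33, tau_DR = 3.5)
}

# Boxcar spectrum: constant value on [540, 550] at 1 nm spacing.
boxcar_spectrum <- function(value, kind) {
  spectrum(540:550, rep(value, 11), kind = kind)
}
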