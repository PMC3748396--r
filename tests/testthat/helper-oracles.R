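# Brute-force quadrature oracle for the PRC cross-correlation
# h_nm(phi) = (1/2/pi) integral Delta_n(theta) Delta_m(theta + phi) dtheta,
# independent of the FFT path used by the package.
brute_h <- function(prc_n, prc_m, phi, n_quad = 2048) {
  th <- 2 * pi * (seq_len(n_quad) - 1) / n_quad
  dn <- prc_eval(prc_n, th)
  vapply(phi, function(p) mean(dn * prc_eval(prc_m, th + p)), numeric(1))
}

# The reference heterogeneous double-sinusoidal pair used throughout the
# synchrony examples (one good, one bad synchronizer).
ref_pair <- function() {
  list(p1 = prc_double_sine(0.1, 0.32), p2 = prc_double_sine(0.6, 0.3))
}

expect_density_close <- function(emp, ref, max_z = 3, frac_over = 0) {
  # emp: empirical density with an `se` column; ref: reference density
  z <- abs(emp$density - density_interp(ref, emp$phi)) / pmax(emp$se, 1e-12)
  expect_lte(mean(z > max_z), frac_over + 1e-12)
}
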