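test_that("parameter sets validate and the printed same-frequency pair matches", {
  expect_error(ml_params(gCa = -1), "conductances")
  expect_error(ml_params(foo = 1), "unknown")
  cA <- find_limit_cycle(ml_params(I = 110, phi_w = 0.04616))
  cB <- find_limit_cycle(ml_params(I = 120, phi_w = 0.04))
  # tuned to fire at the same frequency
  expect_lt(abs(cA$period - cB$period) / cB$period, 0.001)
  expect_equal(cB$period, 73.09, tolerance = 0.001)
})

test_that("deterministic simulation is bounded and periodic; quiescence is flagged", {
  p <- ml_params(I = 120, phi_w = 0.04)
  tr <- simulate_ml_pair(p, p, sigma = 0, tau = 5, c = 0, T = 2000,
                         record_dt = 0.1)
  expect_true(all(tr$V1_mV > -84 & tr$V1_mV < 120))
  # below rheobase: no oscillation detected
  expect_error(find_limit_cycle(ml_params(I = 30, phi_w = 0.04)),
               "no oscillation")
})

test_that("perfectly correlated noise drives identical cells identically", {
  p <- ml_hopf_params()
  t1 <- simulate_ml_pair(p, p, sigma = 2, tau = 5, c = 1, T = 500, seed = 3,
                         state0 = c(-26, 0.1, -26, 0.1))
  expect_identical(t1$V1_mV, t1$V2_mV)
})

test_that("limit cycles close and are insensitive to the initial condition", {
  cyc <- find_limit_cycle(ml_hopf_params())
  expect_lt(cyc$closure, 1e-6)
  expect_gt(cyc$period, 0)
  # a different transient (hence different attained state) gives the same period
  cyc2 <- find_limit_cycle(ml_hopf_params(), transient = 3173)
  expect_lt(abs(cyc$period - cyc2$period) / cyc$period, 1e-4)
})

test_that("the adjoint PRC is normalized and matches direct perturbations", {
  hopf <- ml_hopf_params()
  cyc <- find_limit_cycle(hopf)
  z <- adjoint_prc(cyc)
  # Z . F constant along the cycle (pre-correction spread is small)
  expect_lt(attr(z, "normalization_spread"), 0.05)
  pp <- pulse_prc(cyc, n_phases = 16)
  za <- prc_eval(z, pp$theta)
  expect_lt(max(abs(pp$prc - za)) / max(abs(za)), 0.02)
})

test_that("Hopf and SNIC regimes give characteristically different PRCs", {
  zh <- adjoint_prc(find_limit_cycle(ml_hopf_params()))
  zs <- adjoint_prc(find_limit_cycle(ml_snic_params()))
  th <- seq(0, 2 * pi, length.out = 200)
  vh <- prc_eval(zh, th); vs <- prc_eval(zs, th)
  # Hopf: substantial negative lobe; SNIC: predominantly non-negative
  expect_gt(-min(vh) / max(vh), 0.15)
  expect_lt(-min(vs) / max(vs), 0.10)
  expect_gt(mean(vs < 0), 0) # small negative dip allowed
  expect_gt(mean(vh < 0), 0.3)
})

test_that("same-frequency construction matches the Hopf period", {
  Th <- find_limit_cycle(ml_hopf_params())$period
  Ts <- find_limit_cycle(ml_snic_params())$period
  expect_lt(abs(Th - Ts) / Th, 0.001)
})

test_that("Hilbert phase is linear on the noise-free cycle and uniform", {
  hopf <- ml_hopf_params()
  cyc <- find_limit_cycle(hopf)
  tr <- simulate_ml_pair(hopf, hopf, sigma = 0, tau = 5, c = 0, T = 2200,
                         record_dt = 0.02, seed = 1)
  # resample 16 whole periods onto 128 points each (an FFT-friendly
  # length), so the record is exactly periodic
  t0 <- 500
  tt <- t0 + cyc$period * (0:(16 * 128 - 1)) / 128
  v <- stats::approx(tr$t_ms, tr$V1_mV, xout = tt)$y
  ph <- hilbert_phase(v, cyc)
  expct <- (2 * pi * (tt - tt[1]) / cyc$period + ph[1]) %% (2 * pi)
  expect_lt(max(abs(wrap_pi(ph - expct))), 0.02)
  # phase distribution of the noise-free cycle is uniform after the remap
  ks <- suppressWarnings(stats::ks.test(ph / (2 * pi), "punif"))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("independent noise leaves the biophysical phase difference flat", {
  # with c = 0 the phase difference only diffuses (no restoring drift), so
  # it mixes slowly; a strong drive and a long run keep the Monte Carlo
  # error on the order parameter small
  d <- ml_phase_difference_density(ml_hopf_params(), ml_hopf_params(),
                                   sigma = 4, tau = 5, c = 0,
                                   T = 300000, seed = 7, n_bins = 25)
  expect_lt(order_parameter(d)$OP, 0.15)
})

test_that("biophysical, phase-reduced and BVP densities agree (two-level reduction)", {
  hopf <- ml_hopf_params(); snic <- ml_snic_params()
  cych <- find_limit_cycle(hopf); cycs <- find_limit_cycle(snic)
  pm <- ml_phase_model(cych, cycs, tau_ms = 5, sigma = 2)
  expect_equal(pm$omega, 0, tolerance = 1e-4)

  d_ml <- ml_phase_difference_density(hopf, snic, sigma = 2, tau = 5, c = 0.8,
                                      T = 400000, seed = 5, n_bins = 16)
  tr <- simulate_phase_pair(pm$prc1, pm$prc2, eps = pm$eps, omega = 0,
                            tau = pm$tau, c = 0.8, dt = 0.02, T = 2e5,
                            seed = 6)
  d_ph <- empirical_density(tr, 16)
  d_bvp <- solve_density(build_problem(pm$prc1, pm$prc2, pm$tau, 0.8, 0))

  argmax <- function(d) d$phi[which.max(d$density)]
  binw <- 2 * pi / 16
  expect_lt(abs(argmax(d_ml) - argmax(d_ph)), binw + 1e-9)
  bvp_at <- function(d) density_interp(d_bvp, d$phi)
  # common peak shifted off the origin for the heterogeneous pair
  expect_lt(argmax(d_ph), -0.3)
  expect_lt(abs(argmax(d_ml) - d_bvp$phi[which.max(d_bvp$density)]),
            2 * binw + 1e-9)
  # amplitudes agree within ~15%
  expect_lt(abs(max(d_ml$density) - max(d_bvp$density)) / max(d_bvp$density),
            0.15)
  expect_lt(abs(max(d_ph$density) - max(d_bvp$density)) / max(d_bvp$density),
            0.15)

  # Hopf-Hopf synchronizes better than SNIC-SNIC at the same correlation
  dh <- ml_phase_difference_density(hopf, hopf, sigma = 2, tau = 5, c = 0.8,
                                    T = 120000, seed = 2, n_bins = 25)
  ds <- ml_phase_difference_density(snic, snic, sigma = 2, tau = 5, c = 0.8,
                                    T = 120000, seed = 3, n_bins = 25)
  expect_gt(order_parameter(dh)$OP, order_parameter(ds)$OP)
})

test_that("ML traces export to CSV", {
  p <- ml_hopf_params()
  tr <- simulate_ml_pair(p, p, sigma = 0, tau = 5, c = 0, T = 10)
  f <- tempfile(fileext = ".csv")
  write_ml_trace_csv(tr, f)
  expect_equal(names(utils::read.csv(f)),
               c("t_ms", "V1_mV", "w1", "V2_mV", "w2"))
})
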