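test_that("the OU filter scales harmonics by 1/(1 + k^2 tau^2)", {
  p <- prc_double_sine(0, 0) # h = cos(phi)/2
  g <- filtered_correlation(p, p, tau = 1)
  expect_equal(g$values, cos(g$grid) / 4, tolerance = 1e-12)
  # white-noise limit returns h unchanged
  h <- cross_correlation_h(p, p)
  g0 <- filtered_correlation(p, p, tau = 1e-6)
  expect_lt(max(abs(g0$values - h$values)), 1e-4)
  # a constant function passes through for every tau (unit-mass kernel)
  cst <- prc_tabulated(2 * pi * (0:31) / 32, rep(0.7, 32))
  gc <- filtered_correlation(cst, cst, tau = 3)
  expect_equal(gc$values, rep(0.49, gc$n), tolerance = 1e-10)
  expect_error(filtered_correlation(p, p, tau = 0), "positive")
})

test_that("problem assembly satisfies the printed structural identities", {
  pr <- ref_pair()
  # identical PRCs: C2 = 0 exactly (to rounding) and g even
  prob_id <- build_problem(pr$p1, pr$p1, tau = 1.3, c = 0.5)
  expect_equal(prob_id$C2, 0, tolerance = 1e-14)
  expect_equal(pf_eval(prob_id$g, 0.7), pf_eval(prob_id$g, -0.7),
               tolerance = 1e-12)

  # first-harmonic pairs: (1+tau^2)*C1 = (1+tau^2)(sin^2 a1 + sin^2 a2) + 1
  for (tau in c(0.25, 1, 4)) {
    for (aa in list(c(0.1, 0.6), c(0.3, 1.2))) {
      pb <- build_problem(prc_double_sine(aa[1], 0), prc_double_sine(aa[2], 0),
                          tau, c = 0.5)
      expect_equal((1 + tau^2) * pb$C1,
                   (1 + tau^2) * (sin(aa[1])^2 + sin(aa[2])^2) + 1,
                   tolerance = 1e-10)
    }
  }

  # -sin pair: C1 = 1/(1+tau^2), g = cos/(1+tau^2): R is tau-invariant
  ds <- prc_double_sine(0, 0)
  dens <- lapply(c(0.1, 1, 10), function(tau) {
    pb <- build_problem(ds, ds, tau, c = 0.7)
    expect_equal(pb$C1, 1 / (1 + tau^2), tolerance = 1e-12)
    expect_equal(pb$g$values, cos(pb$g$grid) / (1 + tau^2), tolerance = 1e-12)
    solve_density(pb)$density
  })
  expect_equal(dens[[1]], dens[[2]], tolerance = 1e-10)
  expect_equal(dens[[2]], dens[[3]], tolerance = 1e-10)

  # K is forced by integrating the BVP over one period
  pb <- build_problem(pr$p1, pr$p2, tau = 1, c = 0.8, omega = 0.4)
  expect_equal(pb$K, (2 * 0.4 / 1 - pb$C2) / (2 * pi), tolerance = 1e-14)

  expect_error(build_problem(pr$p1, pr$p2, tau = -1, c = 0.5), "positive")
  expect_error(build_problem(pr$p1, pr$p2, tau = 1, c = 1.4), "\\[0, 1\\]")
})

test_that("the spectral solver reproduces known solutions", {
  pr <- ref_pair()
  # no correlated drive: uniform density
  d0 <- solve_density(build_problem(pr$p1, pr$p2, tau = 1, c = 0, omega = 0))
  expect_equal(d0$density, rep(1 / (2 * pi), nrow(d0)), tolerance = 1e-10)

  # identical PRCs, omega = 0: matches the closed form
  pb <- build_problem(pr$p1, pr$p1, tau = 1, c = 0.8)
  db <- solve_density(pb)
  dc <- closed_form_density(pr$p1, tau = 1, c = 0.8)
  expect_lt(max(abs(db$density - dc$density)), 1e-8)

  # degenerate transport at c = 1 for a homogeneous pair is refused
  pb1 <- build_problem(pr$p1, pr$p1, tau = 1, c = 1)
  expect_true(pb1$degenerate)
  expect_error(solve_density(pb1), "degenerate")
})

test_that("the white-noise limit recovers the unfiltered closed form", {
  pr <- ref_pair()
  tau <- 1e-4
  d <- solve_density(build_problem(pr$p1, pr$p2, tau, c = 0.6, omega = 0))
  h11 <- cross_correlation_h(pr$p1, pr$p1)
  h22 <- cross_correlation_h(pr$p2, pr$p2)
  h12 <- cross_correlation_h(pr$p1, pr$p2)
  denom <- h11$values[1] + h22$values[1] - 2 * 0.6 * h12$values
  R <- (1 / denom) / (sum(1 / denom) * 2 * pi / length(denom))
  phi <- wrap_pi(h12$grid)
  expect_lt(max(abs(d$density[order(d$phi)] - R[order(phi)])), 1e-3)
})

test_that("closed-form homogeneous density matches its analytic values", {
  p <- prc_double_sine(0, 0)
  d <- closed_form_density(p, tau = 2, c = 0.8)
  expect_equal(max(d$density), sqrt(1 - 0.8^2) / (2 * pi * (1 - 0.8)),
               tolerance = 1e-4)
  expect_equal(d$density, density_interp(d, -d$phi), tolerance = 1e-10)
  expect_equal(closed_form_op(p, 1, 0.8), 0.5, tolerance = 1e-9)
  expect_equal(closed_form_op(p, 1, 0), 0, tolerance = 1e-12)
  # c -> 1: order parameter increases to 1 (perfect synchrony)
  ops <- vapply(1 - 10^-(2:6), function(cc)
    closed_form_op(prc_double_sine(0.1, 0.32), 1, cc), numeric(1))
  expect_true(all(diff(ops) > 0))
  expect_gt(ops[5], 0.998)
  expect_error(closed_form_density(p, 1, 1), "delta")
})

test_that("small-c expansion reproduces the first-harmonic susceptibility law", {
  # slope * (1 + (tau^2+1)(sin^2 aj + sin^2 ak)) is the constant 1/2
  for (tau in c(0.25, 1, 4)) {
    for (aa in list(c(0.1, 0.1), c(0.1, 0.6), c(0.6, 0.6), c(0.2, 1.0))) {
      pb <- build_problem(prc_double_sine(aa[1], 0), prc_double_sine(aa[2], 0),
                          tau, c = 0.05)
      sl <- small_c_expansion(pb)
      expect_equal(sl$R0, 1 / (2 * pi))
      expect_equal(mean(sl$R1$values), 0, tolerance = 1e-12)
      denom <- 1 + (tau^2 + 1) * (sin(aa[1])^2 + sin(aa[2])^2)
      expect_equal(sl$op_linear_coefficient * denom, 0.5, tolerance = 1e-10)
    }
  }

  # linear prediction agrees with the full BVP at c = 0.05
  pr <- ref_pair()
  pb <- build_problem(pr$p1, pr$p2, tau = 1, c = 0.05)
  lin <- 0.05 * small_c_expansion(pb)$op_linear_coefficient
  full <- order_parameter(solve_density(pb))$OP
  expect_lt(abs(lin - full) / full, 0.05)
})

test_that("the noise-induced drift matches a Monte Carlo frequency-shift oracle", {
  # two PRCs with very different second-harmonic content give a measurable
  # noise-induced frequency-shift asymmetry
  pa <- prc_double_sine(0, 0.8)
  pb_ <- prc_double_sine(0, 0)
  tau <- 1
  nu_th <- function(p) { # shift of a single oscillator, simulation units
    co <- pf_coefs(cross_correlation_h(p, p))
    kk <- seq_along(co$a)
    tau * sum(-co$a * kk^2 * tau / (2 * (1 + kk^2 * tau^2)))
  }
  eps <- 0.3
  nu_mc <- function(p, seed) {
    tr <- simulate_phase_pair(p, p, eps = eps, omega = 0, tau = tau, c = 0,
                              dt = 0.01, T = 3e4, burn_in = 0, seed = seed)
    ((tail(tr$theta1, 1) - tr$theta1[1]) / (tail(tr$t, 1) - tr$t[1]) - 1) / eps^2
  }
  sh_a <- mean(vapply(1:4, function(s) nu_mc(pa, s), numeric(1)))
  sh_b <- mean(vapply(5:8, function(s) nu_mc(pb_, s), numeric(1)))
  expect_lt(abs(sh_a - nu_th(pa)) / abs(nu_th(pa)), 0.15)
  # the asymmetry maps onto C2 with the implemented sign convention:
  # C2 = 2*(nu1 - nu2)/tau in filter-normalized units
  prob <- build_problem(pa, pb_, tau, c = 0.5)
  expect_equal(prob$C2, 2 * (nu_th(pa) - nu_th(pb_)) / tau, tolerance = 1e-10)

  # peak-shift direction of the heterogeneous density agrees with Monte Carlo
  pr <- ref_pair()
  d_bvp <- solve_density(build_problem(pr$p1, pr$p2, 1, 0.8, 0))
  tr <- simulate_phase_pair(pr$p1, pr$p2, eps = 0.1, omega = 0, tau = 1,
                            c = 0.8, dt = 0.05, T = 2e5, seed = 11)
  pk_mc <- order_parameter(empirical_density(tr))$peak_angle
  pk_bvp <- order_parameter(d_bvp)$peak_angle
  expect_lt(pk_bvp, 0) # shifted left of the origin
  expect_lt(pk_mc, 0)
  expect_lt(abs(pk_mc - pk_bvp), 0.25)
})

test_that("order parameter is symmetric in the frequency difference", {
  # exact symmetry for first-harmonic pairs (C2 = 0, single-harmonic g)
  q1 <- prc_double_sine(0.1, 0)
  q2 <- prc_double_sine(0.6, 0)
  for (w in c(0.1, 0.5)) {
    opp <- order_parameter(solve_density(build_problem(q1, q2, 1, 0.8, w)))$OP
    opm <- order_parameter(solve_density(build_problem(q1, q2, 1, 0.8, -w)))$OP
    expect_equal(opp, opm, tolerance = 1e-9)
  }
  # near-symmetry for the general heterogeneous pair
  pr <- ref_pair()
  opp <- order_parameter(solve_density(build_problem(pr$p1, pr$p2, 1, 0.8, 0.3)))$OP
  opm <- order_parameter(solve_density(build_problem(pr$p1, pr$p2, 1, 0.8, -0.3)))$OP
  expect_lt(abs(opp - opm) / opp, 0.02)
})

test_that("BVP densities match Monte Carlo across noise amplitudes", {
  # the stationary density is, to leading order, independent of eps
  p <- prc_double_sine(0.5, 0.3)
  d_bvp <- solve_density(build_problem(p, p, tau = 0.25, c = 0.5, omega = 0.5))
  for (eps in c(0.1, 0.5)) {
    tr <- simulate_phase_pair(p, p, eps = eps, omega = 0.5, tau = 0.25,
                              c = 0.5, dt = 0.02, T = 1e5, seed = 21)
    d <- empirical_density(tr, 50, se_blocks = 40)
    expect_density_close(d, d_bvp, max_z = 3, frac_over = 0.04)
  }
})

test_that("densities and problems export to CSV", {
  pr <- ref_pair()
  prob <- build_problem(pr$p1, pr$p2, 1, 0.8)
  d <- solve_density(prob)
  f1 <- tempfile(fileext = ".csv")
  write_density_csv(d, f1)
  back <- utils::read.csv(f1)
  expect_equal(back$density, d$density)
  f2 <- tempfile(fileext = ".csv"); f3 <- tempfile(fileext = ".csv")
  write_problem_csv(prob, f2, f3)
  sc <- utils::read.csv(f3)
  expect_equal(sc$C1, prob$C1)
  expect_equal(sc$K, prob$K)
})
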