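#' Morris-Lecar parameter sets
#'
#' `ml_params()` returns the base parameter set used throughout:
#' `VK = -84`, `VL = -60`, `VCa = 120` mV, `gK = 8`, `gL = 2`, `gCa = 4`
#' mS/cm^2, `Cm = 20` uF/cm^2, `Va = -1.2`, `Vb = 18`, `Vc = 2`, `Vd = 30`
#' mV; the applied current `I` (uA/cm^2) and recovery rate scale `phi_w`
#' (1/ms) select the firing regime.
#'
#' `ml_hopf_params()` and `ml_snic_params()` are the two classic
#' excitability regimes of the model: onset of firing through a
#' (subcritical) Hopf bifurcation (`gCa = 4.4`, `phi_w = 0.04`) versus a
#' saddle-node on an invariant circle (`gCa = 4`, `Vc = 12`, `Vd = 17.4`,
#' `phi_w = 1/15`). With the default currents the two regimes fire with a
#' common period near 91.2 ms (the SNIC current is matched to the Hopf
#' period by [ml_match_frequency()]), giving a same-frequency pair whose
#' PRCs differ qualitatively: the Hopf PRC has a substantial negative
#' lobe, the SNIC PRC is predominantly non-negative.
#'
#' @param I applied current, uA/cm^2
#' @param phi_w recovery time scale, 1/ms
#' @param ... overrides for any of the named parameters
#' @return named numeric vector of class `ml_params`
#' @export
ml_params <- function(I = 120, phi_w = 0.04, ...) {
  p <- c(VK = -84, VL = -60, VCa = 120, gK = 8, gL = 2, gCa = 4, C = 20,
         Va = -1.2, Vb = 18, Vc = 2, Vd = 30, I = I, phi = phi_w)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown ML parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  if (any(p[c("gK", "gL", "gCa")] < 0)) stop("conductances must be >= 0")
  if (p["C"] <= 0) stop("membrane capacitance must be positive")
  structure(p, class = "ml_params")
}

#' @rdname ml_params
#' @export
ml_hopf_params <- function(I = 95) ml_params(I = I, phi_w = 0.04, gCa = 4.4)

#' @rdname ml_params
#' @export
ml_snic_params <- function(I = 46.17) {
  ml_params(I = I, phi_w = 1 / 15, Vc = 12, Vd = 17.4)
}

#' Simulate a Morris-Lecar pair under correlated OU drive
#'
#' Euler-Maruyama integration of two Morris-Lecar cells, cell 1 driven by
#' the current `sigma*x` and cell 2 by `sigma*y` where `(x, y)` is a
#' partially correlated OU pair with time constant `tau` (ms) and
#' correlation `c`. With `sigma = 0` this reduces to the deterministic
#' model.
#'
#' @param params1,params2 [ml_params()] vectors for the two cells
#' @param sigma noise amplitude, uA/cm^2
#' @param tau OU time constant, ms
#' @param c input correlation in `[0, 1]`
#' @param dt time step, ms (must be <= 0.05)
#' @param T total simulated time, ms
#' @param seed optional integer seed
#' @param record_dt recording interval, ms (default `dt`)
#' @param state0 initial `(V1, w1, V2, w2)`
#' @return tibble `t_ms, V1_mV, w1, V2_mV, w2, x, y`
#' @export
simulate_ml_pair <- function(params1, params2, sigma, tau, c,
                             dt = 0.01, T = 10000, seed = NULL,
                             record_dt = dt,
                             state0 = c(-26, 0.1, -26.5, 0.12)) {
  stopifnot(inherits(params1, "ml_params"), inherits(params2, "ml_params"))
  if (dt > 0.05) stop("dt must be <= 0.05 ms")
  if (c < 0 || c > 1) stop("c must lie in [0, 1]")
  if (tau <= 0) stop("tau must be positive")
  if (!is.null(seed)) set.seed(seed)
  nsteps <- floor(T / dt)
  every <- max(1L, as.integer(round(record_dt / dt)))
  m <- cpp_ml_pair(unclass(params1), unclass(params2), sigma, tau, c,
                   dt, nsteps, every, state0)
  out <- tibble::tibble(t_ms = m[, 1], V1_mV = m[, 2], w1 = m[, 3],
                        V2_mV = m[, 4], w2 = m[, 5], x = m[, 6], y = m[, 7])
  attr(out, "pars") <- list(sigma = sigma, tau = tau, c = c, dt = dt,
                            seed = seed)
  out
}

# Upward threshold crossings of a sampled voltage trace, with linear
# interpolation of the crossing times.
voltage_crossings <- function(t, V, threshold = 0) {
  i <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  if (!length(i)) return(numeric(0))
  t[i] + (t[i + 1] - t[i]) * (threshold - V[i]) / (V[i + 1] - V[i])
}

#' Find the deterministic Morris-Lecar limit cycle
#'
#' Integrates the noise-free model past a transient, measures the period
#' from successive upward crossings of a voltage threshold, and resamples
#' one cycle (starting at a crossing, i.e. at the spike) onto a uniform
#' grid. Errors if the cell does not oscillate or the period has not
#' converged to within 0.1% between consecutive cycles.
#'
#' @param params an [ml_params()] vector
#' @param dt integration step, ms
#' @param transient discarded initial time, ms
#' @param threshold spike threshold, mV
#' @param n_grid number of uniform samples of the returned cycle
#' @return object of class `ml_cycle`: `period` (ms), vectors `t`, `V`,
#'   `w` over one period, and the parameters
#' @export
find_limit_cycle <- function(params, dt = 0.005, transient = 2000,
                             threshold = 0, n_grid = 1024) {
  stopifnot(inherits(params, "ml_params"))
  n1 <- as.integer(round(transient / dt))
  tr <- cpp_ml_det(unclass(params), c(-26, 0.1), dt, n1, n1)
  s <- c(tr[nrow(tr), 2], tr[nrow(tr), 3])
  # record ~6 further cycles densely
  n2 <- as.integer(round(900 / dt))
  tr <- cpp_ml_det(unclass(params), s, dt, n2, 1L)
  tc <- voltage_crossings(tr[, 1], tr[, 2], threshold)
  if (length(tc) < 3) stop("no oscillation: fewer than 3 threshold crossings")
  per <- diff(tc)
  if (max(abs(diff(per))) / mean(per) > 0.001)
    stop("not converged: period drift between consecutive cycles exceeds 0.1%")
  period <- mean(utils::tail(per, 3))
  t0 <- tc[length(tc) - 1]
  ts <- t0 + period * (seq_len(n_grid) - 1) / n_grid
  V <- stats::spline(tr[, 1], tr[, 2], xout = ts, method = "fmm")$y
  w <- stats::spline(tr[, 1], tr[, 3], xout = ts, method = "fmm")$y
  amp <- max(V) - min(V)
  Vend <- stats::spline(tr[, 1], tr[, 2], xout = t0 + period, method = "fmm")$y
  wend <- stats::spline(tr[, 1], tr[, 3], xout = t0 + period, method = "fmm")$y
  closure <- sqrt((Vend - V[1])^2 + (wend - w[1])^2) / amp
  structure(
    list(period = period, t = ts - t0, V = V, w = w, params = params,
         closure = closure, dt = dt, threshold = threshold),
    class = "ml_cycle")
}

#' @export
print.ml_cycle <- function(x, ...) {
  cat("<ml_cycle> period", signif(x$period, 6), "ms;",
      length(x$t), "samples; closure", signif(x$closure, 2), "\n")
  invisible(x)
}

# Jacobian of the ML vector field at (V, w).
ml_jacobian <- function(p, V, w) {
  sech2 <- function(u) 1 / cosh(u)^2
  minf <- 0.5 * (1 + tanh((V - p["Va"]) / p["Vb"]))
  dminf <- 0.5 * sech2((V - p["Va"]) / p["Vb"]) / p["Vb"]
  winf <- 0.5 * (1 + tanh((V - p["Vc"]) / p["Vd"]))
  dwinf <- 0.5 * sech2((V - p["Vc"]) / p["Vd"]) / p["Vd"]
  u <- (V - p["Vc"]) / (2 * p["Vd"])
  tw <- 1 / cosh(u)
  dtw <- -sinh(u) / cosh(u)^2 / (2 * p["Vd"])
  a11 <- (-p["gL"] - p["gK"] * w - p["gCa"] * (dminf * (V - p["VCa"]) + minf)) / p["C"]
  a12 <- -p["gK"] * (V - p["VK"]) / p["C"]
  a21 <- p["phi"] * (dwinf / tw - (winf - w) * dtw / tw^2)
  a22 <- -p["phi"] / tw
  matrix(c(a11, a12, a21, a22), 2, 2, byrow = TRUE,
         dimnames = NULL)
}

ml_field <- function(p, V, w) {
  minf <- 0.5 * (1 + tanh((V - p["Va"]) / p["Vb"]))
  winf <- 0.5 * (1 + tanh((V - p["Vc"]) / p["Vd"]))
  tw <- 1 / cosh((V - p["Vc"]) / (2 * p["Vd"]))
  c((p["I"] - p["gL"] * (V - p["VL"]) - p["gK"] * w * (V - p["VK"]) -
       p["gCa"] * minf * (V - p["VCa"])) / p["C"],
    p["phi"] * (winf - w) / tw)
}

#' Infinitesimal PRC of a Morris-Lecar cycle by the adjoint method
#'
#' Solves the adjoint (transposed-Jacobian) linear system
#' `Z' = -J(X0(t))' Z` backward in time along the limit cycle until
#' periodic (backward integration is contracting onto the unique periodic
#' adjoint solution), normalizes so that `Z(t) . F(X0(t))` equals the
#' constant phase speed `2*pi/T` at every point, and returns the voltage
#' component divided by the membrane capacitance. The returned tabulated
#' PRC `Delta(theta)` therefore measures the phase shift (radians) per
#' unit injected charge density (uA/cm^2 * ms): a brief current pulse of
#' amplitude `I_p` and duration `d` at phase `theta` advances the phase by
#' `Delta(theta) * I_p * d`.
#'
#' @param cycle an `ml_cycle` from [find_limit_cycle()]
#' @param params the matching [ml_params()] (defaults to the cycle's)
#' @param tol relative periodicity tolerance
#' @param max_periods maximum number of backward periods
#' @param steps_per_sample backward RK4 substeps per cycle sample
#' @return a tabulated `prc_spec` on the cycle's phase grid `[0, 2*pi)`
#' @export
adjoint_prc <- function(cycle, params = cycle$params, tol = 1e-6,
                        max_periods = 50, steps_per_sample = 4) {
  stopifnot(inherits(cycle, "ml_cycle"))
  n <- length(cycle$t)
  Tp <- cycle$period
  # periodic interpolants of the cycle
  tt <- c(cycle$t, Tp)
  Vf <- stats::splinefun(tt, c(cycle$V, cycle$V[1]), method = "periodic")
  wf <- stats::splinefun(tt, c(cycle$w, cycle$w[1]), method = "periodic")
  omega0 <- 2 * pi / Tp
  h <- Tp / (n * steps_per_sample)

  rhs <- function(tmod, Z) {
    # backward time: dZ/ds = J(X0(t))^T Z with t decreasing
    J <- ml_jacobian(params, Vf(tmod), wf(tmod))
    as.numeric(t(J) %*% Z)
  }
  F0 <- ml_field(params, cycle$V[1], cycle$w[1])
  Z <- F0 / sum(F0^2) * omega0
  Zstore <- matrix(NA_real_, n, 2)
  prev <- NULL
  for (it in seq_len(max_periods)) {
    tcur <- 0
    for (j in seq_len(n)) {
      # store Z at time (n - j + 1)-th grid point going backwards from t = 0
      Zstore[n - j + 1L, ] <- Z
      for (s in seq_len(steps_per_sample)) {
        k1 <- rhs(tcur %% Tp, Z)
        k2 <- rhs((tcur - h / 2) %% Tp, Z + h / 2 * k1)
        k3 <- rhs((tcur - h / 2) %% Tp, Z + h / 2 * k2)
        k4 <- rhs((tcur - h) %% Tp, Z + h * k3)
        Z <- Z + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        tcur <- tcur - h
      }
    }
    # rescale the (neutral) amplitude once per period
    Fh <- ml_field(params, Vf(tcur %% Tp), wf(tcur %% Tp))
    Z <- Z * omega0 / sum(Z * Fh)
    if (!is.null(prev)) {
      rel <- max(abs(Zstore - prev)) / max(abs(Zstore))
      if (rel < tol) break
      if (it == max_periods)
        stop("adjoint iteration did not reach periodicity after ",
             max_periods, " periods (rel. change ", signif(rel, 3), ")")
    }
    prev <- Zstore + 0
  }
  # enforce the normalization Z . F = 2*pi/T pointwise
  Fv <- vapply(seq_len(n), function(j)
    sum(Zstore[j, ] * ml_field(params, cycle$V[j], cycle$w[j])), numeric(1))
  Zv <- Zstore[, 1] * omega0 / Fv
  theta <- 2 * pi * (seq_len(n) - 1) / n
  prc <- prc_tabulated(theta, Zv / params[["C"]])
  attr(prc, "normalization_spread") <- diff(range(Fv)) / omega0
  prc
}

#' PRC by direct pulse perturbation
#'
#' Reference (finite-perturbation) PRC: applies a brief square current
#' pulse at a set of phases and measures the induced spike-time shift
#' several periods later. Serves as the independent oracle for
#' [adjoint_prc()].
#'
#' @param cycle an `ml_cycle`
#' @param params matching [ml_params()]
#' @param n_phases number of probe phases
#' @param amp pulse amplitude, uA/cm^2
#' @param dur pulse duration, ms
#' @param settle_periods periods to wait before reading the shift
#' @return tibble `theta`, `prc` (phase shift per unit charge density)
#' @export
pulse_prc <- function(cycle, params = cycle$params, n_phases = 32,
                      amp = 1, dur = 0.2, settle_periods = 6) {
  Tp <- cycle$period
  dt <- 0.002
  npulse <- as.integer(round(dur / dt))
  nafter <- as.integer(round(settle_periods * Tp / dt))
  thetas <- 2 * pi * (seq_len(n_phases) - 1) / n_phases
  pulsed <- params
  pulsed["I"] <- params[["I"]] + amp
  ref_cross <- cycle$threshold
  shift <- vapply(thetas, function(th) {
    j <- th / (2 * pi) * length(cycle$t)
    jlo <- floor(j) + 1
    frac <- j - (jlo - 1)
    jhi <- if (jlo == length(cycle$t)) 1L else jlo + 1L
    s0 <- c(cycle$V[jlo] * (1 - frac) + cycle$V[jhi] * frac,
            cycle$w[jlo] * (1 - frac) + cycle$w[jhi] * frac)
    trp <- cpp_ml_det(unclass(pulsed), s0, dt, npulse, npulse)
    s1 <- c(trp[nrow(trp), 2], trp[nrow(trp), 3])
    tr <- cpp_ml_det(unclass(params), s1, dt, nafter, 1L)
    tc <- voltage_crossings(tr[, 1], tr[, 2], ref_cross)
    tc <- tc[tc > (settle_periods - 2) * Tp]
    # elapsed time since the phase-theta start; compare with the
    # unperturbed spike times (1 - theta/2pi)*Tp + k*Tp
    elapsed <- dur + tc[1]
    t1 <- (1 - th / (2 * pi)) * Tp
    k <- round((elapsed - t1) / Tp)
    delta_t <- (t1 + k * Tp) - elapsed # advance > 0
    2 * pi * delta_t / Tp
  }, numeric(1))
  tibble::tibble(theta = thetas, prc = shift / (amp * dur))
}

#' Match the firing frequency of one ML cell to a target period
#'
#' Root-finds the applied current so the deterministic period equals
#' `target_period`; this is how same-frequency heterogeneous pairs are
#' constructed (e.g. a SNIC cell matched to a Hopf cell's period).
#'
#' @param params an [ml_params()] vector (its `I` entry is replaced)
#' @param target_period desired period, ms
#' @param I_range bracketing interval for the current
#' @return the matched [ml_params()]
#' @export
ml_match_frequency <- function(params, target_period, I_range) {
  f <- function(I) {
    p <- params; p["I"] <- I
    find_limit_cycle(p)$period - target_period
  }
  r <- stats::uniroot(f, I_range, tol = 1e-4)
  params["I"] <- r$root
  params
}

# Largest 5-smooth integer <= n (FFT-friendly length).
smooth_length <- function(n) {
  best <- 1
  p2 <- 1
  while (p2 <= n) {
    p23 <- p2
    while (p23 <= n) {
      p235 <- p23
      while (p235 <= n) {
        if (p235 > best) best <- p235
        p235 <- p235 * 5
      }
      p23 <- p23 * 3
    }
    p2 <- p2 * 2
  }
  best
}

# Analytic signal via the FFT construction: zero the negative
# frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert-transform phase mapped onto the noise-free cycle
#'
#' Computes the analytic-signal angle of a (mean-subtracted) voltage
#' trace and remaps it to a temporal phase through a monotone lookup
#' built on the noise-free limit cycle, so that the noise-free cycle's
#' phase advances uniformly in time. The raw Hilbert angle is not a
#' temporal phase (it compresses fast segments of the orbit); the remap
#' makes the phase distribution of the unperturbed cycle uniform, as the
#' stationary theory requires. Phase 0 is the spike (the cycle's upward
#' threshold crossing).
#'
#' To keep the FFT cost near `n log n` for any record length, the input
#' is truncated to the largest 5-smooth (factors 2, 3, 5 only) length not
#' exceeding it; at most a fraction of a percent of the tail is dropped.
#'
#' @param v voltage samples
#' @param cycle the reference `ml_cycle` for the same cell
#' @return numeric vector of phases in `[0, 2*pi)` (length possibly
#'   slightly below `length(v)`, see above)
#' @export
hilbert_phase <- function(v, cycle) {
  stopifnot(inherits(cycle, "ml_cycle"))
  v <- v[seq_len(smooth_length(length(v)))]
  n <- length(cycle$V)
  reps <- 8
  tiled <- rep(cycle$V - mean(cycle$V), reps)
  a <- analytic_signal(tiled)
  mid <- ((reps %/% 2) * n + 1):((reps %/% 2 + 1) * n)
  psi <- Arg(a[mid])
  psiu <- psi[1] + cumsum(c(0, wrap_pi(diff(psi))))
  if (any(diff(psiu) <= 0))
    stop("Hilbert phase is not monotone on the reference cycle; ",
         "reference not suitable")
  # lookup: analytic-signal angle -> elapsed-time fraction of the cycle
  frac <- (seq_len(n) - 1) / n
  psi0 <- psiu[1]
  map <- stats::approxfun(c(psiu, psi0 + 2 * pi), c(frac, 1))
  ang <- Arg(analytic_signal(v - mean(v)))
  key <- psi0 + (ang - psi0) %% (2 * pi)
  2 * pi * map(key)
}

#' Phase-difference density of a noisy Morris-Lecar pair
#'
#' End-to-end biophysical pipeline: simulate the correlated-noise driven
#' pair, reconstruct each cell's phase via [hilbert_phase()] against its
#' own noise-free cycle, and histogram the wrapped phase difference.
#'
#' @inheritParams simulate_ml_pair
#' @param transient time discarded before density accumulation, ms
#' @param n_bins histogram bins
#' @param record_dt sampling interval of the stored trace, ms
#' @return a [phase_density()] with provenance `"simulation"`
#' @export
ml_phase_difference_density <- function(params1, params2, sigma, tau, c,
                                        T = 200000, dt = 0.01,
                                        record_dt = 0.5, transient = 2000,
                                        n_bins = 100, seed = NULL) {
  cyc1 <- find_limit_cycle(params1)
  cyc2 <- find_limit_cycle(params2)
  tr <- simulate_ml_pair(params1, params2, sigma, tau, c, dt = dt, T = T,
                         seed = seed, record_dt = record_dt)
  keep <- tr$t_ms >= transient
  th1 <- hilbert_phase(tr$V1_mV[keep], cyc1)
  th2 <- hilbert_phase(tr$V2_mV[keep], cyc2)
  empirical_density(tibble::tibble(theta1 = th1, theta2 = th2), n_bins)
}

#' Phase-model inputs equivalent to a Morris-Lecar pair
#'
#' Converts a pair of ML cells plus noise settings into the matching
#' phase-reduction inputs: tabulated adjoint PRCs, the noise time
#' constant in phase-time units (`2*pi*tau/T`), and the effective noise
#' magnitude `eps = sigma * T/(2*pi)` that arises when time is rescaled
#' so the period is `2*pi` (both the biophysical and the phase simulator
#' drive with unit-power colored noise, so the amplitudes map directly). Frequency detuning between the cells
#' appears as `omega = (T1 - T2) * pi/(T1 * eps^2)` to leading order.
#'
#' @param cycle1,cycle2 `ml_cycle` objects for the two cells
#' @param tau_ms OU time constant in ms
#' @param sigma noise amplitude, uA/cm^2
#' @return list with `prc1`, `prc2`, `tau`, `eps`, `omega`
#' @export
ml_phase_model <- function(cycle1, cycle2, tau_ms, sigma) {
  T1 <- cycle1$period; T2 <- cycle2$period
  Tbar <- (T1 + T2) / 2
  eps <- sigma * Tbar / (2 * pi)
  omega <- if (abs(T1 - T2) / Tbar < 1e-9) 0 else
    (2 * pi / T2 - 2 * pi / T1) * (Tbar / (2 * pi)) / eps^2
  list(prc1 = adjoint_prc(cycle1),
       prc2 = adjoint_prc(cycle2),
       tau = 2 * pi * tau_ms / Tbar,
       eps = eps,
       omega = omega)
}

#' Write an ML trace as CSV
#'
#' Columns `t_ms,V1_mV,w1,V2_mV,w2`.
#'
#' @param trace output of [simulate_ml_pair()]
#' @param path file path
#' @export
write_ml_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("t_ms", "V1_mV", "w1", "V2_mV", "w2")],
                   path, row.names = FALSE)
  invisible(path)
}
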