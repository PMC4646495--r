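#' Oscillator state
#'
#' Instantaneous state of the virtual teacher's limb: time, position and
#' velocity. Positions are in normalized arbitrary units (a.u.), velocities
#' in a.u./s.
#'
#' @param t Time in seconds.
#' @param x Position (a.u.).
#' @param dx Velocity (a.u./s).
#' @return An object of class `oscillator_state`.
#' @export
oscillator_state <- function(t = 0, x = 1, dx = 0) {
  if (!all(is.finite(c(t, x, dx)))) {
    stop("oscillator state is corrupted: non-finite t, x or dx", call. = FALSE)
  }
  structure(list(t = t, x = x, dx = dx), class = "oscillator_state")
}

#' Partner observation
#'
#' One sample of the partner's movement as seen by the virtual teacher:
#' position and velocity.
#'
#' @param y Partner position (a.u.).
#' @param dy Partner velocity (a.u./s).
#' @return An object of class `human_observation`.
#' @export
human_observation <- function(y = 0, dy = 0) {
  if (!all(is.finite(c(y, dy)))) {
    stop("partner observation is corrupted: non-finite y or dy", call. = FALSE)
  }
  structure(list(y = y, dy = dy), class = "human_observation")
}

#' Virtual teacher parameters
#'
#' Parameters of the virtual teacher equation. The intrinsic part is a hybrid
#' Van der Pol-Rayleigh oscillator
#' \deqn{\ddot x + (\alpha \dot x^2 + \beta x^2 - \gamma)\dot x + \omega^2 x = F}
#' whose right-hand side F collects the HKB coupling
#' \eqn{[A + B(x-\mu y)^2](\dot x - \mu\dot y)} and the intentional
#' (Schoener-Kelso) forcing \eqn{C[(\dot x-\dot y)\cos\Psi + \omega y \sin\Psi]}.
#'
#' Defaults are the package calibration: a 1 Hz, unit-amplitude, near-sinusoidal
#' limit cycle (see [calibrate_vt()]), with HKB coefficients chosen so that, in
#' a dyad with the default surrogate partner, in-phase is strongly stable and
#' anti-phase loses stability (the empirical Memory-period collapse toward 0).
#'
#' @param alpha Rayleigh (cubic-velocity) damping coefficient (>= 0).
#' @param beta Van der Pol (position-squared) damping coefficient (>= 0).
#' @param gamma Negative linear damping: energy injection rate (> 0), 1/s.
#' @param omega Angular frequency (rad/s, > 0).
#' @param A HKB linear coupling coefficient.
#' @param B HKB nonlinear coupling coefficient.
#' @param mu Partner-to-VT amplitude scaling (> 0, dimensionless).
#' @return An object of class `vt_params`.
#' @export
vt_params <- function(alpha = 0.3464796, beta = 24.2359682, gamma = 18,
                      omega = 5.9139321, A = 2, B = -3.5, mu = 1) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma),
            is.finite(omega), is.finite(A), is.finite(B), is.finite(mu))
  if (alpha < 0 || beta < 0) {
    stop("alpha and beta must be non-negative", call. = FALSE)
  }
  if (gamma <= 0 || omega <= 0) {
    stop("gamma and omega must be positive for a self-sustained limit cycle",
         call. = FALSE)
  }
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, omega = omega,
                 A = A, B = B, mu = mu), class = "vt_params")
}

#' Intentional coupling setting
#'
#' The Schoener-Kelso intentional term's strength C and target relative
#' phase Psi. Psi is given in degrees at every user interface and stored in
#' radians internally.
#'
#' @param C Coupling strength (1/s, signed; the experiments use negative C).
#' @param psi_deg Specified relative phase in degrees (any value; interpreted
#'   modulo 360).
#' @return An object of class `intentional_setting` with fields `C` and
#'   `psi` (radians).
#' @export
intentional_setting <- function(C = 0, psi_deg = 0) {
  stopifnot(is.finite(C), is.finite(psi_deg))
  structure(list(C = C, psi = psi_deg * pi / 180),
            class = "intentional_setting")
}

#' Intrinsic acceleration of the virtual teacher
#'
#' The uncoupled hybrid oscillator:
#' \eqn{\ddot x = -(\alpha\dot x^3 + \beta x^2\dot x - \gamma\dot x) - \omega^2 x}.
#' Zeroing `alpha` recovers a pure Van der Pol damping, zeroing `beta` a pure
#' Rayleigh damping.
#'
#' @param state An [oscillator_state()].
#' @param p A [vt_params()].
#' @return Acceleration (a.u./s^2).
#' @export
intrinsic_acceleration <- function(state, p) {
  x <- state$x; dx <- state$dx
  if (!all(is.finite(c(x, dx)))) {
    stop("oscillator state is corrupted: non-finite x or dx", call. = FALSE)
  }
  -(p$alpha * dx^3 + p$beta * x^2 * dx - p$gamma * dx) - p$omega^2 * x
}

#' HKB coupling force on the virtual teacher
#'
#' \eqn{[A + B(x - \mu y)^2](\dot x - \mu \dot y)}: the bidirectional-coupling
#' term that, in a symmetric dyad, gives rise to stable coordination at 0 and
#' 180 degrees relative phase. `mu` rescales both the partner's position and
#' velocity to the VT's dynamic range.
#'
#' @param state An [oscillator_state()].
#' @param obs A [human_observation()].
#' @param p A [vt_params()].
#' @return Force (a.u./s^2).
#' @export
hkb_coupling_force <- function(state, obs, p) {
  (p$A + p$B * (state$x - p$mu * obs$y)^2) * (state$dx - p$mu * obs$dy)
}

#' Intentional (Schoener-Kelso) force on the virtual teacher
#'
#' \eqn{C[(\dot x - \dot y)\cos\Psi + \omega y \sin\Psi]}: steers the
#' co-produced relative phase toward the specified Psi; the attraction
#' strengthens with |C| (negative C in the experimental range).
#'
#' @param state An [oscillator_state()].
#' @param obs A [human_observation()].
#' @param p A [vt_params()].
#' @param s An [intentional_setting()].
#' @return Force (a.u./s^2).
#' @export
intentional_force <- function(state, obs, p, s) {
  s$C * ((state$dx - obs$dy) * cos(s$psi) + p$omega * obs$y * sin(s$psi))
}

#' Full virtual teacher derivative
#'
#' The sum of the intrinsic acceleration, the HKB coupling force and the
#' intentional force, paired with the velocity, giving the first-order system
#' integrated by [rk4_step()].
#'
#' @inheritParams intentional_force
#' @return A list with `dx` (velocity) and `ddx` (acceleration).
#' @export
vt_derivative <- function(state, obs, p, s) {
  ddx <- intrinsic_acceleration(state, p) +
    hkb_coupling_force(state, obs, p) +
    intentional_force(state, obs, p, s)
  list(dx = state$dx, ddx = ddx)
}

#' One classical RK4 step of the virtual teacher
#'
#' Advances (x, dx) by one fixed step of the classical 4th-order Runge-Kutta
#' scheme, holding the partner observation constant within the step
#' (zero-order hold: the partner is sampled at the loop rate, so interpolating
#' within sub-steps would invent data).
#'
#' @inheritParams intentional_force
#' @param dt Step size in seconds (> 0; the experiments integrate at 500 Hz,
#'   dt = 1/500).
#' @return The updated [oscillator_state()] with `t` advanced by `dt`.
#' @export
rk4_step <- function(state, obs, p, s, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  f <- function(x, dx) {
    st <- list(t = state$t, x = x, dx = dx)
    intrinsic_acceleration(st, p) +
      hkb_coupling_force(st, obs, p) +
      intentional_force(st, obs, p, s)
  }
  x <- state$x; v <- state$dx
  k1x <- v;                 k1v <- f(x, v)
  k2x <- v + dt / 2 * k1v;  k2v <- f(x + dt / 2 * k1x, v + dt / 2 * k1v)
  k3x <- v + dt / 2 * k2v;  k3v <- f(x + dt / 2 * k2x, v + dt / 2 * k2v)
  k4x <- v + dt * k3v;      k4v <- f(x + dt * k3x, v + dt * k3v)
  xn <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
  vn <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  if (!is.finite(xn) || !is.finite(vn)) {
    stop(sprintf("integration failure at t = %.6f s: non-finite state",
                 state$t), call. = FALSE)
  }
  oscillator_state(t = state$t + dt, x = xn, dx = vn)
}

#' Calibrate the virtual teacher's intrinsic oscillator
#'
#' Finds (alpha, beta, gamma) giving a limit cycle with the requested
#' frequency and unit amplitude. First-order averaging of the hybrid
#' oscillator gives the amplitude flow
#' \eqn{\dot r = r(4\gamma - 3\alpha\omega^2 r^2 - \beta r^2)/8}, so unit
#' amplitude requires \eqn{4\gamma = 3\alpha\omega^2 + \beta}; `vdp_share`
#' splits the saturating term between the Van der Pol (`beta`) and Rayleigh
#' (`alpha`) channels. The analytic point is then refined against a simulated
#' cycle: `omega` is adjusted so the measured period matches `1/omega_hz`, and
#' the saturation split is kept as requested. The mixed form is used because
#' the two damping channels distort the waveform in opposite directions,
#' keeping harmonic distortion low even at stiff `gamma`.
#'
#' @param omega_hz Target frequency in Hz.
#' @param gamma Energy-injection rate (1/s); also the amplitude relaxation
#'   rate, so larger values resist amplitude perturbation by strong coupling.
#' @param vdp_share Fraction of amplitude saturation carried by the Van der
#'   Pol term (0..1).
#' @param A,B,mu Coupling coefficients copied into the returned parameters.
#' @param refine Number of secant refinement passes on omega (0 = analytic
#'   point only).
#' @return A [vt_params()] whose free-running limit cycle has period
#'   `1/omega_hz` and amplitude 1 to within a fraction of a percent.
#' @export
calibrate_vt <- function(omega_hz = 1, gamma = 18, vdp_share = 0.4,
                         A = 2, B = -3.5, mu = 1, refine = 3) {
  omega <- 2 * pi * omega_hz
  ksc <- 1
  make <- function(om, ks) {
    beta <- ks * vdp_share * 4 * gamma
    alpha <- ks * (1 - vdp_share) * 4 * gamma / (3 * om^2)
    vt_params(alpha = alpha, beta = beta, gamma = gamma, omega = om,
              A = A, B = B, mu = mu)
  }
  p <- make(omega, ksc)
  if (refine > 0) {
    for (i in seq_len(refine)) {
      m <- measure_limit_cycle(p)
      # period scales ~ 1/omega; amplitude^2 ~ 1/saturation scale
      omega <- omega * m$period * omega_hz
      ksc <- ksc * m$amplitude^2
      p <- make(omega, ksc)
    }
  }
  p
}

#' Measure the free-running limit cycle
#'
#' Simulates the uncoupled oscillator from a given initial condition,
#' discards a transient, and measures the steady period (from upward
#' zero crossings of position, sub-sample interpolated) and peak amplitude.
#'
#' @param p A [vt_params()].
#' @param x0,dx0 Initial condition.
#' @param t_transient Seconds discarded before measuring.
#' @param t_measure Seconds measured.
#' @param fs Sampling/integration rate in Hz.
#' @return A list with `period` (s), `amplitude` (a.u.) and `thd` (total
#'   harmonic distortion of the position waveform, as a fraction).
#' @export
measure_limit_cycle <- function(p, x0 = 1, dx0 = 0, t_transient = 10,
                                t_measure = 10, fs = 500) {
  n <- round((t_transient + t_measure) * fs)
  tr <- simulate_vt_free(p, x0 = x0, dx0 = dx0, n = n, dt = 1 / fs)
  keep <- tr$t >= t_transient
  x <- tr$x[keep]
  tt <- tr$t[keep]
  # upward zero crossings with linear interpolation
  s <- sign(x)
  idx <- which(s[-length(s)] < 0 & s[-1] >= 0)
  if (length(idx) < 3) stop("no sustained oscillation detected", call. = FALSE)
  tc <- tt[idx] - x[idx] * (tt[idx + 1] - tt[idx]) / (x[idx + 1] - x[idx])
  period <- mean(diff(tc))
  amplitude <- max(abs(x))
  # harmonic distortion from the FFT over an integer number of cycles
  ncyc <- floor((tt[length(tt)] - tc[1]) / period)
  seg <- x[tt >= tc[1] & tt < tc[1] + ncyc * period]
  sp <- Mod(stats::fft(seg))[seq_len(floor(length(seg) / 2))]
  fund <- which.max(sp)
  harm <- sp[pmin(length(sp), (fund - 1) * (2:5) + 1)]
  thd <- sqrt(sum(harm^2)) / sp[fund]
  list(period = period, amplitude = amplitude, thd = thd)
}

# Free-running VT trajectory (no coupling), R reference implementation.
simulate_vt_free <- function(p, x0 = 1, dx0 = 0, n = 5000, dt = 1 / 500) {
  obs <- human_observation(0, 0)
  s <- intentional_setting(0, 0)
  sched <- data.frame(C = numeric(n), A = numeric(n), B = numeric(n),
                      psi = numeric(n))
  out <- dyad_loop_interface(
    n = n, dt = dt, p = p, sched = sched,
    partner_kind = "scripted", partner = list(y = numeric(n), dy = numeric(n)),
    x0 = x0, dx0 = dx0, delay_ticks = 1L, seed_state = FALSE)
  data.frame(t = (seq_len(n) - 1) * dt, x = out$x, dx = out$dx)
}
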