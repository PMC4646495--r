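#' Surrogate learner parameters
#'
#' Parameters of the synthetic partner standing in for the human learner. Its
#' coordination tendencies live at the relative-phase level: the flow
#' \deqn{\dot\varphi = -a\sin\varphi - 2b\sin 2\varphi + c\sin(\psi - \varphi)}
#' has, for `c = 0` and `b > a/4`, a strongly stable fixed point at 0
#' (in-phase) and a more weakly stable one at pi (anti-phase) -- the
#' spontaneous repertoire observed before any learning. The negative-sign
#' form is the canonical HKB phase flow; it is adopted so that 0 is stable
#' for positive `a`, `b`.
#'
#' `c` and `psi_intent` implement the learner's own intention (zero for a
#' naive learner; scheduled upward across practice blocks to emulate
#' learning). `sigma` is the phase-noise intensity, `delay_s` the perceptual
#' delay with which the learner sees the VT, `amplitude` and `omega_h` the
#' movement amplitude and preferred frequency (1 Hz by default).
#'
#' Defaults are a package calibration chosen so that the surrogate alone is
#' reliably bistable at the stated noise level while a scanning dyad can
#' still be steered to any phase (see the methods vignette).
#'
#' @param a First-harmonic coefficient (1/s, > 0).
#' @param b Second-harmonic coefficient (1/s; anti-phase is stable iff
#'   `b > a/4`).
#' @param c Intentional strength (1/s, >= 0).
#' @param psi_intent_deg Intended relative phase, degrees.
#' @param sigma Phase-noise intensity (rad/sqrt(s), >= 0).
#' @param delay_s Perceptual delay (s, >= 0).
#' @param amplitude Movement amplitude (a.u., > 0).
#' @param omega_h Preferred angular frequency (rad/s).
#' @return An object of class `surrogate_params`.
#' @export
surrogate_params <- function(a = 0.5, b = 0.35, c = 0, psi_intent_deg = 0,
                             sigma = 0.08, delay_s = 0.05, amplitude = 1,
                             omega_h = 2 * pi) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), is.finite(sigma),
            is.finite(delay_s), is.finite(amplitude), is.finite(omega_h))
  if (a <= 0) stop("a must be positive (in-phase must be stable)",
                   call. = FALSE)
  if (sigma < 0 || delay_s < 0) {
    stop("sigma and delay_s must be non-negative", call. = FALSE)
  }
  if (amplitude <= 0 || omega_h <= 0) {
    stop("amplitude and omega_h must be positive", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, psi_intent = psi_intent_deg * pi / 180,
                 sigma = sigma, delay_s = delay_s, amplitude = amplitude,
                 omega_h = omega_h),
            class = "surrogate_params")
}

#' Relative-phase flow of the surrogate learner
#'
#' \eqn{\dot\varphi = -a\sin\varphi - 2b\sin 2\varphi + c\sin(\psi - \varphi)}.
#'
#' @param phi Relative phase (radians; vectorized).
#' @param p A [surrogate_params()].
#' @return d(phi)/dt in rad/s.
#' @export
rp_flow <- function(phi, p) {
  -p$a * sin(phi) - 2 * p$b * sin(2 * phi) + p$c * sin(p$psi_intent - phi)
}

#' Fixed points of the surrogate's relative-phase flow
#'
#' Finds all roots of [rp_flow()] on (-pi, pi] by dense sign-change
#' bracketing followed by bisection ([stats::uniroot()]), and classifies each
#' by the sign of the flow's derivative (negative = stable attractor,
#' positive = repellor). A continuous periodic flow has an even number of
#' transversal roots, so the list is never empty for valid parameters.
#'
#' @param p A [surrogate_params()].
#' @param n_grid Number of bracketing grid points on the circle.
#' @return A data.frame with columns `phi` (radians in (-pi, pi]),
#'   `phi_deg`, and `stable` (logical).
#' @export
fixed_points <- function(p, n_grid = 2048) {
  h <- 2 * pi / n_grid
  grid <- -pi + (seq_len(n_grid) - 1) * h
  f <- rp_flow(grid, p)
  # close the circle: the interval (pi - h, pi] wraps onto (-pi, ...]
  f_next <- c(f[-1], f[1])
  roots <- numeric(0)
  for (i in seq_len(n_grid)) {
    if (f[i] == 0) {
      roots <- c(roots, grid[i])
    } else if (f[i] * f_next[i] < 0) {
      fu <- rp_flow(grid[i] + h, p)
      r <- if (f[i] * fu < 0) {
        stats::uniroot(function(x) rp_flow(x, p), c(grid[i], grid[i] + h),
                       tol = 1e-12)$root
      } else {
        # crossing sits at the interval end within floating noise (e.g. a
        # root exactly at the +/-pi seam)
        grid[i] + h
      }
      roots <- c(roots, r)
    }
  }
  roots <- sort(unique(round(wrap_angle(roots), 10)))
  eps <- 1e-6
  dflow <- (rp_flow(roots + eps, p) - rp_flow(roots - eps, p)) / (2 * eps)
  data.frame(phi = roots, phi_deg = roots * 180 / pi, stable = dflow < 0)
}

#' Integrate the surrogate's phase dynamics alone
#'
#' Euler-Maruyama integration of [rp_flow()] plus phase noise, without any
#' virtual teacher in the loop -- the surrogate's relative phase relaxing
#' under its intrinsic dynamics. Vectorized over initial conditions so that
#' basin and switching statistics over many seeds are cheap.
#'
#' @param p A [surrogate_params()].
#' @param phi0 Vector of initial phases (radians).
#' @param duration Seconds to integrate.
#' @param dt Step (s).
#' @param seed Optional integer seed.
#' @return A matrix with one row per time step (including t = 0) and one
#'   column per initial condition, wrapped to (-pi, pi].
#' @export
simulate_rp_flow <- function(p, phi0, duration = 20, dt = 1 / 500,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  m <- length(phi0)
  out <- matrix(0, nrow = n + 1, ncol = m)
  out[1, ] <- phi0
  phi <- phi0
  sq <- p$sigma * sqrt(dt)
  for (i in seq_len(n)) {
    phi <- phi + rp_flow(phi, p) * dt + sq * stats::rnorm(m)
    out[i + 1, ] <- phi
  }
  wrap_angle(out)
}
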