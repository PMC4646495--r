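#' Surrogate partner model
#'
#' Wraps a [surrogate_params()] set as a partner usable by [simulate_dyad()].
#' The surrogate integrates its own movement phase `theta_y` at its preferred
#' frequency, adjusted each tick by the HKB relative-phase flow [rp_flow()]
#' evaluated on its estimate of the current relative phase, plus phase noise
#' (Euler-Maruyama). The estimate uses the VT signal seen through the
#' surrogate's perceptual delay; the known delay is compensated by phase
#' extrapolation at the preferred frequency, emulating the predictive timing
#' of trained rhythmic movement. The readout is `y = amplitude * cos(theta_y)`
#' with `dy` its analytic derivative (noise enters the phase only).
#'
#' During periods where the partner cannot see the VT (Pacing), the
#' relative-phase adjustment is switched off and the surrogate free-runs at
#' its preferred frequency.
#'
#' @param params A [surrogate_params()].
#' @return A `partner_model` object.
#' @export
surrogate_partner <- function(params = surrogate_params()) {
  stopifnot(inherits(params, "surrogate_params"))
  structure(list(kind = "surrogate", params = params), class = "partner_model")
}

#' Scripted partner model
#'
#' Replays a recorded or constructed position trace as the partner. If the
#' trace has no velocity column, velocity is computed by 3-point
#' differentiation (central differences, one-sided at the ends).
#'
#' @param trace A data.frame with columns `t`, `y` and optionally `dy`, or a
#'   numeric vector of positions.
#' @param fs Sampling rate of the trace in Hz; must equal the simulation
#'   loop rate.
#' @return A `partner_model` object.
#' @export
scripted_partner <- function(trace, fs = 500) {
  if (is.numeric(trace)) trace <- data.frame(y = trace)
  stopifnot(is.data.frame(trace), "y" %in% names(trace))
  if (!is.null(trace$t) && nrow(trace) > 1) {
    dt_obs <- stats::median(diff(trace$t))
    if (abs(dt_obs - 1 / fs) > 1e-9) {
      stop(sprintf("trace sampled at %.6g Hz but loop runs at %g Hz",
                   1 / dt_obs, fs), call. = FALSE)
    }
  }
  y <- trace$y
  dy <- trace$dy
  if (is.null(dy)) dy <- diff3pt(y, 1 / fs)
  structure(list(kind = "scripted", y = y, dy = dy, fs = fs),
            class = "partner_model")
}

#' Limb-level partner model
#'
#' An alternative partner for robustness checks: a second hybrid oscillator
#' (same form as the VT's intrinsic dynamics) coupled to the VT through its
#' own HKB term \eqn{[A_h + B_h (y - x)^2](\dot y - \dot x)}. Unlike the
#' phase-level surrogate it has no ground-truth phase and no intention.
#'
#' @param params A [vt_params()] giving the partner's intrinsic oscillator
#'   (its `A`, `B`, `mu` fields are ignored).
#' @param A_h,B_h HKB coupling coefficients of the partner toward the VT.
#' @return A `partner_model` object.
#' @export
limb_partner <- function(params = vt_params(), A_h = -1, B_h = 0.2) {
  stopifnot(inherits(params, "vt_params"))
  structure(list(kind = "limb", params = params, A_h = A_h, B_h = B_h),
            class = "partner_model")
}

# 3-point numerical differentiation (central; one-sided at the ends).
diff3pt <- function(y, dt) {
  n <- length(y)
  if (n < 3) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}

# Expand a coupling schedule into per-tick parameter vectors.
expand_schedule <- function(schedule, fs) {
  validate_schedule(schedule)
  nper <- round(schedule$duration * fs)
  list(
    n = sum(nper),
    C = rep(schedule$C, nper),
    A = rep(schedule$A, nper),
    B = rep(schedule$B, nper),
    psi = rep(schedule$psi_deg * pi / 180, nper),
    visible = rep(!schedule$pacing, nper),
    label = rep(as.character(schedule$label), nper)
  )
}

validate_schedule <- function(schedule) {
  need <- c("label", "duration", "C", "A", "B", "psi_deg", "pacing")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule))) {
    stop("schedule must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(schedule$duration)) || any(schedule$duration <= 0)) {
    stop("schedule periods must have positive duration (no gaps or overlaps)",
         call. = FALSE)
  }
  invisible(schedule)
}

#' Simulate a closed-loop virtual-teacher trial
#'
#' Runs the bidirectionally coupled VT-partner loop at the stated rate
#' (default 500 Hz): each tick the VT is advanced one RK4 step against the
#' partner's last emitted sample, and the partner consumes the VT's delayed
#' output and emits its next sample. Both directions pass through a loop
#' delay of `delay_ticks` samples (default 1 tick = 2 ms, the maximum
#' acquisition-to-output delay of the reference apparatus).
#'
#' @param schedule A coupling schedule from [make_scanning_trial()] or
#'   [make_learning_trial()] (or any data.frame with the same columns).
#' @param partner A `partner_model` from [surrogate_partner()],
#'   [scripted_partner()] or [limb_partner()].
#' @param p VT parameters, a [vt_params()].
#' @param seed Integer seed; identical seeds give identical trials.
#' @param fs Loop rate in Hz.
#' @param delay_ticks Integer loop delay in ticks (>= 1).
#' @param x0,dx0 VT initial condition (default: peak flexion, rest velocity,
#'   i.e. the VT beats with the pacing metronome).
#' @param theta0 Initial partner phase in radians, or `NULL` (default) to
#'   draw it as metronome-synchronized with human-like timing jitter
#'   (N(0, 0.25 rad), about a 40 ms tap-timing error at 1 Hz): both partners
#'   produce peak flexion on the pacing beat, so trials begin near in-phase
#'   as the protocol instructs. Pass an explicit value to start elsewhere.
#' @param engine `"cpp"` (compiled loop) or `"r"` (reference implementation;
#'   identical semantics and RNG stream, used for cross-validation).
#' @return A `trial_record`: a data.frame with columns `t`, `x_vt`,
#'   `y_partner`, `C`, `A`, `B`, `psi_deg`, `period_label`, `reward` plus
#'   in-memory auxiliary columns `dx_vt`, `dy_partner` and (surrogate only)
#'   `phi` (ground-truth partner-minus-VT phase, radians). The schedule,
#'   seed, sampling rate and parameters are carried as attributes.
#' @export
simulate_dyad <- function(schedule, partner, p = vt_params(), seed = 1,
                          fs = 500, delay_ticks = 1, x0 = 1, dx0 = 0,
                          theta0 = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(partner, "partner_model"), inherits(p, "vt_params"))
  if (delay_ticks < 1) stop("delay_ticks must be >= 1", call. = FALSE)
  ex <- expand_schedule(schedule, fs)
  if (partner$kind == "scripted" && length(partner$y) < ex$n) {
    stop(sprintf("scripted trace has %d samples but the trial needs %d",
                 length(partner$y), ex$n), call. = FALSE)
  }
  set.seed(seed)
  if (is.null(theta0)) theta0 <- stats::rnorm(1, 0, 0.25)
  sched <- list(C = ex$C, A = ex$A, B = ex$B, psi = ex$psi,
                visible = ex$visible)
  out <- if (engine == "cpp") {
    .dyad_loop_cpp(ex$n, 1 / fs, unclass(p), ex$C, ex$A, ex$B, ex$psi,
                   ex$visible, partner$kind, unclass(partner), x0, dx0,
                   as.integer(delay_ticks), theta0)
  } else {
    dyad_loop_r(ex$n, 1 / fs, p, sched, partner, x0, dx0,
                as.integer(delay_ticks), theta0)
  }
  trial <- data.frame(
    t = (seq_len(ex$n) - 1) / fs,
    x_vt = out$x, y_partner = out$y,
    C = ex$C, A = ex$A, B = ex$B, psi_deg = ex$psi * 180 / pi,
    period_label = ex$label, reward = 0L,
    dx_vt = out$dx, dy_partner = out$dy, phi = out$phi,
    stringsAsFactors = FALSE
  )
  structure(trial, class = c("trial_record", "data.frame"),
            schedule = schedule, seed = seed, fs = fs, vt_params = p,
            partner_kind = partner$kind,
            partner_params = if (partner$kind == "surrogate") partner$params)
}

# Internal entry point shared by calibration helpers.
dyad_loop_interface <- function(n, dt, p, sched, partner_kind, partner,
                                x0, dx0, delay_ticks, seed_state = TRUE) {
  .dyad_loop_cpp(n, dt, unclass(p), sched$C, sched$A, sched$B, sched$psi,
                 rep(TRUE, n), partner_kind, partner, x0, dx0, delay_ticks,
                 0)
}

# Pure-R reference engine with semantics identical to the compiled loop.
dyad_loop_r <- function(n, dt, p, sched, partner, x0, dx0, delay_ticks,
                        theta0) {
  X <- numeric(n); DX <- numeric(n)
  Y <- numeric(n); DY <- numeric(n); PHI <- rep(NA_real_, n)
  X[1] <- x0; DX[1] <- dx0
  surrogate <- partner$kind == "surrogate"
  limb <- partner$kind == "limb"
  if (surrogate) {
    sp <- partner$params
    d_per <- round(sp$delay_s / dt)
    theta_y <- theta0
    Y[1] <- sp$amplitude * cos(theta_y)
    DY[1] <- -sp$amplitude * sp$omega_h * sin(theta_y)
  } else if (limb) {
    ph <- partner$params
    yy <- cos(theta0); ydy <- -ph$omega * sin(theta0)
    Y[1] <- yy; DY[1] <- ydy
  } else {
    Y <- partner$y[seq_len(n)]
    DY <- partner$dy[seq_len(n)]
  }
  sqdt <- sqrt(dt)
  for (i in 2:n) {
    j <- i - delay_ticks
    obs <- if (j >= 1) human_observation(Y[j], DY[j]) else
      human_observation(0, 0)
    p_tick <- p
    p_tick$A <- sched$A[i - 1]
    p_tick$B <- sched$B[i - 1]
    s_tick <- structure(list(C = sched$C[i - 1], psi = sched$psi[i - 1]),
                        class = "intentional_setting")
    st <- rk4_step(oscillator_state((i - 2) * dt, X[i - 1], DX[i - 1]), obs,
                   p_tick, s_tick, dt)
    X[i] <- st$x; DX[i] <- st$dx
    if (surrogate) {
      k <- i - delay_ticks - d_per
      drift <- sp$omega_h
      if (sched$visible[i - 1] && k >= 1) {
        th_x <- atan2(-DX[k] / sp$omega_h, X[k]) +
          sp$omega_h * (sp$delay_s + delay_ticks * dt)
        phih <- wrap_angle(theta_y - th_x)
        drift <- drift + rp_flow(phih, sp)
      }
      theta_y <- theta_y + drift * dt + sp$sigma * sqdt * stats::rnorm(1)
      Y[i] <- sp$amplitude * cos(theta_y)
      DY[i] <- -sp$amplitude * drift * sin(theta_y)
      PHI[i] <- wrap_angle(theta_y - atan2(-DX[i] / sp$omega_h, X[i]))
    } else if (limb) {
      k <- i - delay_ticks
      obs_x <- if (k >= 1) human_observation(X[k], DX[k]) else
        human_observation(0, 0)
      ph2 <- ph
      ph2$A <- if (sched$visible[i - 1]) partner$A_h else 0
      ph2$B <- if (sched$visible[i - 1]) partner$B_h else 0
      ph2$mu <- 1
      st2 <- rk4_step(oscillator_state((i - 2) * dt, yy, ydy), obs_x, ph2,
                      intentional_setting(0, 0), dt)
      yy <- st2$x; ydy <- st2$dx
      Y[i] <- yy; DY[i] <- ydy
    }
  }
  list(x = X, dx = DX, y = Y, dy = DY, phi = PHI)
}

# Wrap angles to (-pi, pi]; vectorized.
wrap_angle <- function(a) {
  a - 2 * pi * ceiling((a - pi) / (2 * pi))
}
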