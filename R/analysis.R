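#' Preprocess a movement time series
#'
#' The standard data-reduction chain applied to each position signal before
#' phase extraction, in order: mean-centering, linear least-squares
#' detrending (optional), zero-phase low-pass filtering (second-order
#' Butterworth applied forward and backward, cutoff 20 Hz), and cycle-by-
#' cycle amplitude normalization into \[-1, 1\]. Cycles are delimited by the
#' zero crossings of the filtered signal; each half-cycle is rescaled by its
#' own extremum, so slow amplitude drifts are removed while phase is
#' untouched.
#'
#' @param v Numeric vector, uniformly sampled.
#' @param fs Sampling rate (Hz).
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param detrend `"linear"` or `"none"`.
#' @param normalize Apply cycle-wise normalization (logical).
#' @return Numeric vector, same length as `v`.
#' @export
preprocess <- function(v, fs = 500, cutoff_hz = 20,
                       detrend = c("linear", "none"), normalize = TRUE) {
  detrend <- match.arg(detrend)
  if (length(v) < 2 * fs) stop("need at least 2 s of data", call. = FALSE)
  if (!all(is.finite(v))) stop("non-finite values in input", call. = FALSE)
  v <- v - mean(v)
  if (detrend == "linear") {
    tt <- seq_along(v)
    v <- stats::residuals(stats::lm.fit(cbind(1, tt), v))
  }
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  v <- as.numeric(signal::filtfilt(bf, v))
  if (normalize) v <- normalize_cycles(v)
  v
}

# Rescale each zero-crossing-delimited half-cycle by its own extremum.
normalize_cycles <- function(v) {
  s <- sign(v)
  s[s == 0] <- 1
  cross <- which(diff(s) != 0)
  if (length(cross) < 2) {
    stop("no detectable movement cycles: cannot normalize", call. = FALSE)
  }
  bounds <- c(0, cross, length(v))
  out <- v
  for (i in seq_len(length(bounds) - 1)) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    m <- max(abs(v[idx]))
    if (m > 0) out[idx] <- v[idx] / m
  }
  out
}

#' Analytic signal and instantaneous phase
#'
#' Constructs the analytic signal by the frequency-domain method (zeroing
#' negative frequencies of the FFT and doubling positive ones) and returns
#' the instantaneous phase.
#'
#' @param v Numeric vector (should be mean-centered).
#' @return Phase in radians, same length as `v` (not unwrapped).
#' @export
analytic_phase <- function(v) {
  n <- length(v)
  X <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  Arg(z)
}

#' Continuous Hilbert relative phase
#'
#' Relative phase between two preprocessed series via their analytic-signal
#' phases. The default convention is `rp = phase_VT - phase_partner`, so a
#' positive value means the partner lags the VT (a partner peaking a quarter
#' cycle after the VT gives +90 degrees); the opposite convention is
#' available via `convention`.
#'
#' @param x VT position series (preprocessed).
#' @param y Partner position series (preprocessed, same grid).
#' @param t Optional time vector (returned alongside).
#' @param convention `"vt_minus_partner"` (default) or `"partner_minus_vt"`.
#' @return A data.frame with columns `t` (if given) and `rp` in degrees
#'   wrapped to (-180, 180].
#' @export
continuous_rp <- function(x, y, t = NULL,
                          convention = c("vt_minus_partner",
                                         "partner_minus_vt")) {
  convention <- match.arg(convention)
  if (length(x) != length(y)) {
    stop("series lengths differ: ", length(x), " vs ", length(y),
         call. = FALSE)
  }
  px <- analytic_phase(x)
  py <- analytic_phase(y)
  rp <- if (convention == "vt_minus_partner") px - py else py - px
  rp <- wrap_angle(rp) * 180 / pi
  if (is.null(t)) data.frame(rp = rp) else data.frame(t = t, rp = rp)
}

#' Trim transients and segment a relative-phase series
#'
#' Drops the Pacing period and the final second of the trial (Hilbert edge
#' and end-of-trial transients), then splits the remainder into the
#' Exposition period, the first 5 s of Memory (M1: the transient shift after
#' the intentional coupling is removed) and the last 5 s (M2: potential
#' stabilization). A 6-20-11 s trial therefore yields 20, 5 and 5 s segments.
#'
#' @param rp A data.frame with columns `t` and `rp` covering the full trial.
#' @param schedule The trial's coupling schedule.
#' @param fs Sampling rate (Hz).
#' @return A named list of data.frames `Exposition`, `M1`, `M2`.
#' @export
trim_and_segment <- function(rp, schedule, fs = 500) {
  validate_schedule(schedule)
  lab <- as.character(schedule$label)
  t_pace <- sum(schedule$duration[schedule$pacing])
  d_expo <- sum(schedule$duration[lab == "Exposition"])
  d_mem <- sum(schedule$duration[lab == "Memory"])
  if (d_expo <= 0 || d_mem < 11) {
    stop("schedule must contain an Exposition and at least 11 s of Memory",
         call. = FALSE)
  }
  t0 <- t_pace
  t1 <- t_pace + d_expo                  # Memory onset
  t_end <- t1 + d_mem - 1                # final second trimmed
  if (max(rp$t) + 1 / fs < t_end - 1e-9) {
    stop("relative-phase series shorter than the schedule", call. = FALSE)
  }
  seg <- function(a, b) rp[rp$t >= a - 1e-9 & rp$t < b - 1e-9, , drop = FALSE]
  list(
    Exposition = seg(t0, t1),
    M1 = seg(t1, t1 + 5),
    M2 = seg(t_end - 5, t_end)
  )
}

#' Circular mean of angles in degrees
#'
#' The argument of the mean resultant vector.
#'
#' @param deg Angles in degrees.
#' @return Mean direction in degrees, in (-180, 180].
#' @export
circular_mean <- function(deg) {
  a <- deg * pi / 180
  wrap_angle(atan2(mean(sin(a)), mean(cos(a)))) * 180 / pi
}

#' Circular variance of angles in degrees
#'
#' One minus the mean resultant length: 0 for perfectly concentrated
#' samples, approaching 1 for angles uniform on the circle.
#'
#' @param deg Angles in degrees.
#' @return Circular variance in \[0, 1\].
#' @export
circular_variance <- function(deg) {
  a <- deg * pi / 180
  1 - sqrt(mean(sin(a))^2 + mean(cos(a))^2)
}

#' Constant error against a specified pattern
#'
#' Smallest wrapped angular distance between the produced relative phase and
#' the specified pattern *or its mirror image* (+Psi and -Psi describe the
#' same coordination up to which partner leads, so e.g. -90 produced against
#' a specified 90 counts as zero error).
#'
#' @param produced_deg Produced (mean) relative phase, degrees.
#' @param psi_deg Specified relative phase, degrees.
#' @param signed If `TRUE` return the signed deviation from the nearer
#'   image; otherwise its absolute value.
#' @return Error in degrees; signed values lie in \[-180, 180\], absolute
#'   values in \[0, 180\].
#' @export
constant_error <- function(produced_deg, psi_deg, signed = TRUE) {
  d1 <- wrap_angle((produced_deg - psi_deg) * pi / 180) * 180 / pi
  d2 <- wrap_angle((produced_deg + psi_deg) * pi / 180) * 180 / pi
  d <- ifelse(abs(d1) <= abs(d2), d1, d2)
  if (signed) d else abs(d)
}

#' Analyze one trial: relative phase and circular statistics by segment
#'
#' Runs the full data-reduction pipeline on a trial record: preprocessing of
#' both position series, continuous Hilbert relative phase (computed over
#' the whole record so no filter/Hilbert edge falls at a segment boundary),
#' trimming and segmentation, then circular mean, circular variance and
#' constant error per segment.
#'
#' @param trial A `trial_record` from [simulate_dyad()] or [read_trial()].
#' @param convention Relative-phase sign convention, see [continuous_rp()].
#' @return A data.frame with one row per segment: `segment`, `psi_deg`,
#'   `circ_mean`, `circ_var`, `ce`, `abs_ce`, `n`.
#' @export
analyze_trial <- function(trial, convention = "vt_minus_partner") {
  fs <- attr(trial, "fs") %||% 500
  schedule <- attr(trial, "schedule")
  if (is.null(schedule)) stop("trial carries no schedule", call. = FALSE)
  x <- preprocess(trial$x_vt, fs = fs)
  y <- preprocess(trial$y_partner, fs = fs)
  rp <- continuous_rp(x, y, t = trial$t, convention = convention)
  segs <- trim_and_segment(rp, schedule, fs = fs)
  psi <- schedule$psi_deg[as.character(schedule$label) == "Exposition"][1]
  out <- do.call(rbind, lapply(names(segs), function(nm) {
    m <- circular_mean(segs[[nm]]$rp)
    data.frame(segment = nm, psi_deg = psi, circ_mean = m,
               circ_var = circular_variance(segs[[nm]]$rp),
               ce = constant_error(m, psi, signed = TRUE),
               abs_ce = constant_error(m, psi, signed = FALSE),
               n = nrow(segs[[nm]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Analyze a list of trials into a tidy results table
#'
#' @param trials A list of `trial_record`s (e.g. from
#'   [run_scanning_session()]).
#' @param convention See [continuous_rp()].
#' @return A data.frame with one row per trial and segment, with a `trial`
#'   index column prepended.
#' @export
analyze_session <- function(trials, convention = "vt_minus_partner") {
  out <- lapply(seq_along(trials), function(i) {
    cbind(trial = i, analyze_trial(trials[[i]], convention = convention))
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
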