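#' Build one scanning trial schedule
#'
#' The attractor-scanning trial: 6 s Pacing (all couplings off, 1 Hz pacing
#' metronome, VT not visible), 20 s Exposition (intentional coupling C = -10
#' toward the specified phase, HKB coupling active), 11 s Memory (C = 0, HKB
#' coupling left active so the dyad relaxes toward its spontaneous
#' patterns).
#'
#' @param psi_deg Specified relative phase in degrees, in \[0, 180\].
#' @param p A [vt_params()] supplying the HKB coefficients used during
#'   Exposition and Memory.
#' @param C_expo Intentional coupling strength during Exposition.
#' @param fs Sampling rate (Hz), stored on the schedule.
#' @return A `coupling_schedule` data.frame (columns `label`, `duration`,
#'   `C`, `A`, `B`, `psi_deg`, `pacing`).
#' @export
make_scanning_trial <- function(psi_deg, p = vt_params(), C_expo = -10,
                                fs = 500) {
  if (!is.finite(psi_deg) || psi_deg < 0 || psi_deg > 180) {
    stop("psi_deg must lie in [0, 180]", call. = FALSE)
  }
  sched <- data.frame(
    label = c("Pacing", "Exposition", "Memory"),
    duration = c(6, 20, 11),
    C = c(0, C_expo, 0),
    A = c(0, p$A, p$A),
    B = c(0, p$B, p$B),
    psi_deg = c(0, psi_deg, 0),
    pacing = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  structure(sched, class = c("coupling_schedule", "data.frame"), fs = fs)
}

#' Build one learning trial schedule
#'
#' The reward-based learning trial: 6 s Pacing, 20 s Exposition with a
#' deliberately weakened intentional coupling (C = -3, avoiding an overly
#' passive learner) toward 90 degrees and the HKB coupling switched off
#' (A = B = 0), then 11 s Memory with *all* couplings off, so the VT
#' free-runs and any persistence of the pattern is the learner's own.
#'
#' @param psi_deg Specified phase (degrees; the learning experiment uses 90).
#' @param C_expo Intentional coupling during Exposition.
#' @param fs Sampling rate (Hz).
#' @return A `coupling_schedule`.
#' @export
make_learning_trial <- function(psi_deg = 90, C_expo = -3, fs = 500) {
  if (!is.finite(psi_deg) || psi_deg < 0 || psi_deg > 180) {
    stop("psi_deg must lie in [0, 180]", call. = FALSE)
  }
  sched <- data.frame(
    label = c("Pacing", "Exposition", "Memory"),
    duration = c(6, 20, 11),
    C = c(0, C_expo, 0),
    A = c(0, 0, 0),
    B = c(0, 0, 0),
    psi_deg = c(0, psi_deg, 0),
    pacing = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  structure(sched, class = c("coupling_schedule", "data.frame"), fs = fs)
}

#' Plan a scanning session
#'
#' Four scanning blocks, each presenting the thirteen phases 0, 15, ..., 180
#' degrees once, in an independent seeded random order per block.
#'
#' @param seed Integer seed.
#' @param n_blocks Number of scanning blocks.
#' @return A data.frame with columns `block`, `trial` (1..52) and `psi_deg`,
#'   plus a `trial_seed` column of per-trial integer seeds so each trial is
#'   reproducible on its own.
#' @export
make_scanning_session <- function(seed, n_blocks = 4) {
  psis <- seq(0, 180, by = 15)
  set.seed(seed)
  order <- unlist(lapply(seq_len(n_blocks), function(b) sample(psis)))
  n <- length(order)
  data.frame(
    block = rep(seq_len(n_blocks), each = length(psis)),
    trial = seq_len(n),
    psi_deg = order,
    trial_seed = sample.int(.Machine$integer.max %/% 2, n)
  )
}

#' Plan a learning session
#'
#' Five practice blocks of ten identical 90-degree learning trials. The
#' surrogate's practice-dependent change is emulated by scheduling its
#' intentional strength `c` upward across blocks, while its phase noise
#' `sigma` first rises (feedback-driven exploration once rewards start
#' arriving) and then falls as the pattern consolidates. The package does
#' not fit a learning law; the schedule is the study condition.
#'
#' @param seed Integer seed.
#' @param blocks Number of practice blocks.
#' @param trials_per_block Trials per block.
#' @param c_schedule Surrogate intentional strength per block (1/s).
#' @param sigma_schedule Surrogate phase noise per block (rad/sqrt(s)).
#' @return A data.frame with columns `block`, `trial`, `psi_deg`, `c`,
#'   `sigma`, `trial_seed`.
#' @export
make_learning_session <- function(seed, blocks = 5, trials_per_block = 10,
                                  c_schedule = c(0, 0.8, 1.3, 1.9, 2.8),
                                  sigma_schedule = c(0.40, 0.60, 0.50,
                                                     0.30, 0.12)) {
  if (blocks != 5) {
    if (missing(c_schedule)) c_schedule <- seq(0, 2.8, length.out = blocks)
    if (missing(sigma_schedule)) {
      sigma_schedule <- seq(0.5, 0.12, length.out = blocks)
    }
  }
  stopifnot(length(c_schedule) == blocks, length(sigma_schedule) == blocks)
  set.seed(seed)
  n <- blocks * trials_per_block
  data.frame(
    block = rep(seq_len(blocks), each = trials_per_block),
    trial = seq_len(n),
    psi_deg = 90,
    c = rep(c_schedule, each = trials_per_block),
    sigma = rep(sigma_schedule, each = trials_per_block),
    trial_seed = sample.int(.Machine$integer.max %/% 2, n)
  )
}

#' Run a full scanning session
#'
#' Simulates every trial of a [make_scanning_session()] plan against the
#' surrogate learner.
#'
#' @param seed Integer session seed.
#' @param p VT parameters.
#' @param sp Surrogate parameters.
#' @param n_blocks Number of scanning blocks.
#' @param fs Loop rate (Hz).
#' @return A list of `trial_record`s with the session plan attached as
#'   attribute `plan`.
#' @export
run_scanning_session <- function(seed, p = vt_params(),
                                 sp = surrogate_params(), n_blocks = 4,
                                 fs = 500) {
  plan <- make_scanning_session(seed, n_blocks = n_blocks)
  trials <- lapply(seq_len(nrow(plan)), function(k) {
    sched <- make_scanning_trial(plan$psi_deg[k], p = p, fs = fs)
    simulate_dyad(sched, surrogate_partner(sp), p = p,
                  seed = plan$trial_seed[k], fs = fs)
  })
  structure(trials, plan = plan, seed = seed)
}

#' Run a full learning session
#'
#' Simulates every trial of a [make_learning_session()] plan. Within each
#' block the surrogate's intentional strength and noise follow the plan; its
#' intended phase is the experienced one (the partner-minus-VT attractor at
#' -90 degrees for a specified 90). Rewards are detected on each trial and
#' written into its `reward` column.
#'
#' @inheritParams run_scanning_session
#' @param blocks,trials_per_block Session layout.
#' @param rule A [reward_rule()].
#' @param ... Passed to [make_learning_session()] (e.g. custom schedules).
#' @return A list of `trial_record`s with attributes `plan` and `rewards`
#'   (list of reward-time vectors).
#' @export
run_learning_session <- function(seed, p = vt_params(),
                                 sp = surrogate_params(), blocks = 5,
                                 trials_per_block = 10,
                                 rule = reward_rule(), fs = 500, ...) {
  plan <- make_learning_session(seed, blocks = blocks,
                                trials_per_block = trials_per_block, ...)
  sched <- make_learning_trial(fs = fs)
  trials <- vector("list", nrow(plan))
  rewards <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    spk <- sp
    spk$c <- plan$c[k]
    spk$sigma <- plan$sigma[k]
    spk$psi_intent <- -plan$psi_deg[k] * pi / 180
    tr <- simulate_dyad(sched, surrogate_partner(spk), p = p,
                        seed = plan$trial_seed[k], fs = fs)
    ev <- detect_rewards(tr, rule)
    tr$reward <- 0L
    if (length(ev)) {
      idx <- round(ev * fs) + 1
      tr$reward[idx[idx <= nrow(tr)]] <- 1L
    }
    trials[[k]] <- tr
    rewards[[k]] <- ev
  }
  structure(trials, plan = plan, rewards = rewards, seed = seed)
}

#' Reward rule
#'
#' The learning experiment's feedback criterion: a reward is delivered at a
#' partner peak-velocity instant when the measured relative phase lies
#' within `tol_deg` of the target pattern or its mirror image, at most once
#' per movement cycle.
#'
#' @param target_deg Target relative phase (degrees).
#' @param tol_deg Half-width of the reward window (degrees, 0 < tol < 90).
#' @return An object of class `reward_rule`.
#' @export
reward_rule <- function(target_deg = 90, tol_deg = 40) {
  if (!is.finite(tol_deg) || tol_deg <= 0 || tol_deg >= 90) {
    stop("tol_deg must lie strictly between 0 and 90", call. = FALSE)
  }
  structure(list(target_deg = target_deg, tol_deg = tol_deg,
                 max_per_cycle = 1L), class = "reward_rule")
}

#' Detect reward events in a trial
#'
#' Finds the partner's peak-velocity instants (one per movement cycle: local
#' maxima of the low-pass-filtered velocity), evaluates the continuous
#' relative phase there, and emits a reward when the wrapped distance to the
#' target or its mirror image is within tolerance. Movement cycles are
#' delimited by successive partner peak-flexion instants (position maxima);
#' at most one reward is delivered per cycle and never two events closer
#' than 0.75 cycles. Rewards are evaluated during the Exposition period and
#' the first 10 s of Memory (the windows in which feedback could occur at
#' the 1 Hz movement rate: up to 20 and 10 tones respectively).
#'
#' @param trial A `trial_record`.
#' @param rule A [reward_rule()].
#' @return Sorted numeric vector of reward times (s); empty if none.
#' @export
detect_rewards <- function(trial, rule = reward_rule()) {
  if (nrow(trial) == 0) return(numeric(0))
  fs <- attr(trial, "fs") %||% 500
  schedule <- attr(trial, "schedule")
  validate_schedule(schedule)
  lab <- as.character(schedule$label)
  t_pace <- sum(schedule$duration[schedule$pacing])
  d_expo <- sum(schedule$duration[lab == "Exposition"])
  t_mem <- t_pace + d_expo

  # movement-band filter for cycle structure: at high phase noise the raw
  # 20 Hz-filtered signal can carry sub-cycle wiggles that would double-count
  # peaks, so cycles and velocity peaks are located on a 2.5 Hz version
  bf <- signal::butter(2, 2.5 / (fs / 2), type = "low")
  yf <- as.numeric(signal::filtfilt(bf, trial$y_partner - mean(trial$y_partner)))
  dy <- diff3pt(yf, 1 / fs)

  vel_pk <- local_maxima(dy)
  pos_pk <- local_maxima(yf)
  if (length(vel_pk) == 0 || length(pos_pk) < 2) return(numeric(0))
  cycle_len <- stats::median(diff(pos_pk)) / fs

  x <- preprocess(trial$x_vt, fs = fs)
  y <- preprocess(trial$y_partner, fs = fs)
  rp <- continuous_rp(x, y, t = trial$t)

  tpk <- trial$t[vel_pk]
  in_window <- (tpk >= t_pace & tpk < t_mem) |
    (tpk >= t_mem & tpk < t_mem + 10)
  vel_pk <- vel_pk[in_window]
  tpk <- tpk[in_window]
  if (length(vel_pk) == 0) return(numeric(0))

  err <- constant_error(rp$rp[vel_pk], rule$target_deg, signed = FALSE)
  hit <- err <= rule$tol_deg
  tpk <- tpk[hit]
  if (length(tpk) == 0) return(numeric(0))

  # one reward per movement cycle + refractory of 0.75 cycles
  cyc <- findInterval(tpk, trial$t[pos_pk])
  keep <- !duplicated(cyc)
  tpk <- tpk[keep]
  out <- numeric(0)
  last <- -Inf
  for (tt in tpk) {
    if (tt - last >= 0.75 * cycle_len) {
      out <- c(out, tt)
      last <- tt
    }
  }
  out
}

# Indices of strict interior local maxima.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Percent of possible reward hits in a period
#'
#' Expresses a reward count as a percentage of the maximum achievable at the
#' 1 Hz movement rate: 20 during the 20 s Exposition and 10 during the
#' analyzed 10 s of Memory.
#'
#' @param events Vector of reward times in seconds. When `trial` is `NULL` a
#'   single whole-number value is interpreted as an event count instead.
#' @param period `"Exposition"` or `"Memory"`.
#' @param trial Optional `trial_record`; when supplied, events are
#'   attributed to the period via its schedule before counting.
#' @return Percentage in \[0, 100\].
#' @export
percent_hits <- function(events, period = c("Exposition", "Memory"),
                         trial = NULL) {
  period <- match.arg(period)
  max_hits <- if (period == "Exposition") 20 else 10
  count <- if (!is.null(trial)) {
    schedule <- attr(trial, "schedule")
    lab <- as.character(schedule$label)
    t_pace <- sum(schedule$duration[schedule$pacing])
    t_mem <- t_pace + sum(schedule$duration[lab == "Exposition"])
    if (period == "Exposition") {
      sum(events >= t_pace & events < t_mem)
    } else {
      sum(events >= t_mem & events < t_mem + 10)
    }
  } else if (length(events) == 1 && events >= 0 && events == round(events)) {
    events
  } else {
    length(events)
  }
  # a 1 Hz nominal movement can squeeze one extra cycle into a period, so
  # cap at the stated maximum of possible hits
  min(100, 100 * count / max_hits)
}
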