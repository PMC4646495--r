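# Shared fixtures: small parameter sets and constructed trial records.

fs_default <- 500

# A trial record holding both partners at a fixed relative phase
# (rp = phase_VT - phase_partner = shift_deg), on the learning-trial
# schedule. Used for reward-rule and pipeline-consistency checks.
locked_trial <- function(shift_deg, schedule = make_learning_trial(),
                         fs = fs_default, f0 = 1) {
  n <- round(sum(schedule$duration) * fs)
  tt <- (seq_len(n) - 1) / fs
  tr <- data.frame(
    t = tt,
    x_vt = cos(2 * pi * f0 * tt),
    y_partner = cos(2 * pi * f0 * tt - shift_deg * pi / 180),
    C = 0, A = 0, B = 0, psi_deg = 90,
    period_label = rep(as.character(schedule$label),
                       times = round(schedule$duration * fs)),
    reward = 0L, stringsAsFactors = FALSE
  )
  structure(tr, class = c("trial_record", "data.frame"),
            schedule = schedule, fs = fs)
}

wrap_deg <- function(d) (d + 180) %% 360 - 180

# Coupled logistic maps, X driving Y with strength e.
logistic_pair <- function(n, e = 0.4, seed = 1) {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1); y[1] <- runif(1)
  f <- function(u) 4 * u * (1 - u)
  for (i in 2:n) {
    x[i] <- f(x[i - 1])
    y[i] <- f((1 - e) * y[i - 1] + e * x[i - 1])
  }
  list(x = x, y = y)
}

# Session-level caches so the expensive simulations run once per test run.
session_cache <- new.env(parent = emptyenv())

cached_scanning_session <- function(seed = 7) {
  key <- paste0("scan_", seed)
  if (is.null(session_cache[[key]])) {
    session_cache[[key]] <- run_scanning_session(seed)
  }
  session_cache[[key]]
}

cached_learning_session <- function(seed = 7) {
  key <- paste0("learn_", seed)
  if (is.null(session_cache[[key]])) {
    session_cache[[key]] <- run_learning_session(seed)
  }
  session_cache[[key]]
}
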