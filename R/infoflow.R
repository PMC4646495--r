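#' Transfer-entropy configuration
#'
#' Embedding and estimator settings for [transfer_entropy()]. The defaults
#' follow the analysis pipeline: past-state vectors of length 5 for both
#' series (conservative relative to the near-limit-cycle correlation
#' dimension of rhythmic limb movement), prediction lag and embedding delay
#' both taken from the autocorrelation of the target (first zero crossing by
#' default; the first-minimum convention is selectable), 4 equal-width
#' amplitude bins, and decimation of the 500 Hz series by 10 so that the
#' (k+m+1)-dimensional histogram is populated over 5-20 s segments.
#'
#' @param k Target past-state vector length (samples, >= 1).
#' @param m Source past-state vector length (samples, >= 1).
#' @param tau Prediction lag in (decimated) samples, or `NULL` to derive it
#'   from the target autocorrelation.
#' @param embed_delay Samples between embedded coordinates, or `NULL` to use
#'   the autocorrelation-derived delay.
#' @param n_bins Number of equal-width amplitude bins (>= 2).
#' @param downsample Integer decimation factor applied before estimation.
#' @param delay_method `"zero_crossing"` or `"first_minimum"` of the
#'   autocorrelation.
#' @return An object of class `te_config`.
#' @export
te_config <- function(k = 5, m = 5, tau = NULL, embed_delay = NULL,
                      n_bins = 4, downsample = 10,
                      delay_method = c("zero_crossing", "first_minimum")) {
  delay_method <- match.arg(delay_method)
  stopifnot(k >= 1, m >= 1, n_bins >= 2, downsample >= 1)
  if (!is.null(tau) && tau < 1) stop("tau must be >= 1", call. = FALSE)
  structure(list(k = as.integer(k), m = as.integer(m), tau = tau,
                 embed_delay = embed_delay, n_bins = as.integer(n_bins),
                 downsample = as.integer(downsample),
                 delay_method = delay_method),
            class = "te_config")
}

#' Autocorrelation-derived embedding delay
#'
#' The smallest positive lag at which the (biased) autocorrelation of the
#' series decays through zero, interpolated linearly between lags and
#' rounded to the nearest sample; alternatively the first local minimum.
#' A 1 Hz cosine sampled at 500 Hz gives 125 samples (a quarter period).
#'
#' @param v Numeric series (at least ~4 cycles for a meaningful estimate).
#' @param method `"zero_crossing"` (default) or `"first_minimum"`.
#' @return Integer lag in samples (>= 1).
#' @export
autocorr_delay <- function(v, method = c("zero_crossing", "first_minimum")) {
  method <- match.arg(method)
  n <- length(v)
  if (stats::sd(v) == 0) {
    stop("autocorrelation of a constant series has no zero crossing",
         call. = FALSE)
  }
  lag_max <- floor(n / 2)
  ac <- as.numeric(stats::acf(v, lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf)
  if (method == "zero_crossing") {
    neg <- which(ac <= 0)
    if (length(neg) == 0) {
      stop("autocorrelation has no zero crossing within half the series",
           call. = FALSE)
    }
    j <- neg[1]                       # 1-based: lag j-1
    if (ac[j] == 0) return(max(1L, j - 1L))
    # interpolate between lags j-2 and j-1
    frac <- ac[j - 1] / (ac[j - 1] - ac[j])
    max(1L, as.integer(round(j - 2 + frac)))
  } else {
    d <- diff(ac)
    up <- which(d[-1] >= 0 & d[-length(d)] < 0)
    if (length(up) == 0) {
      stop("autocorrelation has no local minimum within half the series",
           call. = FALSE)
    }
    max(1L, up[1])
  }
}

#' Delay embedding
#'
#' Builds the matrix of past-state vectors: the row for index i is
#' (v\[i\], v\[i - delay\], ..., v\[i - (length-1) delay\]) -- the vector
#' *ending* at sample i. Boundary samples without a full history are
#' dropped, so the result has `length(v) - (length - 1) * delay` rows.
#'
#' @param v Numeric or integer series.
#' @param length Embedding dimension (number of coordinates).
#' @param delay Samples between coordinates.
#' @return A matrix with one past-state vector per row; row i corresponds to
#'   sample index `i + (length - 1) * delay` of the input.
#' @export
embed_series <- function(v, length, delay = 1) {
  n <- base::length(v)
  span <- (length - 1) * delay
  if (n <= span) stop("series too short for this embedding", call. = FALSE)
  idx_end <- (span + 1):n
  out <- vapply(0:(length - 1), function(j) v[idx_end - j * delay],
                numeric(n - span))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  out
}

# Quantize a series into 1..n_bins equal-width bins over its range.
quantize_series <- function(v, n_bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  b <- pmin(n_bins, 1L + as.integer(floor((v - r[1]) / diff(r) * n_bins)))
  as.integer(b)
}

# Encode integer-state matrices (values 1..base) as scalar keys.
encode_states <- function(mat, base) {
  pow <- base ^ (seq_len(ncol(mat)) - 1)
  as.numeric((mat - 1) %*% pow)
}

#' Transfer entropy (histogram plug-in estimator)
#'
#' Estimates the transfer entropy from `source` to `target` in bits:
#' the reduction in uncertainty about the target's next value gained from
#' the source's past states over and above the target's own past,
#' \deqn{T_{X\to Y} = \sum p(y_{i+\tau}, y_i^{(k)}, x_i^{(m)}) \log_2
#'   \frac{p(y_{i+\tau}, y_i^{(k)}, x_i^{(m)})\, p(y_i^{(k)})}
#'        {p(y_i^{(k)}, x_i^{(m)})\, p(y_{i+\tau}, y_i^{(k)})}}
#' with probabilities estimated from joint histogram counts and the
#' convention 0 log 0 = 0. Continuous inputs are first decimated and
#' quantized into equal-width amplitude bins; already-discrete inputs can be
#' passed through unchanged with `discretize = FALSE`.
#'
#' @param source Numeric series X (the candidate driver).
#' @param target Numeric series Y (the driven series).
#' @param cfg A [te_config()].
#' @param discretize Quantize the inputs (set `FALSE` for already-discrete
#'   integer series, which are then used as-is and not decimated).
#' @return Transfer entropy in bits (>= 0), with attributes `n` (number of
#'   embedded samples), `tau`, `embed_delay`, and `small_sample` (TRUE when
#'   fewer than 10 samples per occupied joint state were available, in which
#'   case a warning is also issued).
#' @export
transfer_entropy <- function(source, target, cfg = te_config(),
                             discretize = TRUE) {
  if (length(source) != length(target)) {
    stop("source and target must have equal length", call. = FALSE)
  }
  if (discretize) {
    if (cfg$downsample > 1) {
      keep <- seq(1, length(target), by = cfg$downsample)
      source <- source[keep]
      target <- target[keep]
    }
    xs <- quantize_series(source, cfg$n_bins)
    ys <- quantize_series(target, cfg$n_bins)
  } else {
    xs <- as.integer(as.integer(factor(source)))
    ys <- as.integer(as.integer(factor(target)))
  }
  d <- cfg$embed_delay %||% autocorr_delay(ys, cfg$delay_method)
  tau <- cfg$tau %||% d
  n <- length(ys)
  span <- max(cfg$k, cfg$m) * d - d     # history needed before index i
  if (n < span + tau + 2) {
    stop("segment too short for this embedding (need > ",
         span + tau + 1, " samples)", call. = FALSE)
  }
  i <- (span + 1):(n - tau)
  base_n <- max(xs, ys, 2L)
  yp <- encode_states(embed_series(ys, cfg$k, d)[i - (cfg$k - 1) * d, ,
                                                 drop = FALSE], base_n)
  xp <- encode_states(embed_series(xs, cfg$m, d)[i - (cfg$m - 1) * d, ,
                                                 drop = FALSE], base_n)
  yf <- as.numeric(ys[i + tau])

  key_yp <- match(yp, unique(yp))
  key_ypxp <- match(paste(yp, xp), unique(paste(yp, xp)))
  key_yfyp <- match(paste(yf, yp), unique(paste(yf, yp)))
  key3 <- paste(yf, yp, xp)
  u3 <- unique(key3)
  key3 <- match(key3, u3)

  N <- length(i)
  n3 <- tabulate(key3, nbins = length(u3))
  n_yp <- tabulate(key_yp)
  n_ypxp <- tabulate(key_ypxp)
  n_yfyp <- tabulate(key_yfyp)

  # per-observation representative of each joint state
  first3 <- match(seq_along(u3), key3)
  te <- sum(n3 / N * log2(n3 * n_yp[key_yp[first3]] /
                            (n_ypxp[key_ypxp[first3]] *
                               n_yfyp[key_yfyp[first3]])))
  te <- max(0, te)
  small <- N < 10 * length(u3)
  if (small) {
    warning("transfer entropy estimated from fewer than 10 samples per ",
            "occupied state: expect small-sample bias", call. = FALSE)
  }
  structure(te, n = N, tau = tau, embed_delay = d, small_sample = small)
}

#' Transfer entropy via conditional entropies (reference implementation)
#'
#' Computes \eqn{T_{X\to Y} = H(Y_{i+\tau} | Y_i^{(k)}) -
#' H(Y_{i+\tau} | Y_i^{(k)}, X_i^{(m)})} directly from exhaustive joint
#' counts. This is an independent code path from [transfer_entropy()]
#' (entropies of tabulated joint distributions rather than the rewritten
#' single-sum form) used as a cross-check in the test suite; both are
#' algebraically identical on the same counts.
#'
#' @param source,target Integer (discrete) series of equal length.
#' @param k,m,tau,embed_delay Embedding settings (samples).
#' @return Transfer entropy in bits.
#' @export
te_oracle <- function(source, target, k = 1, m = 1, tau = 1,
                      embed_delay = 1) {
  stopifnot(length(source) == length(target))
  d <- embed_delay
  n <- length(target)
  span <- max(k, m) * d - d
  i <- (span + 1):(n - tau)
  emb <- function(v, len) {
    apply(embed_series(v, len, d), 1, paste, collapse = ",")
  }
  yp_all <- emb(target, k)
  xp_all <- emb(source, m)
  yp <- yp_all[i - (k - 1) * d]
  xp <- xp_all[i - (m - 1) * d]
  yf <- as.character(target[i + tau])
  H <- function(...) {
    p <- as.numeric(table(paste(...))) / length(i)
    -sum(p * log2(p))
  }
  (H(yf, yp) - H(yp)) - (H(yf, yp, xp) - H(yp, xp))
}

#' Bidirectional transfer entropy by trial segment
#'
#' Applies [transfer_entropy()] in both directions to the position series of
#' each analysis segment of a trial (Exposition, M1, M2 for scanning trials;
#' Exposition and Memory for learning-style analysis). Signals are
#' preprocessed with the standard chain first, so TE operates on the
#' normalized waveforms the rest of the pipeline sees.
#'
#' @param trial A `trial_record`.
#' @param cfg A [te_config()].
#' @param segments `"scanning"` (Exposition/M1/M2) or `"learning"`
#'   (Exposition/Memory).
#' @return A data.frame with one row per segment: `segment`,
#'   `te_vt_to_partner`, `te_partner_to_vt`, `n`, `tau`, `embed_delay`
#'   (in decimated samples), `k`, `m`, `n_bins`, `downsample`.
#' @export
te_by_segment <- function(trial, cfg = te_config(),
                          segments = c("scanning", "learning")) {
  segments <- match.arg(segments)
  fs <- attr(trial, "fs") %||% 500
  schedule <- attr(trial, "schedule")
  validate_schedule(schedule)
  lab <- as.character(schedule$label)
  t_pace <- sum(schedule$duration[schedule$pacing])
  d_expo <- sum(schedule$duration[lab == "Exposition"])
  d_mem <- sum(schedule$duration[lab == "Memory"])
  t1 <- t_pace + d_expo
  x <- preprocess(trial$x_vt, fs = fs)
  y <- preprocess(trial$y_partner, fs = fs)
  windows <- if (segments == "scanning") {
    list(Exposition = c(t_pace, t1), M1 = c(t1, t1 + 5),
         M2 = c(t1 + d_mem - 6, t1 + d_mem - 1))
  } else {
    list(Exposition = c(t_pace, t1), Memory = c(t1, t1 + d_mem - 1))
  }
  out <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    idx <- trial$t >= w[1] - 1e-9 & trial$t < w[2] - 1e-9
    xy <- suppressWarnings(transfer_entropy(x[idx], y[idx], cfg))
    yx <- suppressWarnings(transfer_entropy(y[idx], x[idx], cfg))
    data.frame(segment = nm, te_vt_to_partner = as.numeric(xy),
               te_partner_to_vt = as.numeric(yx), n = attr(xy, "n"),
               tau = attr(xy, "tau"), embed_delay = attr(xy, "embed_delay"),
               k = cfg$k, m = cfg$m, n_bins = cfg$n_bins,
               downsample = cfg$downsample, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
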