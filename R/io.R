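#' Default run configuration
#'
#' The full configuration tree with every option at its package default.
#' Degrees and Hz at the interface; radians and rad/s internally.
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  p <- vt_params()
  sp <- surrogate_params()
  structure(list(
    vt = list(alpha = p$alpha, beta = p$beta, gamma = p$gamma,
              omega_hz = p$omega / (2 * pi), A = p$A, B = p$B, mu = p$mu),
    surrogate = list(a = sp$a, b = sp$b, c = sp$c,
                     psi_intent_deg = sp$psi_intent * 180 / pi,
                     sigma = sp$sigma, delay_s = sp$delay_s,
                     amplitude = sp$amplitude,
                     omega_hz = sp$omega_h / (2 * pi)),
    loop = list(fs_hz = 500, delay_ticks = 1),
    protocol = list(type = "scan", blocks = NULL, trials_per_block = NULL),
    analysis = list(convention = "vt_minus_partner"),
    te = list(k = 5, m = 5, tau = NULL, embed_delay = NULL, n_bins = 4,
              downsample = 10, delay_method = "zero_crossing"),
    seed = 1
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills every missing key with its package
#' default and rejects unknown keys (naming the offender). An empty file
#' yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(default_config(), user, prefix = "")
}

merge_config <- function(def, user, prefix) {
  if (!is.list(user)) {
    stop("config section '", sub("\\.$", "", prefix),
         "' must be a mapping", call. = FALSE)
  }
  bad <- setdiff(names(user), names(def))
  if (length(bad)) {
    stop("unknown config key: ", prefix, bad[1], call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      def[[nm]] <- merge_config(def[[nm]], user[[nm]],
                                paste0(prefix, nm, "."))
    } else {
      # keep the slot even when the user value is NULL ("use default")
      def[nm] <- list(user[[nm]])
    }
  }
  def
}

#' Save a run configuration
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path, precision = 15)
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

# Materialize parameter objects from a config tree.
config_params <- function(config) {
  list(
    p = vt_params(alpha = config$vt$alpha, beta = config$vt$beta,
                  gamma = config$vt$gamma,
                  omega = 2 * pi * config$vt$omega_hz,
                  A = config$vt$A, B = config$vt$B, mu = config$vt$mu),
    sp = surrogate_params(a = config$surrogate$a, b = config$surrogate$b,
                          c = config$surrogate$c,
                          psi_intent_deg = config$surrogate$psi_intent_deg,
                          sigma = config$surrogate$sigma,
                          delay_s = config$surrogate$delay_s,
                          amplitude = config$surrogate$amplitude,
                          omega_h = 2 * pi * config$surrogate$omega_hz),
    cfg_te = te_config(k = config$te$k, m = config$te$m, tau = config$te$tau,
                       embed_delay = config$te$embed_delay,
                       n_bins = config$te$n_bins,
                       downsample = config$te$downsample,
                       delay_method = config$te$delay_method)
  )
}

trial_csv_columns <- c("t", "x_vt", "y_partner", "C", "A", "B", "psi_deg",
                       "period_label", "reward")

#' Write a trial record to CSV
#'
#' One row per tick, header `t,x_vt,y_partner,C,A,B,psi_deg,period_label,
#' reward`, UTF-8, '.' decimal separator. Numeric columns are written with
#' 17 significant digits so the round trip through [read_trial()] is
#' lossless at double precision. In-memory auxiliary columns (velocities,
#' ground-truth phase) are not part of the on-disk dialect.
#'
#' @param trial A `trial_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  df <- trial[, trial_csv_columns]
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
    }
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial record from CSV
#'
#' Reads a file written by [write_trial()], validates the header and
#' rectangularity, reconstructs the coupling schedule from the parameter
#' traces (which change only at period boundaries) and recomputes partner
#' and VT velocities by 3-point differentiation.
#'
#' @param path Path to a trial CSV.
#' @return A `trial_record`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(header, trial_csv_columns)) {
    stop("trial CSV dialect mismatch: header is '",
         paste(header, collapse = ","), "'", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  num_cols <- setdiff(trial_csv_columns, "period_label")
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("parse error in ", path, ": non-numeric '", nm, "' at data row ",
           bad[1], call. = FALSE)
    }
    df[[nm]] <- v
  }
  df$reward <- as.integer(df$reward)
  fs <- round(1 / stats::median(diff(df$t)))
  r <- rle(df$period_label)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  schedule <- data.frame(
    label = r$values,
    duration = r$lengths / fs,
    C = df$C[starts], A = df$A[starts], B = df$B[starts],
    psi_deg = df$psi_deg[starts],
    pacing = r$values == "Pacing",
    stringsAsFactors = FALSE
  )
  schedule <- structure(schedule, class = c("coupling_schedule",
                                            "data.frame"), fs = fs)
  df$dx_vt <- diff3pt(df$x_vt, 1 / fs)
  df$dy_partner <- diff3pt(df$y_partner, 1 / fs)
  structure(df, class = c("trial_record", "data.frame"),
            schedule = schedule, fs = fs)
}

#' Run a configured session end to end
#'
#' Executes the selected protocol (scanning or learning) against the
#' configured surrogate, writes one trial CSV per trial, a tidy per-segment
#' results table, a transfer-entropy table, and a JSON manifest with the
#' seed, configuration (and its hash) and package version. Rerunning with
#' the same configuration and seed reproduces identical tables.
#'
#' @param config A `run_config` (see [load_config()], [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_session <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prm <- config_params(config)
  type <- config$protocol$type
  seed <- config$seed
  if (type == "scan") {
    trials <- run_scanning_session(seed, p = prm$p, sp = prm$sp,
                                   fs = config$loop$fs_hz)
    seg_kind <- "scanning"
  } else if (type == "learn") {
    trials <- run_learning_session(
      seed, p = prm$p, sp = prm$sp,
      blocks = config$protocol$blocks %||% 5,
      trials_per_block = config$protocol$trials_per_block %||% 10,
      fs = config$loop$fs_hz)
    seg_kind <- "learning"
  } else {
    stop("unknown protocol type: ", type, call. = FALSE)
  }
  for (k in seq_along(trials)) {
    write_trial(trials[[k]], file.path(out_dir,
                                       sprintf("trial_%03d.csv", k)))
  }
  res <- analyze_session(trials, convention = config$analysis$convention)
  utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
  te <- do.call(rbind, lapply(seq_along(trials), function(k) {
    cbind(trial = k,
          te_by_segment(trials[[k]], prm$cfg_te, segments = seg_kind))
  }))
  utils::write.csv(te, file.path(out_dir, "te.csv"), row.names = FALSE)
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(
    package = "hdclamp",
    version = as.character(utils::packageVersion("hdclamp")),
    seed = seed,
    protocol = type,
    n_trials = length(trials),
    config_hash = fnv1a(cfg_json),
    config = unclass_deep(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# 32-bit FNV-1a hash of a string, as 8 hex digits (pure R, double
# arithmetic split into 16-bit halves to stay exact; used to fingerprint
# configurations in manifests).
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)   # xor touches the low byte only
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
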