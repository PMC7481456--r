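#' Read an R-peak annotation file
#'
#' Plain text, one event time in seconds per line (comments and blank lines
#' are not allowed). Times must be strictly increasing.
#'
#' @param path file path.
#' @return Numeric vector of peak times in seconds.
#' @export
read_rpeaks <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty R-peak annotation file: ", path)
  v <- suppressWarnings(as.numeric(lines))
  if (anyNA(v))
    stop("malformed R-peak annotation at line ", which(is.na(v))[1],
         " of ", path)
  if (any(diff(v) <= 0))
    stop("non-monotone R-peak time at line ", which(diff(v) <= 0)[1] + 1,
         " of ", path)
  v
}

#' Write an R-peak annotation file
#' @param rpeak_times numeric vector of peak times in seconds.
#' @param path output path.
#' @export
write_rpeaks <- function(rpeak_times, path) {
  writeLines(format(rpeak_times, digits = 10, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Read a respiration waveform file
#'
#' CSV with either `time,value` columns or a single `value` column; in the
#' single-column case the sampling rate comes from `rate` or from a sidecar
#' JSON (`<path>.json` with a `rate` field).
#'
#' @param path CSV path.
#' @param rate sampling rate in Hz (optional if derivable).
#' @return List with `resp` (numeric waveform) and `rate` (Hz).
#' @export
read_resp <- function(path, rate = NULL) {
  df <- read.csv(path)
  if (nrow(df) == 0) stop("empty respiration file: ", path)
  if (all(c("time", "value") %in% names(df))) {
    dt <- diff(df$time)
    if (any(dt <= 0)) stop("non-monotone time column in ", path)
    rate <- 1 / median(dt)
    return(list(resp = df$value, rate = rate))
  }
  if (is.null(rate)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) rate <- jsonlite::read_json(sidecar)$rate
  }
  if (is.null(rate)) stop("sampling rate not given and no sidecar JSON found")
  list(resp = df[[1]], rate = rate)
}

#' Write a respiration waveform with a sampling-rate sidecar
#' @param resp waveform; @param rate Hz; @param path CSV path.
#' @export
write_resp <- function(resp, rate, path) {
  write.csv(data.frame(value = resp), path, row.names = FALSE)
  jsonlite::write_json(list(rate = rate), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read sleep-state intervals
#'
#' CSV with columns `start`, `end` (seconds) and `state` (e.g. AS/QS).
#' @param path CSV path.
#' @return Data frame `start`, `end`, `state`.
#' @export
read_sleep_states <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "state")
  if (!all(need %in% names(df)))
    stop("sleep-state file must have columns start,end,state")
  if (any(df$end <= df$start)) stop("empty or inverted state interval in ", path)
  df[need]
}

#' Assemble a physiological record from component files
#'
#' @param rpeaks_path R-peak annotation file ([read_rpeaks()]).
#' @param resp_path respiration CSV ([read_resp()]).
#' @param sleep_path optional sleep-state CSV ([read_sleep_states()]).
#' @param resp_rate optional sampling rate override in Hz.
#' @return A `physio_record` usable by [segment_and_normalize()].
#' @export
read_physio_record <- function(rpeaks_path, resp_path, sleep_path = NULL,
                               resp_rate = NULL) {
  rp <- read_rpeaks(rpeaks_path)
  rs <- read_resp(resp_path, rate = resp_rate)
  ss <- if (!is.null(sleep_path)) read_sleep_states(sleep_path) else NULL
  structure(list(rpeak_times = rp, resp = rs$resp, resp_fs = rs$rate,
                 sleep_states = ss, ground_truth = NULL, spec = NULL),
            class = "physio_record")
}

#' Read / write a bivariate series as CSV
#'
#' Comma-separated, dot decimal, mandatory header `x,y`; a lossless round
#' trip for analysis series.
#'
#' @param pair a [bivariate_series()] (for writing).
#' @param path CSV path.
#' @param normalize z-normalize on read (default `FALSE`).
#' @return `read_series_csv`: a [bivariate_series()].
#' @export
write_series_csv <- function(pair, path) {
  stopifnot(inherits(pair, "bivariate_series"))
  df <- data.frame(x = pair$x, y = pair$y)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path, normalize = FALSE) {
  df <- read.csv(path)
  if (nrow(df) == 0) stop("empty series file: ", path)
  if (!all(c("x", "y") %in% names(df)))
    stop("series file must have columns x,y")
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop("malformed series row ", bad[1] + 1, " of ", path)
  bivariate_series(df$x, df$y, normalize = normalize)
}

#' Write lag-profile results as long-format CSV
#'
#' One row per (direction, lag) with the TE value, raw value, surrogate
#' threshold, significance flag and embedding sizes; a `segment_id` column
#' is added when given.
#'
#' @param profile a `te_lag_profile` (or its `results` data frame).
#' @param path CSV path.
#' @param segment_id optional identifier column value.
#' @export
write_results_csv <- function(profile, path, segment_id = NULL) {
  df <- if (inherits(profile, "te_lag_profile")) profile$results else profile
  if (!is.null(segment_id)) df <- cbind(segment_id = segment_id, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write candidate selection frequencies as long-format CSV
#' @param freq data frame from [candidate_frequency()]; @param path CSV path.
#' @export
write_candidate_csv <- function(freq, path) {
  write.csv(freq, path, row.names = FALSE)
  invisible(path)
}

#' Write segment pairs and a provenance manifest
#'
#' Each segment goes to `segment_<i>.csv` (columns `rr,resp`); the manifest
#' JSON records state, start index/time and rejection statistics.
#'
#' @param segments list of `segment_pair` objects.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_segments <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    f <- file.path(dir, sprintf("segment_%03d.csv", i))
    write.csv(data.frame(rr = s$rr, resp = s$resp), f, row.names = FALSE)
    manifest[[i]] <- list(file = basename(f), state = s$state,
                          start_index = s$start_index,
                          start_time = s$start_time,
                          n_flagged = s$n_flagged, L = s$L)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Write a mediation result as JSON
#' @param m a `mediation_result` from [sobel_mediation()].
#' @param path output path.
#' @export
write_mediation_json <- function(m, path) {
  stopifnot(inherits(m, "mediation_result"))
  jsonlite::write_json(
    list(a = unname(m$a["est"]), se_a = unname(m$a["se"]),
         b = unname(m$b["est"]), se_b = unname(m$b["se"]),
         c = unname(m$c["est"]), c_prime = unname(m$c_prime["est"]),
         sobel_z = m$sobel_z, p = m$p,
         prop_mediated_pct = m$prop_mediated_pct, n = m$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline with defaults matching the
#' standard settings: candidate depth `L_max = 10`, lag grid up to
#' `tau_max = 15`, 100 surrogates with maximum shift 20 and a 95th
#' percentile threshold, 100 selection shuffles at `alpha = 0.05`,
#' `k = 10` neighbors.
#'
#' @param k neighbor count.
#' @param clip_negative clip reported TE at zero.
#' @param L_max candidate depth.
#' @param n_shuffles selection-gate permutations.
#' @param alpha selection-gate level.
#' @param gate selection-gate rule (`"sidak"` or `"percentile"`).
#' @param tau_max maximum lag.
#' @param n_surrogates surrogate count.
#' @param max_shift maximum surrogate shift.
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(k = 10, clip_negative = TRUE, L_max = 10,
                       n_shuffles = 100, alpha = 0.05, gate = "sidak",
                       tau_max = 15, n_surrogates = 100, max_shift = 20,
                       seed = 1) {
  cfg <- list(k = as.integer(k), clip_negative = isTRUE(clip_negative),
              L_max = as.integer(L_max), n_shuffles = as.integer(n_shuffles),
              alpha = alpha, gate = gate, tau_max = as.integer(tau_max),
              n_surrogates = as.integer(n_surrogates),
              max_shift = as.integer(max_shift), seed = as.integer(seed))
  stopifnot(cfg$k >= 1, cfg$L_max >= 1, cfg$alpha > 0, cfg$alpha < 1,
            cfg$tau_max >= 0, cfg$n_surrogates >= 1, cfg$max_shift >= 1,
            cfg$gate %in% c("sidak", "percentile"))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Stable hash of a resolved configuration
#'
#' MD5 of the canonical serialized key-value list; two runs with equal hash
#' and seed produce byte-identical result files.
#'
#' @param cfg a `run_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, format, ""), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

# selection_policy carved out of a run_config
config_policy <- function(cfg) {
  selection_policy(L_max = cfg$L_max, n_shuffles = cfg$n_shuffles,
                   alpha = cfg$alpha, gate = cfg$gate)
}
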