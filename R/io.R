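#' Write a time-series stream with header metadata
#'
#' Tab-separated values preceded by `#`-prefixed `key=value` header
#' lines (at least `fs`, `units` and `channels`), a diff-able,
#' language-neutral format for multi-rate laboratory streams.
#'
#' @param x data frame or matrix (one column per channel, one row per
#'   sample).
#' @param path output file path.
#' @param fs sampling rate (Hz).
#' @param units unit string (e.g. `"m"`, `"uV"`).
#' @param channels channel names; default from `colnames(x)`.
#' @param extra named list of extra header fields.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, fs, units = "", channels = colnames(x),
                             extra = list()) {
  x <- as.data.frame(x)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(x)))
  hdr <- c(fs = fs, units = units,
           channels = paste(channels, collapse = ","), extra)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(hdr)) writeLines(sprintf("# %s=%s", k, hdr[[k]]), con)
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = channels)
  invisible(path)
}

#' Read a time-series stream written by [write_timeseries()]
#'
#' Parses the `#` `key=value` header and the tab-separated payload, and
#' validates the stream against an expected schema. Long runs of
#' missing values (over 100 ms) are rejected with their location.
#'
#' @param path input file path.
#' @param expected_schema optional list with any of `fs`, `channels`,
#'   `units`; mismatches raise an error naming the offending field.
#' @return data frame of samples with attributes `fs`, `units`,
#'   `channels` and any extra header fields in `meta`.
#' @export
read_timeseries <- function(path, expected_schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 100L)
  hl <- grep("^#", lines)
  if (length(hl) == 0 || !any(grepl("^#\\s*fs=", lines)))
    stop("missing header: expected '# key=value' lines declaring fs")
  kv <- sub("^#\\s*", "", lines[hl])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  fs <- as.numeric(meta$fs)
  channels <- strsplit(meta$channels %||% "", ",")[[1]]
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE)
  if (length(channels) && !identical(names(x), channels))
    stop("schema error in field 'channels': header declares [",
         paste(channels, collapse = ","), "] but payload has [",
         paste(names(x), collapse = ","), "]")
  if (!is.null(expected_schema)) {
    if (!is.null(expected_schema$fs) &&
        !isTRUE(all.equal(expected_schema$fs, fs)))
      stop("schema error in field 'fs': expected ", expected_schema$fs,
           ", file declares ", fs)
    if (!is.null(expected_schema$channels) &&
        !identical(expected_schema$channels, channels))
      stop("schema error in field 'channels': expected [",
           paste(expected_schema$channels, collapse = ","), "], file has [",
           paste(channels, collapse = ","), "]")
    if (!is.null(expected_schema$units) &&
        !identical(expected_schema$units, meta$units))
      stop("schema error in field 'units': expected ", expected_schema$units,
           ", file declares ", meta$units)
    if (!is.null(expected_schema$n_samples) &&
        nrow(x) != expected_schema$n_samples)
      stop("schema error in field 'n_samples': expected ",
           expected_schema$n_samples, ", file has ", nrow(x))
  }
  max_gap <- ceiling(0.1 * fs)
  for (ch in names(x)) {
    r <- rle(is.na(x[[ch]]))
    if (any(r$values & r$lengths > max_gap)) {
      at <- cumsum(r$lengths)[which(r$values & r$lengths > max_gap)[1]]
      stop(sprintf("NaN run longer than 100 ms in channel '%s' ending at sample %d",
                   ch, at))
    }
  }
  attr(x, "fs") <- fs
  attr(x, "units") <- meta$units
  attr(x, "channels") <- names(x)
  attr(x, "meta") <- meta
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read perturbation event times
#'
#' One onset time (s) per line.
#'
#' @param events numeric vector of onset times (s).
#' @param path file path.
#' @return `write_events`: `path` invisibly; `read_events`: numeric
#'   vector.
#' @export
write_events <- function(events, path) {
  writeLines(format(events, digits = 15, trim = TRUE), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- as.numeric(readLines(path))
  if (any(is.na(ev)) || any(diff(ev) <= 0))
    stop("events must be numeric and strictly increasing")
  ev
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order — synthetic-trial generation
#' (stance simulation + multi-rate streams), posturography (joint
#' angles, CoM, relative CoP, EMG envelopes, event-locked averages),
#' phase-plane analytics (switch events, CoM-CoP zero-crossing rate,
#' OFF-onset), and EEG spectral analysis (ERP peaks, ERSP + bootstrap
#' mask, ITC, band time courses, ERS onset) — and writes the artifacts
#' into a directory. Deterministic given `seed`: all stage seeds are
#' derived from the top-level seed, no stage mutates its inputs, and a
#' resolved copy of the configuration is written next to the outputs.
#'
#' @param config nested list of stage parameter overrides; recognised
#'   blocks: `trial` (arguments of [synth_trial()]), `eeg` (arguments of
#'   [synth_eeg()]), `tfr` (`freqs`, `decim`), `rate` (`window`,
#'   `step`), `stages` (character subset of `c("trial", "eeg")`).
#'   May also be a path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param seed top-level integer seed.
#' @return named list of result objects, invisibly; artifacts are
#'   written under `out_dir` (`summary.json`, `config.yaml`, delimited
#'   profiles).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("stancekit-run-"),
                         seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("trial", "eeg", "tfr", "rate", "stages")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "))
  stages <- config$stages %||% c("trial", "eeg")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(seed = seed)
  summary <- list(seed = seed)

  if ("trial" %in% stages) {
    targs <- config$trial %||% list()
    targs$seed <- seed
    if (is.null(targs$n_events)) targs$n_events <- 3
    if (is.null(targs$interval)) targs$interval <- 20
    trial <- do.call(synth_trial, targs)
    body <- attr(trial$sim, "body")
    ang <- joint_angles_from_markers(trial$markers)
    com <- estimate_com(ang, trial$markers$fs, body)
    ankle_ap <- (trial$markers$ankle_l[, "ap"] +
                   trial$markers$ankle_r[, "ap"]) / 2
    cop_g <- resample_stream(trial$grf$cop, trial$fs[["forceplate"]],
                             trial$markers$fs)
    n <- min(length(cop_g), length(ankle_ap))
    cop <- cop_relative(cop_g[seq_len(n)], ankle_ap[seq_len(n)],
                        trial$markers$fs)
    window <- c(-5, min(15, targs$interval - 5.5))
    ela_com <- event_locked_average(com$x_com, trial$markers$fs,
                                    trial$events, window,
                                    t0 = trial$markers$t[1])
    emg_so <- process_emg(trial$emg$so_l, trial$emg$so_r,
                          trial$fs[["emg"]], trial$events, window,
                          t0 = trial$emg$t[1])
    eps <- epsilon_series(trial$sim)
    rate_args <- config$rate %||% list()
    rates <- upward_zero_crossing_rate(eps$t, eps$epsilon,
                                       window = rate_args$window %||% 2,
                                       step = rate_args$step %||% 0.1)
    sw <- detect_switch_events(trial$sim)
    res$trial <- trial
    res$posturography <- list(angles = ang, com = com, cop = cop,
                              com_avg = ela_com, emg_so = emg_so)
    res$phase <- list(rates = rates, switch_events = sw,
                      off_onset = off_onset_time(rates, trial$events[1]))
    summary$trial <- list(n_events = length(trial$events),
                          fallen = attr(trial$sim, "fallen"),
                          n_switch_events = nrow(sw),
                          off_onset_s = res$phase$off_onset,
                          emg_so_peak_latency_s = emg_so$peak_latency)
    write_timeseries(data.frame(t = ela_com$t, x_com = ela_com$mean),
                     file.path(out_dir, "com_event_locked.tsv"),
                     fs = trial$markers$fs, units = "m")
    write_timeseries(rates, file.path(out_dir, "crossing_rate.tsv"),
                     fs = 1 / attr(rates, "step"), units = "Hz")
    write_events(trial$events, file.path(out_dir, "events.txt"))
  }

  if ("eeg" %in% stages) {
    eargs <- config$eeg %||% list()
    eargs$seed <- seed + 1L
    se <- do.call(synth_eeg, eargs)
    tfr_args <- config$tfr %||% list()
    freqs <- tfr_args$freqs %||% seq(2, 40, by = 1)
    tfr <- morlet_tfr(se$epochs, freqs = freqs,
                      decim = tfr_args$decim %||% 10)
    er <- ersp(tfr)
    mk <- bootstrap_mask(tfr, n_boot = tfr_args$n_boot %||% 500,
                         seed = seed + 2L)
    er <- apply_ersp_mask(er, mk)
    it <- itc(tfr)
    erp <- compute_erp(se$epochs)
    pk <- erp_peaks(erp, channel = 1)
    bands <- Filter(function(b) b[1] >= min(freqs) && b[2] <= max(freqs),
                    unclass(band_set()))
    bt <- band_timecourse(er, bands = bands, channel = 1)
    onset <- tryCatch(ers_onset(er, mk, c(21, 30), channel = 1, t_min = 0.5),
                      error = function(e) NA_real_)
    res$eeg <- list(epochs = se$epochs, ground_truth = se$ground_truth,
                    ersp = er, itc = it, erp = erp, peaks = pk,
                    bands = bt, beta_ers_onset = onset)
    summary$eeg <- list(erp_peaks = as.list(stats::setNames(pk$latency,
                                                            pk$peak)),
                        beta_ers_onset_s = onset)
    write_timeseries(data.frame(t = erp$t, t(erp$erp)),
                     file.path(out_dir, "erp.tsv"), fs = se$epochs$fs,
                     units = "uV", channels = c("t", erp$channels))
  }

  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
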