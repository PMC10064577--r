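# Waveform / events / answer-key CSV I/O with provenance headers.
#
# Waveform column contract (header row mandatory):
#   time_s, paw_cmh2o, flow_lps, volume_l, pmus_cmh2o, phase, breath_id,
#   effort_id
# The pmus_cmh2o column is omitted for the control-group view. Files open
# with '#'-prefixed provenance comment lines (tool version, seed, config
# hash); the data section is byte-reproducible for identical inputs.

WAVEFORM_COLS <- c("time_s", "paw_cmh2o", "flow_lps", "volume_l",
                   "pmus_cmh2o", "phase", "breath_id", "effort_id")

provenance_header <- function(seed = NA, extra = character(0)) {
  c(sprintf("# pvsim %s", as.character(utils::packageVersion("pvsim"))),
    sprintf("# seed: %s", seed),
    extra)
}

#' Write a waveform record to CSV
#'
#' @param signals a `breath_signals` record.
#' @param path output file.
#' @param include_pmus include the gold Pmus column (`FALSE` emits the
#'   control-group view).
#' @param digits significant digits for numeric channels (default 8, which
#'   round-trips every channel within 1e-6).
#' @return `path`, invisibly.
#' @export
write_waveform <- function(signals, path, include_pmus = TRUE, digits = 8) {
  stopifnot(inherits(signals, "breath_signals"))
  df <- data.frame(
    time_s = signif(signals$time, digits),
    paw_cmh2o = signif(signals$paw, digits),
    flow_lps = signif(signals$flow, digits),
    volume_l = signif(signals$volume, digits),
    pmus_cmh2o = signif(signals$pmus_true, digits),
    phase = signals$phase, breath_id = signals$breath_id,
    effort_id = signals$effort_id
  )
  if (!include_pmus || all(is.na(signals$pmus_true))) df$pmus_cmh2o <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(
    seed = attr(signals, "seed"),
    extra = sprintf("# sampling_hz: %g | noise_sd: %g",
                    attr(signals, "sampling_hz"), attr(signals, "noise_sd"))
  ), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a waveform record from CSV
#'
#' Validates the header against the column contract and rejects non-monotone
#' time with the offending line number. A file without the Pmus column yields
#' a record with Pmus marked absent.
#'
#' @param path CSV file as written by [write_waveform()].
#' @return a `breath_signals` record.
#' @export
read_waveform <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- setdiff(WAVEFORM_COLS, "pmus_cmh2o")
  if (!all(need %in% names(df))) {
    stop("malformed waveform header: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    stop("time_s not strictly increasing at data line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "))
  }
  # re-derive the sampling rate from the full span (robust to 6-digit
  # rounding of individual time stamps)
  hz <- (nrow(df) - 1L) / (df$time_s[nrow(df)] - df$time_s[1L])
  breath_signals(
    time = (seq_len(nrow(df)) - 1L) / hz + df$time_s[1L],
    paw = df$paw_cmh2o, flow = df$flow_lps, volume = df$volume_l,
    pmus_true = if ("pmus_cmh2o" %in% names(df)) df$pmus_cmh2o else NULL,
    phase = df$phase, breath_id = df$breath_id, effort_id = df$effort_id,
    sampling_hz = hz, noise_sd = NA_real_, validate = FALSE
  )
}

#' Write a breath-event log to CSV
#'
#' @param events a `breath_events` table.
#' @param path output file.
#' @param seed seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  utils::write.csv(as.data.frame(events), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a breath-event log from CSV
#'
#' @param path file as written by [write_events()].
#' @return a `breath_events` table.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  breath_events(df$trigger_time, df$cycleoff_time, df$trigger_kind,
                df$breath_id)
}

#' Write the full battery to a directory
#'
#' Renders all scenarios and writes, per scenario, the waveform CSV with the
#' Pmus column (`scenario_NN_pmus.csv`), the control-group view without it
#' (`scenario_NN_control.csv`), the event log (`scenario_NN_events.csv`) and
#' the effort-onset markers; plus `manifest.yaml` (composition) and
#' `answerkey.csv`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed render seed.
#' @param battery list of scenarios (default battery if omitted).
#' @param noise_sd render noise override (`NULL` = per-scenario default).
#' @return invisibly, the answer-key data.frame.
#' @export
write_battery <- function(out_dir, seed = 1L,
                          battery = build_default_battery(), noise_sd = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (b in battery) {
    r <- render_scenario(b, seed = seed, noise_sd = noise_sd)
    stem <- file.path(out_dir, sprintf("scenario_%02d", b$scenario_id))
    write_waveform(r$signals, paste0(stem, "_pmus.csv"), include_pmus = TRUE)
    write_waveform(r$signals, paste0(stem, "_control.csv"), include_pmus = FALSE)
    write_events(r$events, paste0(stem, "_events.csv"), seed = seed)
    utils::write.csv(as.data.frame(r$efforts_gold),
                     paste0(stem, "_effort_onsets.csv"), row.names = FALSE)
  }
  yaml::write_yaml(battery_manifest(battery),
                   file.path(out_dir, "manifest.yaml"))
  ak <- answer_key(battery)
  utils::write.csv(ak, file.path(out_dir, "answerkey.csv"), row.names = FALSE)
  invisible(ak)
}
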