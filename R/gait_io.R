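#' Construct a signal channel
#'
#' A channel is one uniformly sampled time series belonging to a gait trial:
#' a joint angle (deg), a joint moment (N·m), a ground reaction force
#' component (N), a centre-of-pressure coordinate (m), or any other scalar
#' signal.
#'
#' @param name Channel label, e.g. `"ankle_angle_r"`.
#' @param samples Numeric vector of samples at a uniform rate; length >= 2,
#'   no missing values.
#' @param kind One of `"angle"`, `"moment"`, `"grf_force"`, `"grf_cop"`,
#'   `"other"`. If `NULL`, inferred from `name` (see
#'   [infer_channel_kind()]).
#' @param units Physical unit string. If `NULL`, the conventional unit for
#'   `kind` is used (deg, N·m, N, m).
#' @return An object of class `"signal_channel"`.
#' @export
signal_channel <- function(name, samples, kind = NULL, units = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("channel '", name, "': need at least 2 samples", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("channel '", name, "': missing or non-finite samples", call. = FALSE)
  if (is.null(kind)) kind <- infer_channel_kind(name)
  kind <- match.arg(kind, c("angle", "moment", "grf_force", "grf_cop", "other"))
  if (is.null(units))
    units <- c(angle = "deg", moment = "N·m", grf_force = "N",
               grf_cop = "m", other = "")[[kind]]
  structure(list(name = name, kind = kind, units = units, samples = samples),
            class = "signal_channel")
}

#' Infer a channel's kind from its name
#'
#' Uses the naming conventions of common gait exports: names containing
#' `"angle"` are joint angles, `"moment"` or `"torque"` are joint moments,
#' `"cop"` are centre-of-pressure coordinates, and `"force"` or `"grf"` are
#' ground reaction forces; anything else is `"other"`.
#'
#' @param name Channel name.
#' @return One of `"angle"`, `"moment"`, `"grf_force"`, `"grf_cop"`,
#'   `"other"`.
#' @export
infer_channel_kind <- function(name) {
  n <- tolower(name)
  if (grepl("angle", n)) return("angle")
  if (grepl("moment|torque", n)) return("moment")
  if (grepl("cop", n)) return("grf_cop")
  if (grepl("force|grf", n)) return("grf_force")
  "other"
}

#' @export
print.signal_channel <- function(x, ...) {
  cat(sprintf("<signal_channel> %s [%s, %s], %d samples\n",
              x$name, x$kind, x$units, length(x$samples)))
  invisible(x)
}

#' Assemble a gait trial
#'
#' A gait trial is a multi-stride recording: a set of equal-length channels
#' sampled at a common uniform rate, plus trial metadata.
#'
#' @param channels List of [signal_channel()] objects (may be named; names
#'   are taken from the channels themselves).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param participant_id Participant label.
#' @param belt_speed Treadmill belt speed in m/s (optional metadata).
#' @param body_mass Body mass in kg (optional).
#' @param body_height Body height in m (optional).
#' @return An object of class `"gait_trial"` with fields `channels`
#'   (named list), `sampling_rate`, `n_samples`, `duration` (s, equal to
#'   `(n_samples - 1) / sampling_rate`), and the metadata fields.
#' @export
gait_trial <- function(channels, sampling_rate, participant_id = "P0",
                       belt_speed = NA_real_, body_mass = NA_real_,
                       body_height = NA_real_) {
  if (!length(channels)) stop("a gait trial needs at least one channel",
                              call. = FALSE)
  if (!all(vapply(channels, inherits, logical(1), "signal_channel")))
    stop("all channels must be signal_channel objects", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number", call. = FALSE)
  ns <- vapply(channels, function(ch) length(ch$samples), integer(1))
  if (length(unique(ns)) != 1L)
    stop("all channels must have equal length; got lengths ",
         paste(unique(ns), collapse = ", "), call. = FALSE)
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  structure(list(
    participant_id = participant_id,
    belt_speed = belt_speed,
    sampling_rate = sampling_rate,
    n_samples = ns[[1L]],
    duration = (ns[[1L]] - 1) / sampling_rate,
    body_mass = body_mass,
    body_height = body_height,
    channels = channels
  ), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> %s: %d channels x %d samples @ %g Hz (%.2f s)\n",
    x$participant_id, length(x$channels), x$n_samples, x$sampling_rate,
    x$duration))
  if (is.finite(x$belt_speed)) cat(sprintf("  belt speed %g m/s\n", x$belt_speed))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Time vector of a trial
#' @param trial A [gait_trial()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
trial_time <- function(trial) {
  seq(0, by = 1 / trial$sampling_rate, length.out = trial$n_samples)
}

# ---- storage dialect -------------------------------------------------------

#' Read a gait trial from a delimited storage file or CSV
#'
#' Two dialects are accepted. The primary dialect is a plain-text header
#' (`name`, `datacolumns`, `datarows`, `range`, `endheader`) followed by
#' tab-delimited numeric rows whose first column is `time`; this matches the
#' export format of common musculoskeletal tools. Files ending in `.csv`
#' with a single header row of column names (first column `time`) are
#' accepted as a second dialect.
#'
#' The sampling rate is inferred from the time column, which must be
#' strictly increasing and uniform to within 1e-6 s.
#'
#' @param path Path to the file.
#' @param participant_id,belt_speed,body_mass,body_height Optional trial
#'   metadata (the storage format carries none).
#' @return A [gait_trial()] with one channel per non-time column.
#' @seealso [write_gait_storage()]
#' @export
read_gait_storage <- function(path, participant_id = "P0",
                              belt_speed = NA_real_, body_mass = NA_real_,
                              body_height = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  name_field <- NULL
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- utils::read.csv(path, check.names = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    end <- match("endheader", trimws(lines))
    if (is.na(end))
      stop("malformed header: no 'endheader' line in ", path, call. = FALSE)
    hdr <- lines[seq_len(end - 1L)]
    get_field <- function(key) {
      m <- grep(paste0("^", key, "\\b"), trimws(hdr), value = TRUE)
      if (!length(m)) return(NA_character_)
      trimws(sub(paste0("^", key, "[ =\t]*"), "", trimws(m[[1L]])))
    }
    name_field <- get_field("name")
    ncol_decl <- suppressWarnings(as.integer(get_field("datacolumns")))
    nrow_decl <- suppressWarnings(as.integer(get_field("datarows")))
    if (is.na(ncol_decl) || is.na(nrow_decl))
      stop("malformed header: 'datacolumns'/'datarows' missing or non-numeric",
           call. = FALSE)
    body <- lines[(end + 1L):length(lines)]
    body <- body[nzchar(trimws(body))]
    col_names <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(col_names) != ncol_decl)
      stop("malformed header: declared ", ncol_decl, " columns but found ",
           length(col_names), call. = FALSE)
    tab <- utils::read.table(text = paste(body[-1L], collapse = "\n"),
                             sep = "\t", col.names = col_names,
                             check.names = FALSE)
    if (nrow(tab) != nrow_decl)
      stop("malformed header: declared ", nrow_decl, " rows but found ",
           nrow(tab), call. = FALSE)
  }
  if (ncol(tab) < 2L) stop("need a time column plus at least one channel",
                           call. = FALSE)
  if (tolower(names(tab)[[1L]]) != "time")
    stop("first column must be 'time', got '", names(tab)[[1L]], "'",
         call. = FALSE)
  bad <- which(is.na(as.matrix(tab)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("missing value at row %d, column '%s'",
                 bad[1L, 1L], names(tab)[bad[1L, 2L]]), call. = FALSE)
  tt <- tab[[1L]]
  dt <- diff(tt)
  if (any(dt <= 0)) stop("time column must be strictly increasing",
                         call. = FALSE)
  if (max(dt) - min(dt) > 1e-6)
    stop(sprintf("non-uniform time step: spread %.3g s exceeds 1e-6 s",
                 max(dt) - min(dt)), call. = FALSE)
  fs <- (length(tt) - 1) / (tt[length(tt)] - tt[1L])
  chans <- lapply(names(tab)[-1L], function(nm) signal_channel(nm, tab[[nm]]))
  if (identical(participant_id, "P0") && !is.null(name_field) &&
      !is.na(name_field) && nzchar(name_field))
    participant_id <- name_field
  gait_trial(chans, sampling_rate = fs, participant_id = participant_id,
             belt_speed = belt_speed, body_mass = body_mass,
             body_height = body_height)
}

#' Write a gait trial to a delimited storage file or CSV
#'
#' Writes the dialect selected by the file extension (`.csv` gives CSV;
#' anything else gives the headered tab-delimited dialect of
#' [read_gait_storage()]). Values are written with 15 significant digits so
#' a write/read round trip preserves samples to better than 1e-12 relative,
#' and write/read/write is byte-identical.
#'
#' @param trial A valid [gait_trial()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gait_storage <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  if (!length(trial$channels))
    stop("refusing to write a trial with no channels", call. = FALSE)
  tt <- trial_time(trial)
  cols <- c(list(time = tt), lapply(trial$channels, `[[`, "samples"))
  fmt <- function(x) sprintf("%.15g", x)
  mat <- vapply(cols, fmt, character(length(tt)))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    out <- c(paste(names(cols), collapse = ","),
             apply(mat, 1L, paste, collapse = ","))
  } else {
    out <- c(paste0("name ", trial$participant_id),
             paste0("datacolumns ", length(cols)),
             paste0("datarows ", length(tt)),
             paste0("range ", fmt(tt[1L]), " ", fmt(tt[length(tt)])),
             "endheader",
             paste(names(cols), collapse = "\t"),
             apply(mat, 1L, paste, collapse = "\t"))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
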