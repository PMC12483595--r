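#' Build a multichannel recording set
#'
#' A recording set holds the differential voltage traces of one experiment:
#' one row per electrode-pair channel, with channel metadata alongside a
#' list-column of sample vectors, so the usual dplyr verbs apply. All
#' channels share one acquisition configuration (see [acquisition()]).
#'
#' Voltages are stored and processed in volts; the microvolt-order signals
#' these loggers record are therefore values around `1e-6`--`1e-3`. Missing
#' samples (logger pauses, dropped conversions) are `NA`.
#'
#' @param samples List of numeric vectors, one per channel, all the same
#'   length. `NA` marks a missing sample.
#' @param channel_id Character vector of channel names. Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param inoculated Logical vector: was a fungal spore suspension placed on
#'   this electrode pair?
#' @param treatment One of `r paste0('"', treatment_levels(), '"', collapse = ", ")`.
#' @param induction_time Seconds since recording start at which the chemical
#'   stimulus was added, or `NA` if the channel was never induced.
#' @param acq An [acquisition()] object shared by all channels.
#' @param experiment_id Free-text experiment label.
#'
#' @return A tibble of class `myco_recordings` with columns `channel_id`,
#'   `inoculated`, `treatment`, `induction_time`, `n_samples`, `samples`,
#'   and attributes `acq` and `experiment_id`.
#' @examples
#' rs <- recording_set(list(a = rnorm(100) * 1e-6, b = rnorm(100) * 1e-6),
#'                     inoculated = c(TRUE, FALSE))
#' rs
#' @export
recording_set <- function(samples,
                          channel_id = NULL,
                          inoculated = FALSE,
                          treatment = "none",
                          induction_time = NA_real_,
                          acq = acquisition(),
                          experiment_id = "experiment") {
  if (!is.list(samples)) samples <- list(samples)
  n_ch <- length(samples)
  if (is.null(channel_id)) {
    channel_id <- if (!is.null(names(samples)) && all(nzchar(names(samples)))) {
      names(samples)
    } else {
      paste0("ch", seq_len(n_ch))
    }
  }
  meta <- tibble::tibble(
    channel_id = as.character(channel_id),
    inoculated = vctrs_recycle(as.logical(inoculated), n_ch, "inoculated"),
    treatment = vctrs_recycle(as.character(treatment), n_ch, "treatment"),
    induction_time = vctrs_recycle(as.numeric(induction_time), n_ch, "induction_time"),
    n_samples = vapply(samples, length, integer(1)),
    samples = lapply(samples, as.numeric)
  )
  new_recording_set(meta, acq = acq, experiment_id = experiment_id)
}

vctrs_recycle <- function(x, n, name) {
  if (length(x) == n) return(x)
  if (length(x) == 1) return(rep(x, n))
  abort(sprintf("`%s` must have length 1 or %d.", name, n))
}

new_recording_set <- function(meta, acq, experiment_id) {
  out <- tibble::new_tibble(meta, nrow = nrow(meta), class = "myco_recordings")
  attr(out, "acq") <- validate_acquisition(acq)
  attr(out, "experiment_id") <- as.character(experiment_id)
  validate_recording_set(out)
}

validate_recording_set <- function(x) {
  stopifnot(inherits(x, "myco_recordings"))
  validate_acquisition(acq(x))
  if (nrow(x) == 0) return(x)
  bad_treat <- setdiff(unique(x$treatment), treatment_levels())
  if (length(bad_treat)) {
    abort(sprintf("unknown treatment label(s): %s", paste(bad_treat, collapse = ", ")))
  }
  lens <- vapply(x$samples, length, integer(1))
  if (any(lens != x$n_samples)) {
    abort("`n_samples` disagrees with the stored sample vectors.")
  }
  if (length(unique(lens)) > 1) {
    abort(sprintf(
      "channels have inconsistent lengths: %s",
      paste(sprintf("%s=%d", x$channel_id, lens), collapse = ", ")
    ))
  }
  span <- lens[1] / sampling_rate(x)
  it <- x$induction_time
  if (any(!is.na(it) & (it < 0 | it > span))) {
    bad <- x$channel_id[!is.na(it) & (it < 0 | it > span)]
    abort(sprintf(
      "induction_time outside the recording span [0, %.6g] s for channel(s): %s",
      span, paste(bad, collapse = ", ")
    ))
  }
  vmax <- suppressWarnings(max(vapply(
    x$samples, function(s) if (all(is.na(s))) -Inf else max(abs(s), na.rm = TRUE),
    numeric(1)
  )))
  if (is.finite(vmax) && vmax >= 1) {
    warn(sprintf(
      "implausibly large voltages (max |v| = %.3g V >= 1 V); expected microvolt-order signals",
      vmax
    ))
  }
  x
}

#' Acquisition metadata accessors
#'
#' @param x A `myco_recordings` tibble.
#' @return `acq()` returns the shared [acquisition()] object;
#'   `sampling_rate()` its rate in Hz; `experiment_id()` the experiment
#'   label; `recording_span()` the channel duration in seconds.
#' @export
acq <- function(x) attr(x, "acq")

#' @rdname acq
#' @export
sampling_rate <- function(x) acq(x)$sampling_rate

#' @rdname acq
#' @export
experiment_id <- function(x) attr(x, "experiment_id")

#' @rdname acq
#' @export
recording_span <- function(x) {
  if (nrow(x) == 0) return(0)
  length(x$samples[[1]]) / sampling_rate(x)
}

#' @export
print.myco_recordings <- function(x, ...) {
  cat(sprintf(
    "# Recording set '%s': %d channel(s), %.6g Hz (conversion time %.4g s), %.4g s span\n",
    experiment_id(x), nrow(x), sampling_rate(x), acq(x)$conversion_time,
    recording_span(x)
  ))
  NextMethod()
}

# ---- plain-text recording format ------------------------------------------

# Layout: '#'-prefixed metadata header, then one comma-separated column per
# channel; empty cells are missing samples. Values round-trip at 9
# significant digits.

#' Read or write a recording set in the documented plain-text layout
#'
#' The on-disk layout is a comment-prefixed metadata header followed by one
#' comma-separated column per channel:
#'
#' ```
#' # mycovolt-recordings v1
#' # experiment_id: plate3
#' # conversion_time: 0.06
#' # start_time: 0
#' # channel: id=ch1 inoculated=TRUE treatment=none induction_time=604800
#' ch1
#' 1.2e-05
#'
#' -3.4e-06
#' ```
#'
#' An empty cell is a missing sample. The sampling rate is always derived
#' from the stored conversion time on read. Finite values survive a
#' round-trip to 9 significant digits.
#'
#' @param path File path.
#' @param format Only `"csv"` is supported; the vendor HDF5 export this
#'   layout mirrors has no installed R reader.
#' @param set A `myco_recordings` tibble to write.
#' @return `read_recording_set()` returns a `myco_recordings` tibble;
#'   `write_recording_set()` returns `path` invisibly.
#' @examples
#' rs <- recording_set(list(rnorm(5) * 1e-6))
#' f <- tempfile(fileext = ".csv")
#' write_recording_set(rs, f)
#' read_recording_set(f)
#' @export
read_recording_set <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    abort("format = \"hdf5\" is not supported in this build; use the csv layout.")
  }
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  header <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con)
  on.exit(NULL)

  get_field <- function(key, required = TRUE) {
    pat <- paste0("^#\\s*", key, ":\\s*(.*)$")
    hit <- grep(pat, header, value = TRUE)
    if (!length(hit)) {
      if (required) abort(sprintf("malformed recording file: missing header field '%s'", key))
      return(NA_character_)
    }
    trimws(sub(pat, "\\1", hit[1]))
  }
  if (!length(grep("^#\\s*mycovolt-recordings", header))) {
    abort("malformed recording file: missing 'mycovolt-recordings' signature line")
  }
  exp_id <- get_field("experiment_id")
  conv <- as.numeric(get_field("conversion_time"))
  if (!is.finite(conv) || conv <= 0) {
    abort("malformed recording file: field 'conversion_time' is not a positive number")
  }
  start <- as.numeric(get_field("start_time"))

  ch_lines <- grep("^#\\s*channel:", header, value = TRUE)
  parse_kv <- function(line, key) {
    m <- regmatches(line, regexpr(paste0(key, "=\\S+"), line))
    if (!length(m)) abort(sprintf(
      "malformed recording file: channel line lacks '%s': %s", key, line
    ))
    sub(paste0(key, "="), "", m)
  }
  meta <- tibble::tibble(
    channel_id = vapply(ch_lines, parse_kv, character(1), key = "id", USE.NAMES = FALSE),
    inoculated = as.logical(vapply(ch_lines, parse_kv, character(1),
                                   key = "inoculated", USE.NAMES = FALSE)),
    treatment = vapply(ch_lines, parse_kv, character(1),
                       key = "treatment", USE.NAMES = FALSE),
    induction_time = suppressWarnings(as.numeric(
      vapply(ch_lines, parse_kv, character(1), key = "induction_time", USE.NAMES = FALSE)
    ))
  )

  if (nrow(meta) == 0) {
    return(new_recording_set(
      tibble::tibble(
        channel_id = character(), inoculated = logical(), treatment = character(),
        induction_time = numeric(), n_samples = integer(), samples = list()
      ),
      acq = acquisition(conv, start), experiment_id = exp_id
    ))
  }
  dat <- readr::read_csv(
    path, comment = "#", col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  if (!setequal(names(dat), meta$channel_id)) {
    abort(sprintf(
      "malformed recording file: data columns (%s) do not match channel header lines (%s)",
      paste(names(dat), collapse = ", "), paste(meta$channel_id, collapse = ", ")
    ))
  }
  meta$samples <- lapply(meta$channel_id, function(id) as.numeric(dat[[id]]))
  meta$n_samples <- vapply(meta$samples, length, integer(1))
  meta <- meta[, c("channel_id", "inoculated", "treatment", "induction_time",
                   "n_samples", "samples")]
  new_recording_set(meta, acq = acquisition(conv, start), experiment_id = exp_id)
}

#' @rdname read_recording_set
#' @export
write_recording_set <- function(set, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    abort("format = \"hdf5\" is not supported in this build; use the csv layout.")
  }
  validate_recording_set(set)
  a <- acq(set)
  fmt_num <- function(x) {
    out <- sprintf("%.9g", x)
    out[is.na(x)] <- ""
    out
  }
  header <- c(
    "# mycovolt-recordings v1",
    sprintf("# experiment_id: %s", experiment_id(set)),
    sprintf("# conversion_time: %s", sprintf("%.12g", a$conversion_time)),
    sprintf("# start_time: %s", sprintf("%.12g", a$start_time)),
    sprintf(
      "# channel: id=%s inoculated=%s treatment=%s induction_time=%s",
      set$channel_id, set$inoculated, set$treatment,
      ifelse(is.na(set$induction_time), "NA",
             sprintf("%.12g", set$induction_time))
    )
  )
  lines <- header
  if (nrow(set) > 0) {
    cols <- lapply(set$samples, fmt_num)
    body <- do.call(paste, c(cols, sep = ","))
    lines <- c(lines, paste(set$channel_id, collapse = ","), body)
  }
  writeLines(lines, path)
  invisible(path)
}
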