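#' Construct an EEG session object
#'
#' An `eeg_session` bundles a sampled multichannel signal with its sampling
#' rate and a cue-event track. Sample indices are 0-based and intervals are
#' half-open `[onset, onset + duration)`; events must tile the recording
#' exactly, so every sample carries exactly one class label (0 = waiting,
#' 1 = left, 2 = right).
#'
#' @param data Numeric matrix, samples x channels, with channel names as
#'   column names.
#' @param sample_rate Sampling rate in Hz.
#' @param events `data.frame` with columns `label`, `onset_sample`,
#'   `duration_samples` (0-based onsets, lengths in samples).
#' @return An object of class `"eeg_session"` with fields `data`,
#'   `sample_rate`, `channel_names`, `events`.
#' @export
eeg_session <- function(data, sample_rate, events) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L) {
    stop("session data must be a non-empty numeric matrix", call. = FALSE)
  }
  ch <- colnames(data)
  if (is.null(ch) || anyNA(ch) || any(ch == "")) {
    stop("session data must have channel names as column names",
         call. = FALSE)
  }
  if (anyDuplicated(ch)) {
    stop("duplicate channel name: ", ch[duplicated(ch)][1L], call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate <= 0) {
    stop("sample_rate must be a positive number (Hz)", call. = FALSE)
  }
  events <- validate_events(events, nrow(data))
  structure(
    list(data = data, sample_rate = sample_rate, channel_names = ch,
         events = events),
    class = "eeg_session"
  )
}

validate_events <- function(events, n_samples) {
  req <- c("label", "onset_sample", "duration_samples")
  if (!is.data.frame(events) || !all(req %in% names(events))) {
    stop("events must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  events <- events[req]
  events$label <- as.integer(events$label)
  events$onset_sample <- as.integer(events$onset_sample)
  events$duration_samples <- as.integer(events$duration_samples)
  if (anyNA(events)) stop("events contain missing values", call. = FALSE)
  if (!all(events$label %in% 0:2)) {
    stop("event labels must be 0 (waiting), 1 (left) or 2 (right)",
         call. = FALSE)
  }
  if (any(events$duration_samples <= 0L)) {
    stop("event durations must be positive", call. = FALSE)
  }
  o <- order(events$onset_sample)
  events <- events[o, , drop = FALSE]
  ends <- events$onset_sample + events$duration_samples
  starts <- events$onset_sample
  if (starts[1L] != 0L) {
    stop("events must start at sample 0 (first onset is ", starts[1L], ")",
         call. = FALSE)
  }
  if (nrow(events) > 1L) {
    gap <- starts[-1L] - ends[-nrow(events)]
    bad <- which(gap != 0L)
    if (length(bad)) {
      what <- if (gap[bad[1L]] < 0L) "overlaps" else "leaves a gap before"
      stop(sprintf("event row %d (onset %d) %s the previous event",
                   bad[1L] + 1L, starts[bad[1L] + 1L], what), call. = FALSE)
    }
  }
  if (ends[nrow(events)] != n_samples) {
    stop(sprintf(
      "events cover %d samples but the recording has %d",
      ends[nrow(events)], n_samples), call. = FALSE)
  }
  rownames(events) <- NULL
  events
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("eeg_session: %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate))
  cat("channels:", paste(x$channel_names, collapse = " "), "\n")
  tab <- table(factor(session_labels(x), levels = 0:2))
  cat(sprintf("events: %d | samples per class: 0=%d 1=%d 2=%d\n",
              nrow(x$events), tab[["0"]], tab[["1"]], tab[["2"]]))
  invisible(x)
}

#' Per-sample class labels of a session
#'
#' Expands the event track into one label per sample.
#'
#' @param session An [eeg_session()].
#' @return Integer vector of length `nrow(session$data)` with values in
#'   0, 1, 2.
#' @export
session_labels <- function(session) {
  stopifnot(inherits(session, "eeg_session"))
  rep.int(session$events$label, session$events$duration_samples)
}

#' Standard channel blocks
#'
#' The ten 4-channel blocks used to form quaternions from the eight
#' recorded channels. The first channel of a block feeds the scalar
#' component of the quaternion; the remaining three feed the imaginary
#' components. Blocks 5 and 6 are identical as printed in the source
#' protocol; the duplication is reproduced verbatim rather than silently
#' altered (user-defined blocks can be supplied anywhere a block id is
#' accepted).
#'
#' @return A `data.frame` with columns `block_id`, `ch1` (scalar channel),
#'   `ch2`, `ch3`, `ch4`, ten rows.
#' @export
standard_blocks <- function() {
  data.frame(
    block_id = 1:10,
    ch1 = c("FC5", "FC5", "FC6", "FC6", "F3", "F3", "F4", "F4", "T7", "T7"),
    ch2 = c("FC6", "FC6", "FC5", "FC5", "F4", "F4", "F3", "F3", "T8", "T8"),
    ch3 = c("P7", "T7", "P7", "T7", "FC5", "FC5", "FC5", "T7", "FC5", "P7"),
    ch4 = c("P8", "T8", "P8", "T8", "FC6", "FC6", "FC6", "T8", "FC6", "P8"),
    stringsAsFactors = FALSE
  )
}

# Resolve a block argument: an id into standard_blocks(), or a character
# vector of four channel names (first = scalar channel).
resolve_block <- function(block) {
  if (is.numeric(block) && length(block) == 1L) {
    tab <- standard_blocks()
    if (!block %in% tab$block_id) {
      stop("unknown block id ", block, " (standard blocks are 1..10)",
           call. = FALSE)
    }
    row <- tab[tab$block_id == block, ]
    return(structure(c(row$ch1, row$ch2, row$ch3, row$ch4),
                     block_id = as.integer(block)))
  }
  block <- as.character(block)
  if (length(block) != 4L || anyDuplicated(block)) {
    stop("a channel block is an ordered set of 4 distinct channel names",
         call. = FALSE)
  }
  structure(block, block_id = NA_integer_)
}

#' Segment a session on class changes
#'
#' Splits the recording into maximal runs of constant class label, in
#' temporal order. Under the default cue protocol this yields one segment
#' per cue and one per rest period.
#'
#' @param session An [eeg_session()].
#' @return A `data.frame` with columns `segment_id`, `label`,
#'   `start_sample` (0-based), `length` (samples). Segments are contiguous,
#'   non-overlapping, and cover the session.
#' @export
segment_session <- function(session) {
  lab <- session_labels(session)
  if (length(lab) == 0L) stop("empty session", call. = FALSE)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  data.frame(
    segment_id = seq_along(r$values),
    label = r$values,
    start_sample = ends - r$lengths,
    length = r$lengths
  )
}

#' Write a session to CSV
#'
#' The canonical on-disk format is a pair of plain CSV files: the signal
#' file has a one-line metadata header `# sample_rate=<Hz>`, then a header
#' row of channel names and one row per sample; the events sidecar has
#' columns `label,onset_sample,duration_samples`. Values are printed with
#' 17 significant digits so that a write/read round trip is bit-exact for
#' finite doubles.
#'
#' @param session An [eeg_session()].
#' @param path Path of the signal CSV.
#' @param events_path Path of the events sidecar; default replaces the
#'   `.csv` suffix of `path` with `.events.csv`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, events_path = NULL) {
  stopifnot(inherits(session, "eeg_session"))
  if (is.null(events_path)) events_path <- default_events_path(path)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# sample_rate=%.17g", session$sample_rate), con)
  writeLines(paste(session$channel_names, collapse = ","), con)
  cols <- lapply(seq_len(ncol(session$data)),
                 function(j) sprintf("%.17g", session$data[, j]))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  ev <- session$events
  ev_lines <- c("label,onset_sample,duration_samples",
                sprintf("%d,%d,%d", ev$label, ev$onset_sample,
                        ev$duration_samples))
  con2 <- file(events_path, open = "wb")
  on.exit(close(con2), add = TRUE)
  writeLines(ev_lines, con2)
  invisible(path)
}

default_events_path <- function(path) {
  sub("\\.csv$", ".events.csv", path)
}

#' Read a session from CSV
#'
#' Counterpart of [write_session()]; validates the event track (coverage,
#' no overlaps) and channel names (present, unique) on load.
#'
#' @param path Path of the signal CSV.
#' @param events_path Path of the events sidecar; default as in
#'   [write_session()].
#' @return An [eeg_session()].
#' @export
read_session <- function(path, events_path = NULL) {
  if (is.null(events_path)) events_path <- default_events_path(path)
  lines <- readLines(path, n = 1L)
  if (!grepl("^# sample_rate=", lines[1L])) {
    stop("missing '# sample_rate=' metadata line in ", path, call. = FALSE)
  }
  sample_rate <- as.numeric(sub("^# sample_rate=", "", lines[1L]))
  dat <- utils::read.csv(path, skip = 1L, check.names = FALSE,
                         colClasses = "numeric")
  if (anyNA(dat)) {
    bad <- which(!stats::complete.cases(dat))[1L]
    stop("non-numeric or missing value at data row ", bad, " of ", path,
         call. = FALSE)
  }
  ev <- utils::read.csv(events_path)
  eeg_session(as.matrix(dat), sample_rate, ev)
}
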