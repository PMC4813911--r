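#' Cue-protocol specification
#'
#' Describes the visual-cue acquisition protocol emulated by the simulator:
#' directional cues (left/right arrows) shown alternately, each followed by
#' a rest period. The defaults reproduce the reference protocol: 40 cues of
#' 10 s alternating left/right starting with left, a 5 s rest after every
#' cue, 128 Hz sampling and the eight motor/frontal channels FC5, FC6, P7,
#' P8, T7, T8, F3, F4 — a 600 s session of 76,800 samples per channel.
#'
#' @param cue_duration Duration of each directional cue, seconds.
#' @param rest_duration Duration of the rest after each cue, seconds.
#' @param n_cues Number of directional cues.
#' @param sample_rate Sampling rate in Hz.
#' @param channels Ordered channel names (10-20 montage labels).
#' @return An object of class `"protocol_spec"`.
#' @export
protocol_spec <- function(cue_duration = 10, rest_duration = 5, n_cues = 40,
                          sample_rate = 128,
                          channels = c("FC5", "FC6", "P7", "P8",
                                       "T7", "T8", "F3", "F4")) {
  if (cue_duration <= 0 || rest_duration <= 0 || n_cues < 1 ||
      sample_rate <= 0) {
    stop("protocol durations, cue count and sample rate must be positive",
         call. = FALSE)
  }
  channels <- as.character(channels)
  if (anyDuplicated(channels)) {
    stop("duplicate channel name in protocol", call. = FALSE)
  }
  cue_samples <- round(cue_duration * sample_rate)
  rest_samples <- round(rest_duration * sample_rate)
  if (cue_samples < 1 || rest_samples < 1) {
    stop("cue and rest periods must span at least one sample", call. = FALSE)
  }
  structure(
    list(cue_duration = cue_duration, rest_duration = rest_duration,
         n_cues = as.integer(n_cues), sample_rate = sample_rate,
         channels = channels, cue_samples = as.integer(cue_samples),
         rest_samples = as.integer(rest_samples)),
    class = "protocol_spec"
  )
}

#' Signal model for the synthetic session generator
#'
#' Each channel is i.i.d. Gaussian baseline noise plus a mu-band sinusoid
#' with a per-channel random phase. During a directional cue the sinusoid
#' amplitude on the channels mapped to that class is multiplied by
#' `1 - erd_factor`, emulating contralateral event-related
#' desynchronization (ERD): imagining a left movement attenuates the
#' right-hemisphere channels and vice versa.
#'
#' @param baseline_sigma Noise standard deviation (signal units).
#' @param osc_freq Oscillation frequency in Hz (default 10, mu band).
#' @param osc_amp Baseline oscillation amplitude.
#' @param erd_factor Multiplicative amplitude attenuation in `[0, 1)`
#'   applied to the mapped channels during a cue; 0 means no class signal.
#' @param lateral_map Named list mapping class labels (`"1"`, `"2"`) to the
#'   character vector of attenuated channels. The default attenuates the
#'   right-hemisphere channels (FC6, P8, T8, F4) for class 1 (left) and the
#'   left-hemisphere channels (FC5, P7, T7, F3) for class 2 (right).
#' @param seed RNG seed for phases and noise.
#' @return An object of class `"signal_model"`.
#' @export
signal_model <- function(baseline_sigma = 0.1, osc_freq = 10, osc_amp = 1,
                         erd_factor = 0.8,
                         lateral_map = list(
                           "1" = c("FC6", "P8", "T8", "F4"),
                           "2" = c("FC5", "P7", "T7", "F3")),
                         seed = 1L) {
  if (baseline_sigma < 0 || osc_amp < 0) {
    stop("baseline_sigma and osc_amp must be nonnegative", call. = FALSE)
  }
  if (erd_factor < 0 || erd_factor >= 1) {
    stop("erd_factor must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(baseline_sigma = baseline_sigma, osc_freq = osc_freq,
         osc_amp = osc_amp, erd_factor = erd_factor,
         lateral_map = lateral_map, seed = as.integer(seed)),
    class = "signal_model"
  )
}

#' Per-sample label track of a protocol
#'
#' Deterministic expansion of the cue protocol into one class label per
#' sample: cues alternate 1, 2, 1, 2, ... starting with left (1), and every
#' cue — including the last — is followed by a rest (0) period, so the
#' default protocol spans exactly `n_cues * (cue + rest)` seconds.
#'
#' @param protocol A [protocol_spec()].
#' @return Integer vector of labels in 0, 1, 2; one per sample.
#' @export
label_track <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  ev <- protocol_events(protocol)
  rep.int(ev$label, ev$duration_samples)
}

# Event table implied by a protocol: cue, rest, cue, rest, ...
protocol_events <- function(protocol) {
  cue_labels <- rep_len(c(1L, 2L), protocol$n_cues)
  labels <- as.vector(rbind(cue_labels, 0L))
  durs <- rep.int(c(protocol$cue_samples, protocol$rest_samples),
                  protocol$n_cues)
  onsets <- cumsum(c(0L, durs[-length(durs)]))
  data.frame(label = labels, onset_sample = onsets,
             duration_samples = durs)
}

#' Generate a synthetic EEG session
#'
#' Simulates a cue-based motor-imagery session under `protocol` and
#' `model`: per-channel mu-band sinusoids with seeded random phases, i.i.d.
#' Gaussian noise, and class-dependent lateralized amplitude attenuation
#' (ERD) during cues. The same seed always yields the identical session.
#'
#' @param protocol A [protocol_spec()].
#' @param model A [signal_model()].
#' @return An [eeg_session()] whose event track matches [label_track()].
#' @export
generate_session <- function(protocol = protocol_spec(),
                             model = signal_model()) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(model, "signal_model"))
  for (cls in names(model$lateral_map)) {
    unknown <- setdiff(model$lateral_map[[cls]], protocol$channels)
    if (length(unknown)) {
      stop("lateral_map class ", cls, " names unknown channel(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  ev <- protocol_events(protocol)
  labels <- rep.int(ev$label, ev$duration_samples)
  n <- length(labels)
  nch <- length(protocol$channels)
  tt <- (seq_len(n) - 1L) / protocol$sample_rate

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(model$seed)
  phases <- stats::runif(nch, 0, 2 * pi)
  noise <- matrix(stats::rnorm(n * nch, sd = model$baseline_sigma), n, nch)

  data <- matrix(0, n, nch, dimnames = list(NULL, protocol$channels))
  for (j in seq_len(nch)) {
    amp <- rep(model$osc_amp, n)
    for (cls in names(model$lateral_map)) {
      if (protocol$channels[j] %in% model$lateral_map[[cls]]) {
        amp[labels == as.integer(cls)] <-
          model$osc_amp * (1 - model$erd_factor)
      }
    }
    data[, j] <- amp * sin(2 * pi * model$osc_freq * tt + phases[j]) +
      noise[, j]
  }
  eeg_session(data, protocol$sample_rate, ev)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
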