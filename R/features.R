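#' QSA pipeline configuration
#'
#' Tunable parameters of the quaternion-based signal analysis pipeline.
#'
#' @param dt Lag in samples between the quaternion stream q(t) and the pure
#'   stream r(t) = vec(q(t - dt)) that it rotates; integer >= 1. The
#'   reference analysis sweeps 1..10 (multiples of the 1/128 s sample
#'   period).
#' @param rotation_mode `"inverse"` (sandwich product q r q^-1, default) or
#'   `"conjugate"` (q r conj(q), which scales by `||q||^2`).
#' @param features Ordered feature names drawn from `"mean"`, `"variance"`,
#'   `"contrast"`, `"homogeneity"`, `"cluster_shade"`,
#'   `"cluster_prominence"`. The default is the four-feature set (mean,
#'   variance, contrast, homogeneity) in the canonical column order.
#' @param boundary `"drop_prefix"` (default: the rotated stream is
#'   undefined for t < dt and those samples are dropped, affecting only the
#'   first segment) or `"zero_pad"` (t < dt yields the zero vector).
#' @param pure_q If `TRUE`, zero the scalar channel so the stream consists
#'   of pure quaternions; by default the first block channel feeds the
#'   scalar component.
#' @return An object of class `"qsa_config"`.
#' @export
qsa_config <- function(dt = 1L,
                       rotation_mode = c("inverse", "conjugate"),
                       features = c("mean", "variance", "contrast",
                                    "homogeneity"),
                       boundary = c("drop_prefix", "zero_pad"),
                       pure_q = FALSE) {
  rotation_mode <- match.arg(rotation_mode)
  boundary <- match.arg(boundary)
  dt <- as.integer(dt)
  if (is.na(dt) || dt < 1L) stop("dt must be an integer >= 1", call. = FALSE)
  known <- names(qsa_feature_set())
  features <- as.character(features)
  if (length(features) == 0L || !all(features %in% known)) {
    stop("features must be a non-empty subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  structure(
    list(dt = dt, rotation_mode = rotation_mode, features = features,
         boundary = boundary, pure_q = isTRUE(pure_q)),
    class = "qsa_config"
  )
}

#' Build the quaternion stream of a channel block
#'
#' Maps sample t of the session to the quaternion
#' (w, x, y, z) = (ch1, ch2, ch3, ch4)(t): the first block channel is the
#' scalar component, the remaining three the imaginary components.
#'
#' @param session An [eeg_session()].
#' @param block A block id (row of [standard_blocks()]) or a character
#'   vector of four channel names.
#' @param pure_q If `TRUE`, the scalar component is set to 0.
#' @return An n x 4 numeric matrix (columns w, x, y, z) with attributes
#'   `block` (the channel names) and `block_id`.
#' @export
build_quaternion_stream <- function(session, block, pure_q = FALSE) {
  stopifnot(inherits(session, "eeg_session"))
  block <- resolve_block(block)
  missing <- setdiff(block, session$channel_names)
  if (length(missing)) {
    stop("channel(s) not present in session: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stream <- session$data[, block, drop = FALSE]
  colnames(stream) <- c("w", "x", "y", "z")
  if (isTRUE(pure_q)) stream[, "w"] <- 0
  attr(stream, "block") <- as.character(block)
  attr(stream, "block_id") <- attr(block, "block_id")
  stream
}

#' Lagged pure-quaternion stream
#'
#' Forms r(t): the vector part (x, y, z) of the quaternion at sample
#' t - dt, with scalar part 0. Under `boundary = "drop_prefix"` the first
#' `dt` samples are undefined and returned as `NA`; under `"zero_pad"` they
#' are the zero quaternion.
#'
#' @param stream An n x 4 quaternion stream
#'   (see [build_quaternion_stream()]).
#' @param dt Lag in samples, `1 <= dt < n`.
#' @param boundary `"drop_prefix"` or `"zero_pad"`.
#' @return An n x 4 matrix of pure quaternions aligned with `stream`, with
#'   attribute `valid_from` (0-based index of the first defined sample; 0
#'   for `"zero_pad"`).
#' @export
shifted_pure_stream <- function(stream, dt,
                                boundary = c("drop_prefix", "zero_pad")) {
  boundary <- match.arg(boundary)
  dt <- as.integer(dt)
  n <- nrow(stream)
  if (dt < 1L || dt >= n) {
    stop("dt must satisfy 1 <= dt < stream length (", n, ")", call. = FALSE)
  }
  fill <- if (boundary == "drop_prefix") NA_real_ else 0
  r <- matrix(fill, n, 4L, dimnames = list(NULL, c("w", "x", "y", "z")))
  idx <- (dt + 1L):n
  r[idx, 2:4] <- stream[idx - dt, 2:4, drop = FALSE]
  r[idx, 1L] <- 0
  attr(r, "valid_from") <- if (boundary == "drop_prefix") dt else 0L
  r
}

#' Rotate a pure stream by a quaternion stream
#'
#' Applies, sample by sample, the rotation of r(t) by q(t):
#' q(t) r(t) q(t)^-1 in mode `"inverse"` (norm-preserving) or
#' q(t) r(t) conj(q(t)) in mode `"conjugate"`. Samples where
#' `||q(t)|| = 0` yield the zero quaternion and a warning reporting how
#' many were degenerate; undefined (`NA`) samples of `r` stay undefined.
#'
#' @param q_stream n x 4 quaternion stream.
#' @param r_stream n x 4 pure-quaternion stream aligned with `q_stream`.
#' @param mode `"inverse"` or `"conjugate"`.
#' @return An n x 4 matrix of rotated pure quaternions carrying the
#'   `valid_from` attribute of `r_stream`.
#' @export
rotate_stream <- function(q_stream, r_stream,
                          mode = c("inverse", "conjugate")) {
  mode <- match.arg(mode)
  if (nrow(q_stream) != nrow(r_stream)) {
    stop("q_stream and r_stream lengths differ (", nrow(q_stream), " vs ",
         nrow(r_stream), ")", call. = FALSE)
  }
  q <- as.matrix(q_stream)[, 1:4, drop = FALSE]
  r <- as.matrix(r_stream)[, 1:4, drop = FALSE]
  right <- quat_mat_conj(q)
  if (mode == "inverse") {
    n2 <- quat_mat_norm2(q)
    zero <- which(n2 == 0)
    n2[zero] <- 1  # placeholder; zero rows are overwritten below
    right <- right / n2
  } else {
    zero <- which(quat_mat_norm2(q) == 0)
  }
  out <- quat_mat_mul(quat_mat_mul(q, r), right)
  if (length(zero)) {
    defined <- zero[!is.na(r[zero, 2L])]
    out[zero, ] <- 0
    out[is.na(r[, 2L]), ] <- NA_real_
    if (length(defined)) {
      warning(length(defined), " sample(s) had a zero-norm quaternion; ",
              "their rotated output is the zero vector", call. = FALSE)
    }
  }
  colnames(out) <- c("w", "x", "y", "z")
  attr(out, "valid_from") <- attr(r_stream, "valid_from")
  out
}

#' Modulus series of a rotated stream
#'
#' The per-sample quaternion norm of the rotated stream — the nonnegative
#' scalar signal from which all QSA features are computed.
#'
#' @param rotated n x 4 matrix of (pure) quaternions.
#' @return Numeric vector of length n (NA where the input is undefined),
#'   carrying the `valid_from` attribute.
#' @export
modulus_series <- function(rotated) {
  m <- as.matrix(rotated)[, 1:4, drop = FALSE]
  out <- sqrt(m[, 1L]^2 + m[, 2L]^2 + m[, 3L]^2 + m[, 4L]^2)
  attr(out, "valid_from") <- attr(rotated, "valid_from")
  out
}

# Registry of per-segment statistical features on the modulus series.
# Mean, contrast and homogeneity follow the Haralick-style definitions
# adapted to a 1-D nonnegative series; variance is the sample variance.
qsa_feature_set <- function() {
  list(
    mean = function(x) sum(x) / length(x),
    variance = function(x) {
      if (length(x) < 2L) {
        stop("variance requires at least 2 samples", call. = FALSE)
      }
      stats::var(x)
    },
    contrast = function(x) sum(x^2) / length(x)^2,
    homogeneity = function(x) sum(1 / (1 + x^2)),
    cluster_shade = function(x) sum((x - mean(x))^3),
    cluster_prominence = function(x) sum((x - mean(x))^4)
  )
}

#' Statistical features of a modulus series
#'
#' Scalar features computed on a (segment of a) modulus series `x` of
#' length N: `feature_mean` = sum(x)/N; `feature_variance` = sample
#' variance (denominator N - 1); `feature_contrast` = sum(x^2)/N^2;
#' `feature_homogeneity` = sum(1/(1 + x^2)); `feature_cluster_shade` =
#' sum((x - mean)^3); `feature_cluster_prominence` = sum((x - mean)^4).
#'
#' @param x Non-empty numeric vector (a modulus series); the variance
#'   additionally requires N >= 2.
#' @return A single numeric value.
#' @name qsa_features
NULL

feature_wrap <- function(name) {
  f <- qsa_feature_set()[[name]]
  function(x) {
    x <- as.numeric(x)
    if (length(x) == 0L || anyNA(x)) {
      stop("feature '", name, "' requires a non-empty series without NA",
           call. = FALSE)
    }
    f(x)
  }
}

#' @rdname qsa_features
#' @export
feature_mean <- feature_wrap("mean")

#' @rdname qsa_features
#' @export
feature_variance <- feature_wrap("variance")

#' @rdname qsa_features
#' @export
feature_contrast <- feature_wrap("contrast")

#' @rdname qsa_features
#' @export
feature_homogeneity <- feature_wrap("homogeneity")

#' @rdname qsa_features
#' @export
feature_cluster_shade <- feature_wrap("cluster_shade")

#' @rdname qsa_features
#' @export
feature_cluster_prominence <- feature_wrap("cluster_prominence")

#' Extract the QSA feature matrix of a session
#'
#' Runs the full QSA chain for one channel block: builds the quaternion
#' stream, lags it by `dt` into a pure stream, rotates sample-wise,
#' takes the modulus, segments the session on class changes, and computes
#' the configured features per segment.
#'
#' @param session An [eeg_session()].
#' @param block Block id or character 4-vector (see
#'   [build_quaternion_stream()]).
#' @param config A [qsa_config()].
#' @return An object of class `"qsa_features"`: a list with `M` (segments x
#'   features numeric matrix, named columns), `labels` (integer class per
#'   segment), `segments` (the segmentation table), `block`, `config`.
#' @export
extract_features <- function(session, block, config = qsa_config()) {
  stopifnot(inherits(session, "eeg_session"),
            inherits(config, "qsa_config"))
  stream <- build_quaternion_stream(session, block, pure_q = config$pure_q)
  r <- shifted_pure_stream(stream, config$dt, config$boundary)
  rot <- rotate_stream(stream, r, config$rotation_mode)
  q_mod <- modulus_series(rot)
  segs <- segment_session(session)
  valid_from <- attr(q_mod, "valid_from")

  funs <- qsa_feature_set()[config$features]
  M <- matrix(NA_real_, nrow(segs), length(funs),
              dimnames = list(segs$segment_id, names(funs)))
  for (i in seq_len(nrow(segs))) {
    from <- max(segs$start_sample[i], valid_from)
    to <- segs$start_sample[i] + segs$length[i] - 1L
    if (from > to) {
      stop("segment ", segs$segment_id[i],
           " has no samples left after boundary trimming", call. = FALSE)
    }
    x <- q_mod[(from + 1L):(to + 1L)]
    M[i, ] <- vapply(funs, function(f) f(x), numeric(1))
  }
  structure(
    list(M = M, labels = segs$label, segments = segs,
         block = attr(stream, "block"), config = config),
    class = "qsa_features"
  )
}

#' @export
print.qsa_features <- function(x, ...) {
  cat(sprintf("qsa_features: %d segments x %d features (block %s, dt=%d, %s)\n",
              nrow(x$M), ncol(x$M), paste(x$block, collapse = "/"),
              x$config$dt, x$config$rotation_mode))
  tab <- table(factor(x$labels, levels = 0:2))
  cat(sprintf("segments per class: 0=%d 1=%d 2=%d\n",
              tab[["0"]], tab[["1"]], tab[["2"]]))
  invisible(x)
}

#' Write / read a feature matrix CSV
#'
#' Columns: `segment_id`, `label`, then one column per feature.
#'
#' @param features A `"qsa_features"` object.
#' @param path Output CSV path.
#' @return `path` invisibly (write); a `"qsa_features"` object (read; the
#'   `segments`, `block` and `config` fields are not round-tripped and are
#'   `NULL`, except `config$features` which is recovered from the header).
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "qsa_features"))
  df <- data.frame(segment_id = as.integer(rownames(features$M)),
                   label = features$labels)
  df <- cbind(df, as.data.frame(features$M))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(names(df), collapse = ","), con)
  cols <- c(list(sprintf("%d", df$segment_id), sprintf("%d", df$label)),
            lapply(df[-(1:2)], function(x) sprintf("%.17g", x)))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("segment_id", "label") %in% names(df))) {
    stop("feature CSV must have segment_id and label columns",
         call. = FALSE)
  }
  fcols <- setdiff(names(df), c("segment_id", "label"))
  M <- as.matrix(df[fcols])
  rownames(M) <- df$segment_id
  structure(
    list(M = M, labels = as.integer(df$label), segments = NULL,
         block = NULL, config = list(features = fcols)),
    class = "qsa_features"
  )
}
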