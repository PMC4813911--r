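# Independent oracles used to cross-check the implementation. These are
# deliberately written against the mathematical definitions, not the
# package's own code paths.

# 3x3 rotation matrix of a unit quaternion (w, x, y, z): the textbook
# direction-cosine form. Used to verify the sandwich-product rotation.
rotmat_from_unit_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Random quaternion with components ~ U(-1, 1); resampled if near zero.
random_quat <- function() {
  repeat {
    q <- stats::runif(4, -1, 1)
    if (sum(q^2) > 1e-4) return(q)
  }
}

# Scalar (loop-based, non-vectorized) reference of the whole QSA feature
# chain for one block: per-sample quaternion products via the package's
# scalar algebra, per-segment features from their plain-sum definitions.
naive_qsa_features <- function(session, block_channels, dt,
                               mode = "inverse") {
  dat <- session$data[, block_channels, drop = FALSE]
  n <- nrow(dat)
  labels <- rep.int(session$events$label, session$events$duration_samples)
  q_mod <- rep(NA_real_, n)
  for (t in (dt + 1):n) {
    q <- dat[t, ]
    r <- c(0, dat[t - dt, 2:4])
    rot <- if (mode == "inverse") {
      q_mul(q_mul(q, r), q_inv(q))
    } else {
      q_mul(q_mul(q, r), q_conj(q))
    }
    q_mod[t] <- sqrt(sum(unclass(rot)^2))
  }
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  M <- matrix(NA_real_, length(runs$values), 4,
              dimnames = list(NULL, c("mean", "variance", "contrast",
                                      "homogeneity")))
  for (i in seq_along(runs$values)) {
    x <- q_mod[starts[i]:ends[i]]
    x <- x[!is.na(x)]
    N <- length(x)
    mu <- sum(x) / N
    M[i, ] <- c(mu,
                sum((x - mu)^2) / (N - 1),
                sum(x^2) / N^2,
                sum(1 / (1 + x^2)))
  }
  list(M = M, labels = runs$values)
}

# Brute-force recount of classification metrics from expanded
# (true, predicted) label pairs — independent of compute_metrics().
recount_metrics <- function(cm) {
  classes <- seq_len(nrow(cm)) - 1L
  true <- integer(0); pred <- integer(0)
  for (i in seq_len(nrow(cm))) {
    for (j in seq_len(ncol(cm))) {
      true <- c(true, rep(classes[i], cm[i, j]))
      pred <- c(pred, rep(classes[j], cm[i, j]))
    }
  }
  rt <- mean(true == pred)
  per <- lapply(classes, function(d) {
    in_d <- true == d
    list(
      S = if (any(in_d)) mean(pred[in_d] == d) else NA_real_,
      Sp = if (any(!in_d)) mean((pred == true)[!in_d]) else NA_real_,
      A = if (any(pred == d)) mean(true[pred == d] == d) else NA_real_
    )
  })
  list(rt = rt, et = 1 - rt, per_class = per)
}

# Small session fixture: a few seconds, 4 channels, 3 segments.
toy_session <- function(seed = 11, sample_rate = 32) {
  set.seed(seed)
  n <- sample_rate * 4L  # 2 s cue, 1 s rest, 1 s cue
  data <- matrix(stats::rnorm(n * 4), n, 4,
                 dimnames = list(NULL, c("FC5", "FC6", "P7", "P8")))
  ev <- data.frame(label = c(1L, 0L, 2L),
                   onset_sample = c(0L, 2L * sample_rate, 3L * sample_rate),
                   duration_samples = c(2L * sample_rate, sample_rate,
                                        sample_rate))
  eeg_session(data, sample_rate, ev)
}

# Shrunk cue protocol for fast end-to-end runs.
small_protocol <- function(n_cues = 6, sample_rate = 32) {
  protocol_spec(cue_duration = 2, rest_duration = 1, n_cues = n_cues,
                sample_rate = sample_rate)
}
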