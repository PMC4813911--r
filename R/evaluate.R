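#' Train/validation split specification
#'
#' @param train_fraction Fraction of segments used for training, in (0, 1);
#'   default 0.30 (the remaining 70% validate).
#' @param repeats Number of repeated random splits; default 20.
#' @param seed Base RNG seed; the split of repeat r uses `seed + r`.
#' @param stratified Sample the training fraction within each class
#'   (default `TRUE`), guaranteeing every class is represented in training.
#' @return An object of class `"split_spec"`.
#' @export
split_spec <- function(train_fraction = 0.30, repeats = 20L, seed = 1L,
                       stratified = TRUE) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  structure(
    list(train_fraction = train_fraction, repeats = as.integer(repeats),
         seed = as.integer(seed), stratified = isTRUE(stratified)),
    class = "split_spec"
  )
}

#' Classifier specification
#'
#' Defaults mirror the reference analysis environment: `"dt"` is a CART
#' decision tree with the Gini split criterion (via \pkg{rpart});
#' `"knn"` is 1-nearest-neighbour with Euclidean distance (via
#' \pkg{class}); `"svm"` is a Gaussian-RBF support vector machine with
#' kernel scale 1 and cost 1, trained one-vs-rest as three binary machines
#' (via \pkg{e1071}) and combined by [ovr_combine()].
#'
#' @param kind One of `"dt"`, `"knn"`, `"svm"`.
#' @param ... Kind-specific hyperparameters. `"dt"`: `minsplit` (default
#'   10), `cp` (default 0, i.e. unpruned), `maxdepth` (default 30).
#'   `"knn"`: `k` (default 1). `"svm"`:
#'   `gamma` (default 1, i.e. kernel scale 1), `cost` (default 1), `scale`
#'   (default `TRUE`, standardize features before fitting).
#' @return An object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(kind = c("dt", "knn", "svm"), ...) {
  kind <- match.arg(kind)
  hp <- list(...)
  defaults <- switch(kind,
    dt = list(minsplit = 10L, cp = 0, maxdepth = 30L),
    knn = list(k = 1L),
    svm = list(gamma = 1, cost = 1, scale = TRUE)
  )
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(hp)] <- hp
  structure(list(kind = kind, hyperparams = defaults),
            class = "classifier_spec")
}

#' Stratified train/validation split of a feature matrix
#'
#' Draws a seeded, reproducible split: under stratification,
#' `round(train_fraction * n_class)` segments (at least 1, at most
#' `n_class - 1`) are sampled from each class for training; the rest
#' validate.
#'
#' @param features A `"qsa_features"` object (see [extract_features()]).
#' @param spec A [split_spec()].
#' @param repeat_index Which repeat (1-based); determines the seed.
#' @return A list with integer row indices `train` and `validation`
#'   (disjoint, covering all rows).
#' @export
qsa_split <- function(features, spec = split_spec(), repeat_index = 1L) {
  stopifnot(inherits(features, "qsa_features"),
            inherits(spec, "split_spec"))
  labels <- features$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("the feature matrix must contain at least two classes",
         call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(spec$seed + as.integer(repeat_index))
  n <- length(labels)
  if (spec$stratified) {
    train <- integer(0)
    for (cls in classes) {
      idx <- which(labels == cls)
      k <- round(spec$train_fraction * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, k))
    }
    train <- sort(train)
  } else {
    k <- min(max(round(spec$train_fraction * n), 1L), n - 1L)
    train <- sort(sample.int(n, k))
  }
  list(train = train, validation = setdiff(seq_len(n), train))
}

#' Train a classifier and evaluate a split
#'
#' Fits `clf` on the training rows and predicts both partitions; the
#' training and validation accuracies are the fractions of matching
#' labels.
#'
#' @param features A `"qsa_features"` object.
#' @param clf A [classifier_spec()] (or a kind string).
#' @param split A list with `train` and `validation` indices (see
#'   [qsa_split()]).
#' @param seed Optional seed fixing any classifier-internal randomness
#'   (e.g. nearest-neighbour tie-breaking) for exact reproducibility.
#' @return A list with `acc_train`, `acc_val`, and `confusion` (the 3x3
#'   validation confusion matrix, rows = true class, columns = predicted).
#' @export
train_eval <- function(features, clf, split, seed = NULL) {
  stopifnot(inherits(features, "qsa_features"))
  if (is.character(clf)) clf <- classifier_spec(clf)
  stopifnot(inherits(clf, "classifier_spec"))
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
  }
  M <- features$M
  y <- features$labels
  tr <- split$train
  va <- split$validation
  if (length(unique(y[tr])) < 2L) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  classes <- sort(unique(y))
  hp <- clf$hyperparams
  pred <- switch(clf$kind,
    dt = {
      df <- data.frame(M, check.names = TRUE)
      df$.y <- factor(y, levels = classes)
      fit <- rpart::rpart(.y ~ ., data = df[tr, , drop = FALSE],
                          method = "class",
                          control = rpart::rpart.control(
                            minsplit = hp$minsplit, cp = hp$cp,
                            maxdepth = hp$maxdepth, xval = 0L))
      p <- stats::predict(fit, df, type = "class")
      as.integer(as.character(p))
    },
    knn = {
      p_tr <- class::knn(M[tr, , drop = FALSE], M[tr, , drop = FALSE],
                         factor(y[tr]), k = hp$k, use.all = TRUE)
      p_va <- class::knn(M[tr, , drop = FALSE], M[va, , drop = FALSE],
                         factor(y[tr]), k = hp$k, use.all = TRUE)
      p <- integer(length(y))
      p[tr] <- as.integer(as.character(p_tr))
      p[va] <- as.integer(as.character(p_va))
      p
    },
    svm = {
      dec <- matrix(NA_real_, nrow(M), length(classes))
      for (ci in seq_along(classes)) {
        yc <- factor(ifelse(y == classes[ci], "pos", "neg"),
                     levels = c("pos", "neg"))
        fit <- e1071::svm(M[tr, , drop = FALSE], yc[tr],
                          type = "C-classification", kernel = "radial",
                          gamma = hp$gamma, cost = hp$cost,
                          scale = hp$scale)
        dv <- attr(stats::predict(fit, M, decision.values = TRUE),
                   "decision.values")
        # orient so positive means "belongs to this class"
        sgn <- if (colnames(dv)[1L] == "pos/neg") 1 else -1
        dec[, ci] <- sgn * dv[, 1L]
      }
      classes[ovr_combine(dec)]
    }
  )
  acc_train <- mean(pred[tr] == y[tr])
  acc_val <- mean(pred[va] == y[va])
  confusion <- table(
    true = factor(y[va], levels = 0:2),
    predicted = factor(pred[va], levels = 0:2)
  )
  list(acc_train = acc_train, acc_val = acc_val, confusion = confusion)
}

#' Combine one-vs-rest decision values into class predictions
#'
#' Given one decision value per class and sample (positive meaning "this
#' sample belongs to the class"), predicts the class with the largest
#' value. When exactly one machine votes positive this coincides with the
#' one-hot codeword scheme (class 0 = (1,0,0), class 1 = (0,1,0), class 2 =
#' (0,0,1)); the argmax also resolves multi-hot and zero-hot patterns.
#' Exact ties break toward the lowest class index.
#'
#' @param decision_values n x k numeric matrix, one column per class in
#'   ascending class order.
#' @return Integer vector of column indices (1-based) of the predicted
#'   class.
#' @export
ovr_combine <- function(decision_values) {
  decision_values <- as.matrix(decision_values)
  max.col(decision_values, ties.method = "first")
}

#' Per-class performance metrics of a confusion matrix
#'
#' From a square confusion matrix with rows = true class and columns =
#' predicted class, computes the recognition rate RT (fraction of correct
#' predictions) and error rate ET = 1 - RT, and for every class d:
#' sensitivity `S` (fraction of class-d samples predicted d), specificity
#' `Sp` (fraction of samples of other classes that are predicted
#' correctly), accuracy `A` (fraction of samples predicted d that are truly
#' d), false-alarm rate `FA = 1 - Sp`, and the likelihood-style quotients
#' `PP = S / (1 - Sp)` and `NP = (1 - S) / Sp`. A quotient whose
#' denominator is zero (PP when Sp = 1, NP when Sp = 0) is undefined and
#' reported as `NA` with a note in the `undefined` column, never as
#' `NaN`/`Inf`.
#'
#' @param cm Square numeric matrix or table of counts, rows = true,
#'   columns = predicted; class labels from dimnames (fallback 0, 1, ...).
#' @param weighted_lr If `TRUE`, multiply PP and NP by the class-prevalence
#'   odds n_d / (N - n_d) (off by default; the plain quotients are the
#'   documented definition).
#' @return An object of class `"qsa_metrics"`: list with `rt`, `et`,
#'   `n_total`, and `per_class` (data.frame with columns `class`, `n_true`,
#'   `S`, `Sp`, `A`, `FA`, `PP`, `NP`, `undefined`).
#' @export
compute_metrics <- function(cm, weighted_lr = FALSE) {
  cm <- as.matrix(unclass(cm))
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2L) {
    stop("confusion matrix must be square with at least two classes",
         call. = FALSE)
  }
  if (any(cm < 0)) stop("confusion counts must be nonnegative", call. = FALSE)
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)) - 1L)
  correct <- sum(diag(cm))
  rt <- correct / N
  et <- 1 - rt
  n_true <- rowSums(cm)
  n_pred <- colSums(cm)
  k <- nrow(cm)
  S <- Sp <- A <- FA <- PP <- NP <- rep(NA_real_, k)
  undefined <- character(k)
  for (d in seq_len(k)) {
    if (n_true[d] > 0) S[d] <- cm[d, d] / n_true[d]
    if (N - n_true[d] > 0) Sp[d] <- (correct - cm[d, d]) / (N - n_true[d])
    if (n_pred[d] > 0) A[d] <- cm[d, d] / n_pred[d]
    FA[d] <- 1 - Sp[d]
    notes <- character(0)
    w <- if (weighted_lr) n_true[d] / (N - n_true[d]) else 1
    if (!is.na(S[d]) && !is.na(Sp[d])) {
      if (Sp[d] < 1) PP[d] <- w * S[d] / (1 - Sp[d]) else
        notes <- c(notes, "PP undefined (Sp = 1)")
      if (Sp[d] > 0) NP[d] <- w * (1 - S[d]) / Sp[d] else
        notes <- c(notes, "NP undefined (Sp = 0)")
    }
    undefined[d] <- paste(notes, collapse = "; ")
  }
  structure(
    list(rt = rt, et = et, n_total = N,
         per_class = data.frame(class = classes, n_true = as.numeric(n_true),
                                S = S, Sp = Sp, A = A, FA = FA,
                                PP = PP, NP = NP, undefined = undefined,
                                row.names = NULL)),
    class = "qsa_metrics"
  )
}

#' @export
print.qsa_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("recognition rate RT = %.4f, error rate ET = %.4f (n = %d)\n",
              x$rt, x$et, x$n_total))
  pc <- x$per_class
  pc[3:8] <- lapply(pc[3:8], round, digits)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Run the block x dt x classifier x repeat evaluation sweep
#'
#' For every combination of session, channel block, lag `dt`, classifier
#' and repeat, extracts features and evaluates one seeded split, recording
#' training and validation accuracy. Feature extraction is shared across
#' repeats and classifiers of the same (session, block, dt) cell. Cell
#' failures are recorded in the `error` column and the sweep continues.
#'
#' @param sessions A named list of [eeg_session()] objects (a single
#'   session is wrapped automatically).
#' @param blocks Vector of block ids, or list of character 4-vectors.
#' @param dts Integer vector of lags.
#' @param classifiers Character vector of classifier kinds and/or list of
#'   [classifier_spec()] objects.
#' @param spec A [split_spec()]; `spec$seed` is the master seed and every
#'   cell derives its own split seed `master + cell_index` (recorded per
#'   row).
#' @param config Base [qsa_config()]; its `dt` field is overridden by
#'   `dts`.
#' @return A `data.frame` of class `"qsa_sweep"` with one row per
#'   (session, block, dt, classifier, repeat): columns `session`, `block`,
#'   `dt`, `classifier`, `repeat_index`, `seed`, `acc_train`, `acc_val`,
#'   `error`.
#' @export
run_sweep <- function(sessions, blocks, dts, classifiers,
                      spec = split_spec(), config = qsa_config()) {
  if (inherits(sessions, "eeg_session")) sessions <- list(session1 = sessions)
  if (is.null(names(sessions))) {
    names(sessions) <- paste0("session", seq_along(sessions))
  }
  if (!is.list(blocks)) blocks <- as.list(blocks)
  if (!is.list(classifiers)) classifiers <- as.list(classifiers)
  classifiers <- lapply(classifiers, function(cl)
    if (is.character(cl)) classifier_spec(cl) else cl)
  if (!length(blocks) || !length(dts) || !length(classifiers)) {
    stop("blocks, dts and classifiers must be non-empty", call. = FALSE)
  }
  rows <- list()
  cell <- 0L
  for (si in seq_along(sessions)) {
    for (bi in seq_along(blocks)) {
      for (dt in dts) {
        cfg <- config
        cfg$dt <- as.integer(dt)
        feats <- tryCatch(
          extract_features(sessions[[si]], blocks[[bi]], cfg),
          error = function(e) e
        )
        block_label <- if (is.numeric(blocks[[bi]])) {
          as.character(blocks[[bi]])
        } else {
          paste(blocks[[bi]], collapse = "/")
        }
        for (ci in seq_along(classifiers)) {
          for (r in seq_len(spec$repeats)) {
            cell <- cell + 1L
            seed <- spec$seed + cell
            res <- if (inherits(feats, "error")) {
              list(acc_train = NA_real_, acc_val = NA_real_,
                   err = conditionMessage(feats))
            } else {
              tryCatch({
                sp <- qsa_split(feats, split_spec(
                  train_fraction = spec$train_fraction,
                  repeats = spec$repeats, seed = seed,
                  stratified = spec$stratified), repeat_index = 0L)
                te <- train_eval(feats, classifiers[[ci]], sp, seed = seed)
                list(acc_train = te$acc_train, acc_val = te$acc_val,
                     err = NA_character_)
              }, error = function(e) {
                list(acc_train = NA_real_, acc_val = NA_real_,
                     err = conditionMessage(e))
              })
            }
            rows[[cell]] <- data.frame(
              session = names(sessions)[si], block = block_label,
              dt = as.integer(dt), classifier = classifiers[[ci]]$kind,
              repeat_index = r, seed = seed,
              acc_train = res$acc_train, acc_val = res$acc_val,
              error = res$err, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qsa_sweep", "data.frame")
  out
}

#' Aggregate a sweep
#'
#' Max/mean/min of validation accuracy grouped by the given columns — the
#' shape in which sweep results are conventionally reported (per dt, per
#' block, per session).
#'
#' @param sweep A `"qsa_sweep"` data.frame from [run_sweep()].
#' @param by Character vector of grouping columns (subset of `session`,
#'   `block`, `dt`, `classifier`).
#' @return A `data.frame` with the grouping columns and `max`, `mean`,
#'   `min` of `acc_val` (failed cells excluded).
#' @export
aggregate_sweep <- function(sweep, by = c("classifier", "dt")) {
  stopifnot(all(by %in% names(sweep)))
  ok <- sweep[!is.na(sweep$acc_val), , drop = FALSE]
  if (!nrow(ok)) stop("no successful sweep cells to aggregate", call. = FALSE)
  agg <- function(f) stats::aggregate(ok["acc_val"], ok[by], f)
  out <- agg(max)
  names(out)[names(out) == "acc_val"] <- "max"
  out$mean <- agg(mean)$acc_val
  out$min <- agg(min)$acc_val
  out[do.call(order, out[by]), , drop = FALSE]
}
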