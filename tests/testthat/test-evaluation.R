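# Synthetic feature objects with well-separated class clusters.
cluster_features <- function(n_per_class = c(20L, 10L, 10L), sep = 10,
                             seed = 1) {
  set.seed(seed)
  labs <- rep(0:2, n_per_class)
  M <- matrix(stats::rnorm(length(labs) * 4), ncol = 4,
              dimnames = list(NULL, c("mean", "variance", "contrast",
                                      "homogeneity")))
  M <- M + sep * cbind(labs == 0, labs == 1, labs == 2, labs == 0)
  structure(list(M = M, labels = labs, segments = NULL, block = NULL,
                 config = qsa_config()),
            class = "qsa_features")
}

test_that("the stratified 30/70 split has the expected per-class sizes", {
  f <- cluster_features(c(40L, 20L, 20L))
  sp <- qsa_split(f, split_spec(train_fraction = 0.30, seed = 4), 1)
  expect_length(sp$train, 24L)
  expect_length(sp$validation, 56L)
  expect_identical(sort(c(sp$train, sp$validation)), 1:80)
  tab <- table(f$labels[sp$train])
  expect_identical(unname(c(tab)), c(12L, 6L, 6L))
  # every class also remains in validation
  expect_identical(sort(unique(f$labels[sp$validation])), 0:2)
})

test_that("splits are reproducible and reject invalid fractions", {
  f <- cluster_features()
  s1 <- qsa_split(f, split_spec(seed = 7), 3)
  s2 <- qsa_split(f, split_spec(seed = 7), 3)
  s3 <- qsa_split(f, split_spec(seed = 7), 4)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_error(split_spec(train_fraction = 1.0), "strictly between")
  expect_error(split_spec(train_fraction = 0), "strictly between")
  one_class <- cluster_features()
  one_class$labels <- rep(0L, length(one_class$labels))
  expect_error(qsa_split(one_class, split_spec(), 1), "two classes")
})

test_that("all three classifiers separate well-separated clusters perfectly", {
  f <- cluster_features(c(40L, 20L, 20L), sep = 10, seed = 2)
  sp <- qsa_split(f, split_spec(seed = 11), 1)
  for (kind in c("dt", "knn", "svm")) {
    res <- train_eval(f, kind, sp, seed = 5)
    expect_identical(res$acc_val, 1)
    expect_identical(sum(diag(res$confusion)), length(sp$validation))
  }
})

test_that("train_eval is deterministic under a fixed seed", {
  f <- cluster_features(sep = 1, seed = 3)  # overlapping clusters
  sp <- qsa_split(f, split_spec(seed = 1), 1)
  for (kind in c("dt", "knn", "svm")) {
    a <- train_eval(f, kind, sp, seed = 42)
    b <- train_eval(f, kind, sp, seed = 42)
    expect_identical(a$acc_val, b$acc_val)
    expect_identical(a$confusion, b$confusion)
  }
})

test_that("shuffled labels drive validation accuracy to the class prior", {
  set.seed(8)
  f <- cluster_features(c(40L, 20L, 20L), sep = 10)
  accs <- sapply(1:20, function(r) {
    fs <- f
    fs$labels <- sample(f$labels)  # destroy any feature-label association
    sp <- qsa_split(fs, split_spec(seed = r), 1)
    train_eval(fs, "knn", sp, seed = r)$acc_val
  })
  # majority-class fraction is 0.5; permutation accuracy hovers near the
  # sum of squared class priors (0.375) -- well below separable performance
  expect_lt(mean(accs), 0.55)
  expect_gt(mean(accs), 0.2)
})

test_that("degenerate single-class training sets are rejected", {
  f <- cluster_features()
  sp <- list(train = which(f$labels == 0L)[1:5],
             validation = which(f$labels != 0L))
  expect_error(train_eval(f, "dt", sp), "degenerate")
})

test_that("one-vs-rest decision values combine by argmax with stable ties", {
  expect_identical(ovr_combine(rbind(c(2, -1, -1))), 1L)
  expect_identical(ovr_combine(rbind(c(-5, -1, -3))), 2L)
  expect_identical(ovr_combine(rbind(c(-1, -1, -1))), 1L)  # tie -> lowest
  expect_identical(ovr_combine(rbind(c(0, 3, 3))), 2L)
  # one-hot codeword agreement whenever exactly one machine is positive
  set.seed(15)
  for (rep in 1:100) {
    hot <- sample(3, 1)
    dec <- stats::runif(3, -2, -0.1)
    dec[hot] <- stats::runif(1, 0.1, 2)
    expect_identical(ovr_combine(rbind(dec)), hot)
  }
})

test_that("metrics of a perfect classifier are exact", {
  m <- compute_metrics(diag(c(5, 3, 2)))
  expect_identical(m$rt, 1)
  expect_identical(m$et, 0)
  expect_true(all(m$per_class$S == 1))
  expect_true(all(m$per_class$NP == 0))
  # Sp = 1 everywhere, so PP is flagged undefined rather than Inf
  expect_true(all(is.na(m$per_class$PP)))
  expect_true(all(grepl("PP undefined", m$per_class$undefined)))
})

test_that("metrics reproduce the hand-counted example matrix", {
  cm <- rbind(c(5, 1, 0), c(2, 6, 0), c(0, 1, 5))
  m <- compute_metrics(cm)
  ref <- recount_metrics(cm)
  expect_identical(m$rt, 16 / 20)
  expect_identical(m$per_class$S[1], 5 / 6)
  expect_identical(m$per_class$Sp[1], 11 / 14)
  expect_identical(m$per_class$A[1], 5 / 7)
  expect_identical(m$per_class$FA[1], 1 - 11 / 14)
  # and the independent pair-recount agrees on every entry
  expect_equal(m$rt, ref$rt)
  for (d in 1:3) {
    expect_equal(m$per_class$S[d], ref$per_class[[d]]$S)
    expect_equal(m$per_class$Sp[d], ref$per_class[[d]]$Sp)
    expect_equal(m$per_class$A[d], ref$per_class[[d]]$A)
  }
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(23)
  for (rep in 1:100) {
    cm <- matrix(stats::rpois(9, 5), 3, 3)
    if (sum(cm) == 0) cm[1, 1] <- 1
    m <- compute_metrics(cm)
    ref <- recount_metrics(cm)
    # RT + ET = 1 exactly
    expect_identical(m$rt + m$et, 1)
    # weighted sensitivity identity: sum_d (n_d/N) S_d = RT
    have <- !is.na(m$per_class$S)
    expect_equal(sum((m$per_class$n_true[have] / m$n_total) *
                       m$per_class$S[have]), m$rt, tolerance = 1e-12)
    # FA = 1 - Sp; S = 1 => NP = 0; agreement with the recount oracle
    expect_equal(m$per_class$FA, 1 - m$per_class$Sp)
    s1 <- which(!is.na(m$per_class$S) & m$per_class$S == 1 &
                  !is.na(m$per_class$NP))
    expect_true(all(m$per_class$NP[s1] == 0))
    expect_equal(m$rt, ref$rt)
    for (d in 1:3) {
      expect_equal(m$per_class$S[d], ref$per_class[[d]]$S)
      expect_equal(m$per_class$Sp[d], ref$per_class[[d]]$Sp)
      expect_equal(m$per_class$A[d], ref$per_class[[d]]$A)
    }
  }
  expect_error(compute_metrics(matrix(0, 3, 3)), "empty")
  expect_error(compute_metrics(matrix(1, 2, 3)), "square")
})

test_that("weighted likelihood quotients multiply by prevalence odds", {
  cm <- rbind(c(5, 1, 0), c(2, 6, 0), c(0, 1, 5))
  plain <- compute_metrics(cm)
  wt <- compute_metrics(cm, weighted_lr = TRUE)
  odds <- plain$per_class$n_true / (sum(cm) - plain$per_class$n_true)
  expect_equal(wt$per_class$PP, plain$per_class$PP * odds)
  expect_equal(wt$per_class$NP, plain$per_class$NP * odds)
})

test_that("the sweep enumerates the grid and is reproducible", {
  s <- generate_session(small_protocol(n_cues = 8),
                        signal_model(seed = 6))
  spec <- split_spec(repeats = 3, seed = 10)
  sw1 <- run_sweep(s, blocks = c(1, 2), dts = c(1, 2),
                   classifiers = "dt", spec = spec)
  expect_identical(nrow(sw1), 12L)  # 1 session x 2 blocks x 2 dts x 3 reps
  expect_true(all(is.na(sw1$error)))
  sw2 <- run_sweep(s, blocks = c(1, 2), dts = c(1, 2),
                   classifiers = "dt", spec = spec)
  expect_identical(sw1, sw2)

  agg <- aggregate_sweep(sw1, by = c("block", "dt"))
  expect_identical(nrow(agg), 4L)
  cell <- sw1[sw1$block == "1" & sw1$dt == 1L, "acc_val"]
  row <- agg[agg$block == "1" & agg$dt == 1L, ]
  expect_equal(row$mean, mean(cell))
  expect_equal(row$max, max(cell))
  expect_equal(row$min, min(cell))
})

test_that("sweep cell failures are recorded without aborting the sweep", {
  s <- generate_session(small_protocol(n_cues = 8), signal_model(seed = 6))
  sw <- run_sweep(s, blocks = list(c("FC5", "FC6", "P7", "XX")),
                  dts = 1, classifiers = "dt",
                  spec = split_spec(repeats = 2, seed = 1))
  expect_identical(nrow(sw), 2L)
  expect_true(all(grepl("XX", sw$error)))
  expect_true(all(is.na(sw$acc_val)))
})
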