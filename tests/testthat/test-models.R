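encode_for_model <- function(set, method = "zscore") {
  seqs <- encode_sequences(set)
  apply_normalizer(fit_normalizer(seqs, method), seqs)
}

test_that("analytic gradients match finite differences (both architectures)", {
  set.seed(31)
  for (arch in c("bilstm", "lstm")) {
    cfg <- model_config(architecture = arch, units1 = 4, units2 = 3,
                        dropout = c(0, 0))
    B <- 5; D <- 2
    X <- array(rnorm(B * 7 * D), dim = c(B, 7, D))
    y <- sample(1:4, B, replace = TRUE)
    Y <- matrix(0, B, 4); Y[cbind(1:B, y)] <- 1
    w <- runif(B, 0.5, 2)
    p <- audiotype:::init_network(cfg, D)
    fwd <- audiotype:::net_forward(p, cfg, X, keep_cache = TRUE)
    g <- audiotype:::net_backward(p, cfg, X, fwd, Y, w, NULL, NULL)
    fg <- audiotype:::flatten_params(g)
    loss_at <- function(p) {
      f <- audiotype:::net_forward(p, cfg, X)
      audiotype:::weighted_ce(f$P, y, w)
    }
    eps <- 1e-6
    for (nm in names(fg)) {
      path <- strsplit(nm, ".", fixed = TRUE)[[1]]
      getp <- function(pp) if (length(path) == 1) pp[[path]] else
        pp[[path[1]]][[path[2]]]
      setp <- function(pp, ii, v) {
        if (length(path) == 1) pp[[path]][ii] <- v
        else pp[[path[1]]][[path[2]]][ii] <- v
        pp
      }
      idx <- sample(length(getp(p)), min(3, length(getp(p))))
      for (ii in idx) {
        base <- getp(p)[ii]
        num <- (loss_at(setp(p, ii, base + eps)) -
                  loss_at(setp(p, ii, base - eps))) / (2 * eps)
        ana <- fg[[nm]][ii]
        expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("the network memorizes a small training set", {
  d <- generate_audiograms(generator_config(n = 50, seed = 21))
  enc <- encode_for_model(d)
  m <- train_sequence_model(enc, d$label, NULL,
                            model_config(seed = 4, max_epochs = 60,
                                         patience = 60, val_fraction = 0.1))
  pred <- predict_label(m, enc)
  expect_equal(mean(as.character(pred) == d$label), 1)
})

test_that("same seed, same data: identical models and predictions", {
  d <- generate_audiograms(generator_config(n = 80, seed = 6))
  enc <- encode_for_model(d)
  cfg <- model_config(seed = 11, max_epochs = 3)
  m1 <- train_sequence_model(enc, d$label, NULL, cfg)
  m2 <- train_sequence_model(enc, d$label, NULL, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(predict_proba(m1, enc), predict_proba(m2, enc))
})

test_that("predict_proba rows live on the simplex and are batch-invariant", {
  d <- generate_audiograms(generator_config(n = 40, seed = 8))
  enc <- encode_for_model(d)
  m <- train_sequence_model(enc, d$label, NULL,
                            model_config(seed = 2, max_epochs = 2))
  P <- predict_proba(m, enc)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  # single-sample batch equals its row in the full batch
  seqs <- encode_sequences(d)
  norm <- fit_normalizer(seqs, "zscore")
  one <- apply_normalizer(norm, subset_sequences(seqs, 5))
  full <- apply_normalizer(norm, seqs)
  expect_equal(predict_proba(m, one)[1, ], predict_proba(m, full)[5, ],
               tolerance = 1e-12)
  # duplicated inputs give identical rows
  dup <- apply_normalizer(norm, subset_sequences(seqs, c(3, 3)))
  Pd <- predict_proba(m, dup)
  expect_identical(Pd[1, ], Pd[2, ])
})

test_that("predict_proba rejects a normalization mismatch", {
  d <- generate_audiograms(generator_config(n = 40, seed = 8))
  enc <- encode_for_model(d)
  m <- train_sequence_model(enc, d$label, NULL,
                            model_config(seed = 2, max_epochs = 1))
  other <- encode_for_model(d, "minmax")
  expect_error(predict_proba(m, other), "mismatch")
  expect_error(predict_proba(m, encode_sequences(d)), "encoded_sequences")
})

test_that("argmax labelling breaks exact ties by fixed class order", {
  P <- rbind(c(0.1, 0.2, 0.3, 0.4),
             c(0.25, 0.25, 0.25, 0.25),
             c(0.25, 0.3, 0.3, 0.15))
  lab <- proba_to_label(P)
  expect_equal(as.character(lab),
               c("sensorineural", "normal", "conductive"))
})

test_that("tree: hand-computed split, entropy arithmetic and pure leaves", {
  # values (0,0,40,40), labels 2+2: split at 20, gain ratio 1
  f <- matrix(c(0, 0, 40, 40), 4, 1)
  y <- c("normal", "normal", "sensorineural", "sensorineural")
  t1 <- train_tree_baseline(f, y, tree_config(min_samples_leaf = 1))
  expect_equal(t1$root$type, "node")
  expect_equal(t1$root$threshold, 20)
  expect_equal(t1$root$gain, 1)        # 1 bit of information
  expect_equal(t1$root$gain_ratio, 1)
  expect_equal(as.character(predict_tree_label(t1, matrix(c(-5, 99), 2, 1))),
               c("normal", "sensorineural"))
  # pure labels: single leaf, perfect training accuracy
  t2 <- train_tree_baseline(matrix(rnorm(20), 10, 2), rep("mixed", 10))
  expect_equal(t2$root$type, "leaf")
  expect_equal(as.character(predict_tree_label(t2, matrix(0, 1, 2))), "mixed")
  # identical features with mixed labels: majority leaf, not an error
  t3 <- train_tree_baseline(matrix(1, 6, 1),
                            c(rep("normal", 2), rep("mixed", 4)))
  expect_equal(t3$root$type, "leaf")
  expect_equal(as.character(predict_tree_label(t3, matrix(1, 1, 1))), "mixed")
})

test_that("tree learns the diagnostic rule well on synthetic data", {
  d <- generate_audiograms(generator_config(n = 1200, seed = 13))
  feats <- flatten_features(d)
  tr <- 1:1000; te <- 1001:1200
  fit <- train_tree_baseline(feats[tr, ], d$label[tr])
  acc <- mean(as.character(predict_tree_label(fit, feats[te, ])) ==
                d$label[te])
  expect_gt(acc, 0.9)
  P <- predict_tree_proba(fit, feats[te, ])
  expect_equal(unname(rowSums(P)), rep(1, 200), tolerance = 1e-12)
})

test_that("flatten_features applies the documented sentinels", {
  s <- make_audiogram(c(NA, 15, 20, 25, 30, 35, 40), c(NA, 10, 15, 20, 25))
  f <- flatten_features(s)
  expect_equal(unname(f[1, "ac_125"]), 15)   # carried from 250 Hz
  expect_equal(unname(f[1, "bc_250"]), 15)   # paired air value (gap 0)
  expect_equal(unname(f[1, "bc_4000"]), 25)  # measured values untouched
})
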