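test_that("free-parameter counts follow the closed form for every scheme", {
  # X*7*32 + 32 + 32*7*13 + 13, independent of the head split
  closed_form <- function(X) X * 7 * 32 + 32 + 32 * 7 * 13 + 13
  for (X in c(1024L, 50L, 1074L, 100L, 20L, 23L)) {
    m <- build_residue_model(residue_model_config(X), seed = 1)
    expect_equal(count_parameters(m), closed_form(X))
  }
  # the counts printed for the six input encodings, to the nearest thousand
  expect_equal(round(closed_form(1024) / 1000), 232)  # embeddings
  expect_equal(round(closed_form(50) / 1000), 14)     # profiles
  expect_equal(round(closed_form(1074) / 1000), 244)  # profiles+embeddings
  expect_equal(round(closed_form(100) / 1000), 25)    # 3-mer vectors
  expect_equal(round(closed_form(20) / 1000), 7)      # one-hot
  expect_equal(round(closed_form(23) / 1000), 8)      # substitution scores
})

test_that("residue-model gradients match finite differences", {
  cfg <- residue_model_config(6, filters = 4, dropout = 0)
  m <- build_residue_model(cfg, seed = 2)
  set.seed(3)
  X <- matrix(rnorm(10 * 6), 10, 6)
  labels <- list(ss3 = c(sample(1:3, 8, TRUE), NA, NA),
                 ss8 = sample(1:8, 10, TRUE),
                 disorder = sample(1:2, 10, TRUE))
  denom <- c(8, 10, 10)
  lg <- protlm:::.residue_loss_grads(m$params, cfg, X, labels, NULL, denom)
  lossf <- function(params) {
    protlm:::.residue_loss_grads(params, cfg, X, labels, NULL, denom)$loss
  }
  eps <- 1e-6
  for (path in list(c("conv1", "W"), c("conv1", "b"),
                    c("conv2", "W"), c("conv2", "b"))) {
    g <- lg$grads[[path[1]]][[path[2]]]
    for (i in sample(length(g), 3)) {
      p1 <- m$params; p1[[path[1]]][[path[2]]][i] <-
        p1[[path[1]]][[path[2]]][i] + eps
      p2 <- m$params; p2[[path[1]]][[path[2]]][i] <-
        p2[[path[1]]][[path[2]]][i] - eps
      num <- (lossf(p1) - lossf(p2)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("predictions are normalized, length-preserving and local", {
  fx <- small_fixtures()
  cfg <- residue_model_config(20)
  m <- build_residue_model(cfg, seed = 4)
  for (i in 1:10) {
    f <- one_hot_encode(fx$records$sequence[i], fx$records$id[i])
    pr <- predict_residues(m, f)
    for (h in c("ss3", "ss8", "disorder")) {
      expect_equal(nrow(pr$probs[[h]]), nrow(f))
      expect_true(all(abs(rowSums(pr$probs[[h]]) - 1) < 1e-5))
    }
    expect_equal(nchar(pr$labels$ss3), nrow(f))
  }
  # receptive field is 13 residues: a change >= 7 positions away from a
  # site never changes its prediction
  s <- fx$records$sequence[1]
  s2 <- paste0(substr(s, 1, 29), "W", substr(s, 31, nchar(s)))
  stopifnot(substr(s, 30, 30) != "W")
  p1 <- predict_residues(m, one_hot_encode(s))
  p2 <- predict_residues(m, one_hot_encode(s2))
  near <- 24:36  # inside the receptive field of position 30
  far <- setdiff(seq_len(nchar(s)), near)
  expect_equal(p1$probs$ss3[far, ], p2$probs$ss3[far, ], tolerance = 1e-12)
  expect_gt(max(abs(p1$probs$ss3[30, ] - p2$probs$ss3[30, ])), 1e-9)
  # scheme mismatch is rejected
  expect_error(predict_residues(m, blosum_encode(s)), "scheme mismatch")
})

test_that("training is deterministic, masked, and beats the majority class", {
  fx <- generate_corpus(default_grammar(), n = 120, seed = 21)
  feats <- lapply(seq_len(120), function(i) {
    one_hot_encode(fx$records$sequence[i], fx$records$id[i])
  })
  names(feats) <- fx$records$id
  labels <- list(ss3 = fx$ss3, ss8 = fx$ss8, disorder = fx$disorder)
  cfg <- residue_model_config(20, batch_size = 32)
  m0 <- build_residue_model(cfg, seed = 5)
  m1 <- train_residue_model(m0, feats, labels, epochs = 6, seed = 6)
  m2 <- train_residue_model(m0, feats, labels, epochs = 6, seed = 6)
  expect_identical(m1$params, m2$params)

  # held-out accuracy beats the majority-class frequency of the generator
  fx2 <- generate_corpus(default_grammar(), n = 40, seed = 22,
                         id_prefix = "te")
  pred <- vapply(seq_len(40), function(i) {
    predict_residues(m1, one_hot_encode(fx2$records$sequence[i]))$labels$ss3
  }, "")
  q3 <- q_accuracy(pred, unname(fx2$ss3[fx2$records$id]))$value
  truth_all <- unlist(strsplit(unname(fx2$ss3), ""))
  majority <- 100 * max(table(truth_all)) / length(truth_all)
  expect_gt(q3, majority)

  # masked labels ("-") are excluded from the loss without error
  labels_masked <- labels
  labels_masked$ss3 <- vapply(labels$ss3, function(s) {
    paste0("-", substring(s, 2))
  }, "", USE.NAMES = TRUE)
  expect_error(
    train_residue_model(m0, feats[1:10], list(
      ss3 = labels_masked$ss3[1:10], ss8 = labels$ss8[1:10],
      disorder = labels$disorder[1:10]), epochs = 1, seed = 1),
    NA)
})

test_that("predictors refuse embeddings from a different checkpoint", {
  fx <- small_fixtures()
  rec <- fx$records[1:12, ]
  m1 <- small_bilm()
  m2 <- build_bilm(bilm_config("mini"), seed = 999)  # different parameters
  e1 <- embed_residues(m1, rec)
  e2 <- embed_residues(m2, rec)
  as_feats <- function(embs) {
    out <- lapply(names(embs), function(id) {
      feature_matrix(embs[[id]], id, "seqvec")
    })
    names(out) <- names(embs); out
  }
  rmod <- build_residue_model(residue_model_config(64, batch_size = 6),
                              seed = 1)
  rmod <- train_residue_model(rmod, as_feats(e1),
                              list(ss3 = fx$ss3, ss8 = fx$ss8,
                                   disorder = fx$disorder),
                              epochs = 1, seed = 2)
  expect_equal(rmod$meta$feature_hash, model_hash(m1))
  f2 <- as_feats(e2)[[1]]
  expect_error(predict_residues(rmod, f2), "checkpoint mismatch")
  f1 <- as_feats(e1)[[1]]
  expect_silent(predict_residues(rmod, f1))
})
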