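test_that("parameter counting sums leaves and counts shared groups once", {
  toy <- list(layer = list(W = matrix(0, 3, 4), b = numeric(4)))
  expect_equal(count_parameters(toy), 16L)

  cfg <- bilm_config("mini")
  m <- build_bilm(cfg, seed = 1)
  # closed-form shape sum for the mini preset, written out independently:
  # chars: (28 tokens + bow/eow/cpad) x 8; convs w=1..3 with 16 filters;
  # 1 highway on 48; projection 48 -> 32; per direction 2 LSTM layers
  # (32 x 4*64 input + 32 x 4*64 recurrent + 4*64 bias + 64 x 32 proj);
  # softmax 32 x 28 + 28.
  nf <- 48
  lstm <- 32 * 256 + 32 * 256 + 256 + 64 * 32
  expected <- (31 * 8) +
    (1 * 8 * 16 + 16) + (2 * 8 * 16 + 16) + (3 * 8 * 16 + 16) +
    2 * (nf * nf + nf) +
    (nf * 32 + 32) +
    4 * lstm +
    (32 * 28 + 28)
  expect_equal(count_parameters(m), expected)

  # sharing directions removes exactly two recurrent layers' parameters
  ms <- build_bilm(bilm_config("mini", share_directions = TRUE), seed = 1)
  expect_equal(count_parameters(m) - count_parameters(ms), 2L * lstm)
})

test_that("per-layer output dimensions match the presets", {
  expect_equal(layer_dim(bilm_config("paper")), 1024L)
  expect_equal(layer_dim(bilm_config("mini")), 64L)
})

test_that("analytic gradients match finite differences", {
  cfg <- bilm_config("mini", dropout = 0)
  m <- build_bilm(cfg, seed = 3)
  v <- cfg$vocab
  tl <- lapply(c("MKTAYIAKQR", "GLEWFAC"), function(s) tokenize(s, v) + 1L)
  ids_f <- protlm:::.direction_ids(tl, "fwd", v$pad + 1L)
  ids_b <- protlm:::.direction_ids(tl, "bwd", v$pad + 1L)
  lens <- vapply(tl, length, integer(1))
  neg <- c(4L, 7L, 9L, 15L, 20L)

  window_loss <- function(params) {
    m2 <- m; m2$params <- params
    tt <- protlm:::.token_table_forward(params$char, cfg, m$geom)
    total <- 0; n <- 0
    for (direction in c("fwd", "bwd")) {
      ids <- if (direction == "fwd") ids_f else ids_b
      st <- protlm:::.direction_states(m2, protlm:::.dir_params(m2, direction),
                                       tt$R, ids)
      Hs <- list(); ys <- integer(0)
      for (t in seq_len(ncol(ids) - 1L)) {
        vb <- which(lens >= t + 1L)
        if (!length(vb)) next
        Hs[[length(Hs) + 1L]] <- st$H2[[t]][vb, , drop = FALSE]
        ys <- c(ys, ids[vb, t + 1L])
      }
      sl <- protlm:::.sampled_softmax_loss(params$softmax,
                                           do.call(rbind, Hs), ys, neg)
      total <- total + sl$loss; n <- n + sl$n
    }
    total / n
  }

  # analytic gradient of the same quantity via the backward passes
  grad_window <- function(params) {
    m2 <- m; m2$params <- params
    tt <- protlm:::.token_table_forward(params$char, cfg, m$geom)
    P <- cfg$proj_dim
    dR <- matrix(0, nrow(tt$R), P)
    sm_g <- list(W = params$softmax$W * 0, b = params$softmax$b * 0)
    out <- list(); loss_n <- 0
    for (direction in c("fwd", "bwd")) {
      ids <- if (direction == "fwd") ids_f else ids_b
      dirp <- protlm:::.dir_params(m2, direction)
      B <- nrow(ids); Tn <- ncol(ids)
      zero <- list(h = matrix(0, B, P), c = matrix(0, B, cfg$hidden_dim))
      X1 <- lapply(seq_len(Tn - 1L), function(t) tt$R[ids[, t], , drop = FALSE])
      l1 <- protlm:::.lstm_window_forward(dirp$l1, X1, zero)
      l2 <- protlm:::.lstm_window_forward(dirp$l2, l1$H, zero)
      out2 <- mapply(`+`, l2$H, l1$H, SIMPLIFY = FALSE)
      Hs <- list(); ys <- integer(0); pos <- list()
      for (t in seq_len(Tn - 1L)) {
        vb <- which(lens >= t + 1L); if (!length(vb)) next
        Hs[[length(Hs) + 1L]] <- out2[[t]][vb, , drop = FALSE]
        ys <- c(ys, ids[vb, t + 1L])
        pos[[length(pos) + 1L]] <- cbind(vb, t)
      }
      sl <- protlm:::.sampled_softmax_loss(params$softmax,
                                           do.call(rbind, Hs), ys, neg)
      loss_n <- loss_n + sl$n
      sm_g$W <- sm_g$W + sl$grads$W; sm_g$b <- sm_g$b + sl$grads$b
      dOut <- lapply(seq_len(Tn - 1L), function(k) matrix(0, B, P))
      r0 <- 0
      for (j in seq_along(pos)) {
        pi <- pos[[j]]; nj <- nrow(pi)
        dOut[[pi[1, 2]]][pi[, 1], ] <- sl$dH[r0 + seq_len(nj), , drop = FALSE]
        r0 <- r0 + nj
      }
      bk2 <- protlm:::.lstm_window_backward(dirp$l2, l2$cache, dOut)
      d1 <- mapply(`+`, dOut, bk2$dX, SIMPLIFY = FALSE)
      bk1 <- protlm:::.lstm_window_backward(dirp$l1, l1$cache, d1)
      for (t in seq_len(Tn - 1L)) {
        agg <- rowsum(bk1$dX[[t]], group = ids[, t])
        r <- as.integer(rownames(agg))
        dR[r, ] <- dR[r, ] + agg
      }
      out[[direction]] <- list(l1 = bk1$grads, l2 = bk2$grads)
    }
    cg <- protlm:::.token_table_backward(params$char, cfg, m$geom,
                                         tt$cache, dR)
    g <- list(char = cg, fwd = out$fwd, bwd = out$bwd, softmax = sm_g)
    protlm:::.tree_map(g, function(x) x / loss_n)
  }

  g <- grad_window(m$params)
  eps <- 1e-5
  set.seed(99)
  paths <- list(c("char", "emb"), c("char", "proj", "W"),
                c("fwd", "l1", "Wx"), c("fwd", "l2", "Wp"),
                c("bwd", "l1", "Wh"), c("bwd", "l2", "b"),
                c("softmax", "W"), c("softmax", "b"))
  for (path in paths) {
    leaf_g <- g; leaf_p <- m$params
    for (k in path) { leaf_g <- leaf_g[[k]]; leaf_p <- leaf_p[[k]] }
    for (i in sample(length(leaf_p), 2)) {
      bump <- function(delta) {
        p <- m$params
        if (length(path) == 2L) p[[path[1]]][[path[2]]][i] <-
            p[[path[1]]][[path[2]]][i] + delta
        else p[[path[1]]][[path[2]]][[path[3]]][i] <-
            p[[path[1]]][[path[2]]][[path[3]]][i] + delta
        p
      }
      num <- (window_loss(bump(eps)) - window_loss(bump(-eps))) / (2 * eps)
      expect_equal(leaf_g[i], num, tolerance = 1e-4,
                   info = paste(paste(path, collapse = "$"), i))
    }
  }
})

test_that("perplexity is exact under forced output distributions", {
  cfg <- bilm_config("mini")
  m <- build_bilm(cfg, seed = 2)
  rec <- small_fixtures()$records[1:6, ]
  # uniform output over the 28 tokens -> perplexity exactly 28
  m$params$softmax$W[] <- 0
  m$params$softmax$b[] <- 0
  pp <- perplexity(m, rec)
  expect_equal(pp$forward, 28, tolerance = 1e-9)
  expect_equal(pp$backward, 28, tolerance = 1e-9)
  expect_equal(pp$mean, 28, tolerance = 1e-9)

  # forced non-uniform output: logits = log p, so the NLL is the empirical
  # cross-entropy of p against the realized targets (hand-computable)
  v <- cfg$vocab
  set.seed(8)
  p <- runif(28); p <- p / sum(p)
  m$params$softmax$b[] <- log(p)
  counts <- integer(28)
  for (s in rec$sequence) {
    tk <- tokenize(s, v) + 1L
    fwd_targets <- tk[-1L]
    bwd_targets <- rev(tk)[-1L]
    counts <- counts + tabulate(c(fwd_targets, bwd_targets), nbins = 28)
  }
  expected <- exp(-sum(counts * log(p)) / sum(counts))
  expect_equal(perplexity(m, rec)$mean, expected, tolerance = 1e-9)
})

test_that("each direction is causal", {
  m <- small_bilm()
  P <- m$config$proj_dim
  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  mod <- paste0(substr(base, 1, 20), "WWWWWWWWWWWWW")  # right-context change
  recs <- protein_records(c("a", "b"), c(base, mod))
  emb <- embed_residues(m, recs, mode = "concat")
  # concat layout: [layer0 fwd|bwd | layer1 fwd|bwd | layer2 fwd|bwd]
  fwd_cols <- c(2 * P + seq_len(P), 4 * P + seq_len(P))
  bwd_cols <- c(3 * P + seq_len(P), 5 * P + seq_len(P))
  # forward halves agree on the unchanged prefix (positions 1..20)
  expect_equal(emb[["a"]][1:20, fwd_cols], emb[["b"]][1:20, fwd_cols],
               tolerance = 1e-12)
  # and differ somewhere after the perturbation point
  expect_gt(max(abs(emb[["a"]][21:33, fwd_cols] -
                    emb[["b"]][21:33, fwd_cols])), 1e-8)

  # symmetric check for the backward direction: change the prefix
  mod2 <- paste0("WWWWWWWWWW", substr(base, 11, 33))
  recs2 <- protein_records(c("a", "b"), c(base, mod2))
  emb2 <- embed_residues(m, recs2, mode = "concat")
  expect_equal(emb2[["a"]][11:33, bwd_cols], emb2[["b"]][11:33, bwd_cols],
               tolerance = 1e-12)
})

test_that("training is reproducible and reduces training perplexity", {
  rec <- small_fixtures()$records[1:25, ]
  cfg <- bilm_config("mini")
  m0 <- build_bilm(cfg, seed = 5)
  ppl0 <- perplexity(m0, rec)$mean
  m1 <- train_bilm(m0, rec, epochs = 3, seed = 6, trace = FALSE)
  m2 <- train_bilm(m0, rec, epochs = 3, seed = 6, trace = FALSE)
  expect_identical(m1$params, m2$params)
  expect_lt(perplexity(m1, rec)$mean, ppl0)
  expect_error(train_bilm(build_bilm(bilm_config("mini", unroll = 1L),
                                     seed = 1), rec),
               "unroll")
})
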