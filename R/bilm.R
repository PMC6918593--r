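# Bidirectional language model over protein sentences.
#
# Architecture (per token): character embedding -> convolution bank
# (max-pooled over character positions, concatenated over filters) ->
# highway layer(s) -> linear projection to the per-direction word dimension
# -> two recurrent (LSTM with projection) layers -> shared sampled-softmax
# head. The forward and backward directions are trained independently on
# next-token objectives (forward conditions only on the left context,
# backward only on the right); the character encoder, highway, projection
# and softmax parameters are shared between directions while each direction
# owns its two recurrent layers. Because every word is a single amino acid,
# the character encoder collapses to a learned, context-independent table
# with one row per vocabulary token, which is computed once per step.

#' Configuration for the bidirectional language model
#'
#' Two presets are provided. \code{"paper"} is the full-scale architecture:
#' convolution windows 1--7 with filter counts (32, 32, 64, 128, 256, 512,
#' 1024), two highway layers, projection 512 per direction, recurrent
#' hidden dimension 4096, unroll 100, 20 negative samples, dropout 0.1 —
#' about 93 million free parameters, with forward+backward concatenated
#' layer outputs of dimension 1024. \code{"mini"} is a desk-scale analog
#' (windows 1--3 with 16 filters each, one highway layer, projection 32,
#' hidden 64) used for training experiments and tests.
#'
#' @param preset \code{"paper"} or \code{"mini"}.
#' @param vocab A \code{token_vocab}.
#' @param unroll Tokens per truncated-backpropagation window.
#' @param n_negative Negative samples for the sampled softmax (>= 1 and
#'   smaller than the vocabulary).
#' @param dropout Dropout rate in [0, 1), applied to recurrent-layer inputs
#'   during training only.
#' @param sampler Negative-sampling proposal for the sampled softmax:
#'   \code{"uniform"} (default; amino-acid frequencies are near-uniform) or
#'   \code{"log_uniform"} (the NLP convention for frequency-sorted
#'   vocabularies).
#' @param share_directions If TRUE the two directions share their recurrent
#'   parameters as well (halves the recurrent parameter count); default
#'   FALSE, the reference convention.
#' @return An object of class \code{bilm_config}.
#' @export
bilm_config <- function(preset = c("mini", "paper"),
                        vocab = build_vocabulary(),
                        unroll = NULL, n_negative = 20L, dropout = 0.1,
                        sampler = c("uniform", "log_uniform"),
                        share_directions = FALSE) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper") {
    list(char_dim = 16L,
         conv = list(c(1L, 32L), c(2L, 32L), c(3L, 64L), c(4L, 128L),
                     c(5L, 256L), c(6L, 512L), c(7L, 1024L)),
         n_highway = 2L, proj_dim = 512L, hidden_dim = 4096L,
         unroll = 100L)
  } else {
    list(char_dim = 8L,
         conv = list(c(1L, 16L), c(2L, 16L), c(3L, 16L)),
         n_highway = 1L, proj_dim = 32L, hidden_dim = 64L,
         unroll = 20L)
  }
  if (!is.null(unroll)) cfg$unroll <- as.integer(unroll)
  stopifnot(cfg$unroll >= 1L, n_negative >= 1L, n_negative < vocab$size,
            dropout >= 0, dropout < 1)
  cfg$n_layers <- 2L
  cfg$n_negative <- as.integer(n_negative)
  cfg$sampler <- match.arg(sampler)
  cfg$dropout <- dropout
  cfg$share_directions <- isTRUE(share_directions)
  cfg$preset <- preset
  cfg$vocab <- vocab
  cfg$n_filters <- sum(vapply(cfg$conv, `[`, integer(1), 2L))
  cfg$char_width <- max(3L, max(vapply(cfg$conv, `[`, integer(1), 1L)))
  structure(cfg, class = "bilm_config")
}

#' Per-layer embedding dimension of a biLM
#'
#' Forward and backward halves concatenated: twice the projection dim
#' (1024 for the paper preset).
#'
#' @param x A \code{bilm_config} or \code{bilm}.
#' @return Integer dimension.
#' @export
layer_dim <- function(x) {
  if (inherits(x, "bilm")) x <- x$config
  2L * x$proj_dim
}

# character geometry: each token is rendered as
# [<bow>, token symbol, <eow>, <cpad>...] up to char_width characters.
.char_geometry <- function(cfg) {
  V <- cfg$vocab$size
  n_char <- V + 3L  # one char per token symbol + bow/eow/cpad
  bow <- V + 1L; eow <- V + 2L; cpad <- V + 3L
  ids <- matrix(cpad, V, cfg$char_width)
  ids[, 1L] <- bow
  ids[, 2L] <- seq_len(V)  # the token's own symbol
  ids[, 3L] <- eow
  list(n_char = n_char, ids = ids)
}

#' Build a bidirectional language model
#'
#' All parameters are initialized deterministically from \code{seed}.
#'
#' @param config A \code{bilm_config}.
#' @param seed Integer seed.
#' @return An object of class \code{bilm}: list with \code{config},
#'   \code{params} (named parameter groups), and \code{meta}
#'   (epochs seen, perplexity trace).
#' @export
build_bilm <- function(config, seed = 1L) {
  stopifnot(inherits(config, "bilm_config"))
  set.seed(as.integer(seed))
  geom <- .char_geometry(config)
  nf <- config$n_filters; P <- config$proj_dim; N <- config$hidden_dim
  V <- config$vocab$size

  char <- list(
    emb = .nn_init(geom$n_char, config$char_dim, 0.1),
    conv = lapply(config$conv, function(wf) {
      list(W = .nn_init(wf[1L] * config$char_dim, wf[2L]),
           b = .nn_zeros(wf[2L]))
    }),
    highway = lapply(seq_len(config$n_highway), function(i) {
      list(Wt = .nn_init(nf, nf), bt = .nn_zeros(nf) - 2,  # carry-biased
           Wh = .nn_init(nf, nf), bh = .nn_zeros(nf))
    }),
    proj = list(W = .nn_init(nf, P), b = .nn_zeros(P))
  )
  lstm_layer <- function() {
    list(Wx = .nn_init(P, 4L * N), Wh = .nn_init(P, 4L * N),
         b = c(.nn_zeros(N), .nn_zeros(N) + 1, .nn_zeros(2L * N)),
         Wp = .nn_init(N, P))
  }
  params <- list(char = char,
                 fwd = list(l1 = lstm_layer(), l2 = lstm_layer()))
  if (!config$share_directions) {
    params$bwd <- list(l1 = lstm_layer(), l2 = lstm_layer())
  }
  params$softmax <- list(W = .nn_init(P, V), b = .nn_zeros(V))

  structure(
    list(config = config, params = params, geom = geom,
         meta = list(epochs = 0L,
                     perplexity_trace = data.frame(
                       epoch = integer(0), forward = numeric(0),
                       backward = numeric(0), mean = numeric(0)))),
    class = "bilm"
  )
}

.dir_params <- function(model, direction) {
  if (model$config$share_directions || direction == "fwd") {
    model$params$fwd
  } else {
    model$params$bwd
  }
}

# ---- token table (CharCNN + highway + projection) -------------------------

.token_table_forward <- function(params, cfg, geom) {
  E <- params$emb
  V <- nrow(geom$ids); W <- ncol(geom$ids); cd <- ncol(E)
  emb <- array(t(E[t(geom$ids), ]), dim = c(cd, W, V))  # cd x W x V
  pooled <- list(); conv_cache <- list()
  for (k in seq_along(cfg$conv)) {
    w <- cfg$conv[[k]][1L]; f <- cfg$conv[[k]][2L]
    npos <- W - w + 1L
    scores <- array(0, c(V, f, npos))
    blocks <- vector("list", npos)
    for (p in seq_len(npos)) {
      block <- t(matrix(emb[, p:(p + w - 1L), , drop = FALSE], cd * w, V))
      blocks[[p]] <- block
      scores[, , p] <- pmax(block %*% params$conv[[k]]$W +
                              rep(params$conv[[k]]$b, each = V), 0)
    }
    mx <- apply(scores, c(1, 2), max)
    amx <- apply(scores, c(1, 2), which.max)
    pooled[[k]] <- mx
    conv_cache[[k]] <- list(blocks = blocks, scores = scores, argmax = amx)
  }
  x <- do.call(cbind, pooled)
  hw_cache <- list()
  for (l in seq_along(params$highway)) {
    hp <- params$highway[[l]]
    tt <- .nn_sigmoid(x %*% hp$Wt + rep(hp$bt, each = V))
    hh <- pmax(x %*% hp$Wh + rep(hp$bh, each = V), 0)
    hw_cache[[l]] <- list(x = x, t = tt, h = hh)
    x <- tt * hh + (1 - tt) * x
  }
  R <- x %*% params$proj$W + rep(params$proj$b, each = V)
  list(R = R, cache = list(conv = conv_cache, hw = hw_cache, hw_out = x))
}

.token_table_backward <- function(params, cfg, geom, cache, dR) {
  V <- nrow(geom$ids); cd <- cfg$char_dim
  g <- .tree_map(params, function(p) p * 0)
  g$proj$W <- t(cache$hw_out) %*% dR
  g$proj$b <- colSums(dR)
  dx <- dR %*% t(params$proj$W)
  for (l in rev(seq_along(params$highway))) {
    hp <- params$highway[[l]]; cc <- cache$hw[[l]]
    dt <- dx * (cc$h - cc$x) * cc$t * (1 - cc$t)
    dh <- dx * cc$t
    dh <- dh * (cc$h > 0)
    g$highway[[l]]$Wt <- t(cc$x) %*% dt
    g$highway[[l]]$bt <- colSums(dt)
    g$highway[[l]]$Wh <- t(cc$x) %*% dh
    g$highway[[l]]$bh <- colSums(dh)
    dx <- dx * (1 - cc$t) + dt %*% t(hp$Wt) + dh %*% t(hp$Wh)
  }
  dE <- matrix(0, nrow(params$emb), cd)
  off <- 0L
  for (k in seq_along(cfg$conv)) {
    w <- cfg$conv[[k]][1L]; f <- cfg$conv[[k]][2L]
    cc <- cache$conv[[k]]
    dpool <- dx[, off + seq_len(f), drop = FALSE]
    npos <- dim(cc$scores)[3L]
    for (p in seq_len(npos)) {
      sel <- (cc$argmax == p) & (cc$scores[, , p, drop = FALSE][, , 1] > 0)
      ds <- dpool * sel
      if (!any(sel)) next
      g$conv[[k]]$W <- g$conv[[k]]$W + t(cc$blocks[[p]]) %*% ds
      g$conv[[k]]$b <- g$conv[[k]]$b + colSums(ds)
      dblock <- ds %*% t(params$conv[[k]]$W)  # V x (cd*w)
      for (j in seq_len(w)) {
        cols <- (j - 1L) * cd + seq_len(cd)
        ids <- geom$ids[, p + j - 1L]
        agg <- rowsum(dblock[, cols, drop = FALSE], group = ids)
        dE[as.integer(rownames(agg)), ] <-
          dE[as.integer(rownames(agg)), ] + agg
      }
    }
    off <- off + f
  }
  g$emb <- dE
  g
}

# ---- LSTM with projection -------------------------------------------------

.lstm_window_forward <- function(lp, X, state) {
  # lp: layer params; X: list over time of (B x P); state: list(h, c)
  N <- ncol(lp$Wx) / 4L
  Tn <- length(X); B <- nrow(X[[1L]])
  cache <- vector("list", Tn)
  H <- vector("list", Tn)
  h <- state$h; c <- state$c
  for (t in seq_len(Tn)) {
    z <- X[[t]] %*% lp$Wx + h %*% lp$Wh + rep(lp$b, each = B)
    i <- .nn_sigmoid(z[, seq_len(N), drop = FALSE])
    f <- .nn_sigmoid(z[, N + seq_len(N), drop = FALSE])
    gg <- tanh(z[, 2L * N + seq_len(N), drop = FALSE])
    o <- .nn_sigmoid(z[, 3L * N + seq_len(N), drop = FALSE])
    c_new <- f * c + i * gg
    ch <- tanh(c_new)
    hc <- o * ch
    h_new <- hc %*% lp$Wp
    cache[[t]] <- list(x = X[[t]], h_prev = h, c_prev = c, i = i, f = f,
                       g = gg, o = o, c = c_new, ch = ch, hc = hc)
    h <- h_new; c <- c_new
    H[[t]] <- h
  }
  list(H = H, state = list(h = h, c = c), cache = cache)
}

.lstm_window_backward <- function(lp, cache, dH) {
  # dH: list over time of gradients w.r.t. the layer's projected outputs
  N <- ncol(lp$Wx) / 4L
  Tn <- length(cache); B <- nrow(dH[[1L]])
  g <- .tree_map(lp, function(p) p * 0)
  dX <- vector("list", Tn)
  dh_next <- matrix(0, B, ncol(lp$Wp))
  dc_next <- matrix(0, B, N)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- dH[[t]] + dh_next
    dhc <- dh %*% t(lp$Wp)
    g$Wp <- g$Wp + t(cc$hc) %*% dh
    do <- dhc * cc$ch
    dc <- dhc * cc$o * (1 - cc$ch^2) + dc_next
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do * cc$o * (1 - cc$o))
    g$Wx <- g$Wx + t(cc$x) %*% dz
    g$Wh <- g$Wh + t(cc$h_prev) %*% dz
    g$b <- g$b + colSums(dz)
    dX[[t]] <- dz %*% t(lp$Wx)
    dh_next <- dz %*% t(lp$Wh)
  }
  list(grads = g, dX = dX)
}

# ---- softmax heads --------------------------------------------------------

.sampler_probs <- function(V, sampler = "uniform") {
  if (sampler == "log_uniform") {
    k <- seq_len(V) - 1
    log((k + 2) / (k + 1)) / log(V + 1)
  } else {
    rep(1 / V, V)
  }
}

.sample_negatives <- function(V, m, sampler = "uniform") {
  sample.int(V, m, replace = FALSE, prob = .sampler_probs(V, sampler))
}

# sampled-softmax loss over a set of positions.
# H: n x P matrix of top-layer outputs; y: 1-based target token rows;
# neg: 1-based sampled negative rows (shared across positions).
.sampled_softmax_loss <- function(sm, H, y, neg, sampler = "uniform") {
  V <- length(sm$b)
  q <- .sampler_probs(V, sampler)
  n <- nrow(H)
  cols <- neg
  logit_pos <- rowSums(H * t(sm$W[, y, drop = FALSE])) + sm$b[y] - log(q[y])
  logit_neg <- H %*% sm$W[, cols, drop = FALSE] +
    rep(sm$b[cols] - log(q[cols]), each = n)
  hit <- outer(y, cols, `==`)
  logit_neg[hit] <- -Inf
  logits <- cbind(logit_pos, logit_neg)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  probs <- ex / Z
  loss <- sum(-log(probs[, 1L]))
  # gradients
  dlogits <- probs
  dlogits[, 1L] <- dlogits[, 1L] - 1
  dH <- dlogits[, -1L, drop = FALSE] %*% t(sm$W[, cols, drop = FALSE]) +
    dlogits[, 1L] * t(sm$W[, y, drop = FALSE])
  dW <- matrix(0, nrow(sm$W), V)
  db <- numeric(V)
  dneg <- t(H) %*% dlogits[, -1L, drop = FALSE]
  dW[, cols] <- dW[, cols] + dneg
  db[cols] <- db[cols] + colSums(dlogits[, -1L, drop = FALSE])
  dpos <- rowsum(H * dlogits[, 1L], group = y)
  rows <- as.integer(rownames(dpos))
  dW[, rows] <- dW[, rows] + t(dpos)
  db_pos <- rowsum(dlogits[, 1L, drop = FALSE], group = y)
  db[rows] <- db[rows] + db_pos[, 1L]
  list(loss = loss, n = n, dH = dH, grads = list(W = dW, b = db))
}

# exact softmax loss (used for evaluation and for gradient checks)
.full_softmax_loss <- function(sm, H, y, want_grads = TRUE) {
  n <- nrow(H); V <- length(sm$b)
  logits <- H %*% sm$W + rep(sm$b, each = n)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  logZ <- log(rowSums(ex)) + mx
  picked <- logits[cbind(seq_len(n), y)]
  loss <- sum(logZ - picked)
  if (!want_grads) return(list(loss = loss, n = n))
  probs <- ex / rowSums(ex)
  probs[cbind(seq_len(n), y)] <- probs[cbind(seq_len(n), y)] - 1
  dH <- probs %*% t(sm$W)
  list(loss = loss, n = n, dH = dH,
       grads = list(W = t(H) %*% probs, b = colSums(probs)))
}

# ---- batching helpers -----------------------------------------------------

# pad tokenized sequences into a (B x T) 1-based id matrix
.pad_ids <- function(tok_list, pad_index1) {
  B <- length(tok_list)
  Tn <- max(vapply(tok_list, length, integer(1)))
  ids <- matrix(pad_index1, B, Tn)
  for (b in seq_len(B)) ids[b, seq_along(tok_list[[b]])] <- tok_list[[b]]
  ids
}

# Per direction: inputs ids[, t], targets ids[, t + 1]; the backward
# direction reads each sequence reversed, so its terminal target is the
# start token, symmetric to the end token in the forward direction.
.direction_ids <- function(tok_list, direction, pad_index1) {
  if (direction == "bwd") tok_list <- lapply(tok_list, rev)
  .pad_ids(tok_list, pad_index1)
}

# ---- forward pass producing all layer states ------------------------------

# Runs one direction over full (padded) sequences without truncation.
# Returns H1, H2 (lists over time of B x P) given a precomputed table R.
.direction_states <- function(model, dirp, R, ids, drop_masks = NULL) {
  B <- nrow(ids); Tn <- ncol(ids); P <- model$config$proj_dim
  X1 <- lapply(seq_len(Tn), function(t) {
    x <- R[ids[, t], , drop = FALSE]
    if (!is.null(drop_masks)) x <- x * drop_masks$l1
    x
  })
  zero <- list(h = matrix(0, B, P),
               c = matrix(0, B, model$config$hidden_dim))
  l1 <- .lstm_window_forward(dirp$l1, X1, zero)
  X2 <- if (is.null(drop_masks)) l1$H else {
    lapply(l1$H, function(h) h * drop_masks$l2)
  }
  l2 <- .lstm_window_forward(dirp$l2, X2, zero)
  out2 <- mapply(function(a, b) a + b, l2$H, l1$H, SIMPLIFY = FALSE)
  list(H1 = l1$H, H2 = out2)
}

# ---- training -------------------------------------------------------------

#' Train a bidirectional language model
#'
#' Truncated backpropagation through time: each length-sorted batch of
#' proteins is processed in contiguous windows of \code{config$unroll}
#' tokens with recurrent state carried across windows within the batch and
#' reset between batches. The forward objective conditions only on tokens
#' left of the target, the backward objective only on tokens right of it;
#' the two direction losses are averaged per step. Training uses the
#' sampled softmax with the configured negative-sample count (log-uniform
#' sampler over vocabulary ranks, accidental hits masked); evaluation uses
#' the full softmax. Dropout at the configured rate is applied to the
#' recurrent layers' inputs during training only. Deterministic given
#' \code{seed}.
#'
#' @param model A \code{bilm} from \code{\link{build_bilm}}.
#' @param records A \code{protein_records} data.frame.
#' @param epochs Number of passes over the corpus.
#' @param batch_size Proteins per batch (length-sorted packing).
#' @param lr Learning rate.
#' @param optimizer \code{"adam"} (default) or \code{"adagrad"}.
#' @param seed Integer seed.
#' @param trace If TRUE (default), record full-softmax perplexity on the
#'   training corpus after each epoch.
#' @param verbose Print per-epoch perplexity.
#' @return The trained \code{bilm} with updated \code{meta}.
#' @export
train_bilm <- function(model, records, epochs = 5L, batch_size = 32L,
                       lr = NULL, optimizer = c("adam", "adagrad"),
                       seed = 1L, trace = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "bilm"), nrow(records) > 0L)
  if (model$config$unroll < 2L) stop("unroll must be >= 2 for training")
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "adam") 0.003 else 0.2
  cfg <- model$config; vocab <- cfg$vocab
  set.seed(as.integer(seed))
  toks <- lapply(records$sequence, function(s) tokenize(s, vocab) + 1L)
  ord <- order(vapply(toks, length, integer(1)))
  toks <- toks[ord]
  batches <- split(seq_along(toks),
                   ceiling(seq_along(toks) / batch_size))
  opt <- .opt_init(model$params, optimizer)
  pad1 <- vocab$pad + 1L

  for (ep in seq_len(epochs)) {
    for (bi in seq_along(batches)) {
      tl <- toks[batches[[bi]]]
      B <- length(tl)
      lens <- vapply(tl, length, integer(1))
      ids_f <- .direction_ids(tl, "fwd", pad1)
      ids_b <- .direction_ids(tl, "bwd", pad1)
      Tn <- ncol(ids_f)
      P <- cfg$proj_dim; N <- cfg$hidden_dim
      states <- list(
        fwd = list(l1 = list(h = matrix(0, B, P), c = matrix(0, B, N)),
                   l2 = list(h = matrix(0, B, P), c = matrix(0, B, N))),
        bwd = list(l1 = list(h = matrix(0, B, P), c = matrix(0, B, N)),
                   l2 = list(h = matrix(0, B, P), c = matrix(0, B, N))))
      t0 <- 1L
      while (t0 < Tn) {
        t1 <- min(t0 + cfg$unroll - 1L, Tn - 1L)
        step <- .bilm_train_window(model, ids_f, ids_b, lens, t0, t1,
                                   states, opt, lr)
        model$params <- step$params
        opt <- step$opt
        states <- step$states
        t0 <- t1 + 1L
      }
    }
    model$meta$epochs <- model$meta$epochs + 1L
    if (trace) {
      pp <- perplexity(model, records)
      model$meta$perplexity_trace <- rbind(
        model$meta$perplexity_trace,
        data.frame(epoch = model$meta$epochs, forward = pp$forward,
                   backward = pp$backward, mean = pp$mean))
      if (verbose) {
        message(sprintf("epoch %d: perplexity %.3f",
                        model$meta$epochs, pp$mean))
      }
    }
  }
  model
}

# One truncated-BPTT window: forward both directions over columns
# t0..t1 (inputs), targets at t+1; sampled-softmax loss; backward;
# one Adagrad step on all parameter groups.
.bilm_train_window <- function(model, ids_f, ids_b, lens, t0, t1,
                               states, opt, lr) {
  cfg <- model$config
  B <- nrow(ids_f); P <- cfg$proj_dim
  tt <- .token_table_forward(model$params$char, cfg, model$geom)
  neg <- .sample_negatives(cfg$vocab$size, cfg$n_negative, cfg$sampler)
  total_grads <- NULL
  loss_n <- 0L
  new_states <- states
  dR <- matrix(0, nrow(tt$R), P)
  sm_grads <- list(W = model$params$softmax$W * 0,
                   b = model$params$softmax$b * 0)

  for (direction in c("fwd", "bwd")) {
    ids <- if (direction == "fwd") ids_f else ids_b
    dirp <- .dir_params(model, direction)
    st <- states[[direction]]
    masks <- if (cfg$dropout > 0) {
      list(l1 = .dropout_mask(B, P, cfg$dropout),
           l2 = .dropout_mask(B, P, cfg$dropout))
    } else NULL
    ts <- t0:t1
    X1 <- lapply(ts, function(t) {
      x <- tt$R[ids[, t], , drop = FALSE]
      if (!is.null(masks)) x <- x * masks$l1
      x
    })
    l1 <- .lstm_window_forward(dirp$l1, X1, st$l1)
    X2 <- if (is.null(masks)) l1$H else lapply(l1$H, `*`, masks$l2)
    l2 <- .lstm_window_forward(dirp$l2, X2, st$l2)
    out2 <- mapply(`+`, l2$H, l1$H, SIMPLIFY = FALSE)

    # collect valid prediction positions: target column t+1 within length
    Hs <- list(); ys <- integer(0); pos_index <- list()
    for (k in seq_along(ts)) {
      t <- ts[k]
      vb <- which(lens >= t + 1L)
      if (length(vb) == 0L) next
      Hs[[length(Hs) + 1L]] <- out2[[k]][vb, , drop = FALSE]
      ys <- c(ys, ids[vb, t + 1L])
      pos_index[[length(pos_index) + 1L]] <- cbind(vb, k)
    }
    if (length(Hs) == 0L) {
      new_states[[direction]] <- list(l1 = l1$state, l2 = l2$state)
      next
    }
    H <- do.call(rbind, Hs)
    sl <- .sampled_softmax_loss(model$params$softmax, H, ys, neg,
                                sampler = cfg$sampler)
    loss_n <- loss_n + sl$n
    sm_grads$W <- sm_grads$W + sl$grads$W
    sm_grads$b <- sm_grads$b + sl$grads$b

    # scatter dH back onto per-time gradient lists
    dOut <- lapply(seq_along(ts), function(k) matrix(0, B, P))
    row0 <- 0L
    for (j in seq_along(pos_index)) {
      pi <- pos_index[[j]]
      n_j <- nrow(pi)
      dOut[[pi[1L, 2L]]][pi[, 1L], ] <- sl$dH[row0 + seq_len(n_j), ,
                                              drop = FALSE]
      row0 <- row0 + n_j
    }

    bk2 <- .lstm_window_backward(dirp$l2, l2$cache, dOut)
    # gradient w.r.t. layer-1 outputs: residual path (bypasses dropout)
    # plus layer-2 input path (through the dropout mask)
    d1 <- mapply(function(dres, dx2) {
      if (!is.null(masks)) dx2 <- dx2 * masks$l2
      dres + dx2
    }, dOut, bk2$dX, SIMPLIFY = FALSE)
    bk1 <- .lstm_window_backward(dirp$l1, l1$cache, d1)
    # into the token table
    for (k in seq_along(ts)) {
      dx <- bk1$dX[[k]]
      if (!is.null(masks)) dx <- dx * masks$l1
      agg <- rowsum(dx, group = ids[, ts[k]])
      r <- as.integer(rownames(agg))
      dR[r, ] <- dR[r, ] + agg
    }
    dir_grads <- list(l1 = bk1$grads, l2 = bk2$grads)
    key <- if (cfg$share_directions) "fwd" else direction
    if (is.null(total_grads)) total_grads <- list()
    if (is.null(total_grads[[key]])) {
      total_grads[[key]] <- dir_grads
    } else {
      total_grads[[key]] <- .grad_add(total_grads[[key]], dir_grads)
    }
    new_states[[direction]] <- list(l1 = l1$state, l2 = l2$state)
  }

  if (loss_n == 0L) {
    return(list(params = model$params, opt = opt, states = new_states))
  }
  char_grads <- .token_table_backward(model$params$char, cfg, model$geom,
                                      tt$cache, dR)
  grads <- list(char = char_grads)
  grads$fwd <- total_grads$fwd
  if (!cfg$share_directions) grads$bwd <- total_grads$bwd
  grads$softmax <- sm_grads
  # Normalize by the target count of a FULL window (both directions), not
  # by the targets realized in this window: short terminal windows (which
  # hold mostly end-of-sequence targets) must not be up-weighted per
  # target, or the model systematically over-predicts the end token.
  denom <- 2 * B * cfg$unroll
  grads <- .tree_map(grads, function(g) g / denom)
  # align tree order with params
  grads <- grads[names(model$params)]
  stepped <- .opt_step(model$params, grads, opt, lr)
  list(params = stepped$params, opt = stepped$state, states = new_states)
}

#' Evaluate language-model perplexity
#'
#' Exponential of the mean per-token negative log-likelihood under the full
#' softmax. Targets are the residues plus the terminal special token of
#' each direction (end token forward, start token backward); padding is
#' excluded. The \code{mean} direction averages forward and backward
#' per-token NLL before exponentiation.
#'
#' @param model A \code{bilm}.
#' @param records A \code{protein_records} data.frame.
#' @param batch_size Proteins per evaluation batch.
#' @return List with \code{forward}, \code{backward}, \code{mean}
#'   perplexities and \code{n_targets}.
#' @export
perplexity <- function(model, records, batch_size = 64L) {
  stopifnot(inherits(model, "bilm"), nrow(records) > 0L)
  cfg <- model$config; vocab <- cfg$vocab
  toks <- lapply(records$sequence, function(s) tokenize(s, vocab) + 1L)
  ord <- order(vapply(toks, length, integer(1)))
  toks <- toks[ord]
  batches <- split(seq_along(toks), ceiling(seq_along(toks) / batch_size))
  tt <- .token_table_forward(model$params$char, cfg, model$geom)
  pad1 <- vocab$pad + 1L
  nll <- c(fwd = 0, bwd = 0); n_t <- 0L
  for (bi in seq_along(batches)) {
    tl <- toks[batches[[bi]]]
    lens <- vapply(tl, length, integer(1))
    for (direction in c("fwd", "bwd")) {
      ids <- .direction_ids(tl, direction, pad1)
      dirp <- .dir_params(model, direction)
      stt <- .direction_states(model, dirp, tt$R, ids)
      Tn <- ncol(ids)
      Hs <- list(); ys <- integer(0)
      for (t in seq_len(Tn - 1L)) {
        vb <- which(lens >= t + 1L)
        if (length(vb) == 0L) next
        Hs[[length(Hs) + 1L]] <- stt$H2[[t]][vb, , drop = FALSE]
        ys <- c(ys, ids[vb, t + 1L])
      }
      H <- do.call(rbind, Hs)
      fl <- .full_softmax_loss(model$params$softmax, H, ys,
                               want_grads = FALSE)
      nll[[if (direction == "fwd") "fwd" else "bwd"]] <-
        nll[[if (direction == "fwd") "fwd" else "bwd"]] + fl$loss
      if (direction == "fwd") n_t <- n_t + fl$n
    }
  }
  list(forward = exp(nll[["fwd"]] / n_t),
       backward = exp(nll[["bwd"]] / n_t),
       mean = exp((nll[["fwd"]] + nll[["bwd"]]) / (2 * n_t)),
       n_targets = n_t)
}
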