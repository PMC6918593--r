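# Per-residue two-layer convolutional multi-task network: a
# sequence-to-structure convolution (X -> 32 channels, window 7) followed,
# through ReLU and dropout, by a structure-to-structure convolution
# (32 -> 13 channels, window 7) whose output splits into three softmax
# heads: 3-state secondary structure, 8-state secondary structure, and
# binary disorder. Works on any residue feature scheme; the free-parameter
# count is X*7*32 + 32 + 32*7*13 + 13.

#' Class vocabularies of the per-residue heads
#'
#' Three-state secondary structure (helix, strand, other), the eight DSSP
#' states, and the binary disorder labels, in head order.
#' @export
SS3_CLASSES <- c("H", "E", "O")

#' @rdname SS3_CLASSES
#' @export
SS8_CLASSES <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' @rdname SS3_CLASSES
#' @export
DISORDER_CLASSES <- c("0", "1")

#' Configuration of the per-residue predictor
#'
#' @param input_channels Number of input channels X (scheme-dependent:
#'   20 one-hot, 23 BLOSUM, 50 profile, 100 k-mer, 1024 embeddings, 1074
#'   profile+embeddings).
#' @param filters First-layer filters (default 32).
#' @param window Convolution window (odd; default 7).
#' @param dropout Dropout rate between the layers (default 0.25).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Proteins per batch (default 128).
#' @param holdout Fraction of proteins held out for early stopping
#'   (default 0.05).
#' @param patience Early-stopping patience in epochs (default 5).
#' @return An object of class \code{residue_model_config}.
#' @export
residue_model_config <- function(input_channels, filters = 32L, window = 7L,
                                 dropout = 0.25, lr = 0.001,
                                 batch_size = 128L, holdout = 0.05,
                                 patience = 5L) {
  stopifnot(window %% 2L == 1L, filters >= 1L, input_channels >= 1L,
            dropout >= 0, dropout < 1)
  structure(
    list(input_channels = as.integer(input_channels),
         filters = as.integer(filters), window = as.integer(window),
         heads = c(ss3 = 3L, ss8 = 8L, disorder = 2L),
         dropout = dropout, lr = lr, batch_size = as.integer(batch_size),
         holdout = holdout, patience = as.integer(patience)),
    class = "residue_model_config"
  )
}

#' Build the per-residue predictor
#'
#' @param config A \code{residue_model_config}.
#' @param seed Integer seed for deterministic initialization.
#' @return An object of class \code{residue_model}.
#' @export
build_residue_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "residue_model_config"))
  set.seed(as.integer(seed))
  X <- config$input_channels; f <- config$filters; w <- config$window
  K <- sum(config$heads)
  params <- list(
    conv1 = list(W = .nn_init(X * w, f), b = .nn_zeros(f)),
    conv2 = list(W = .nn_init(f * w, K), b = .nn_zeros(K))
  )
  structure(list(config = config, params = params,
                 meta = list(epochs = 0L, history = NULL,
                             feature_hash = NULL)),
            class = "residue_model")
}

# zero-padded "same" unfolding: (L x C) -> (L x C*w)
.im2col <- function(X, w) {
  L <- nrow(X); C <- ncol(X); half <- (w - 1L) %/% 2L
  Xp <- rbind(matrix(0, half, C), X, matrix(0, half, C))
  cols <- lapply(seq_len(w), function(j) Xp[(j - 1L) + seq_len(L), ,
                                            drop = FALSE])
  do.call(cbind, cols)
}

.im2col_backward <- function(dCols, w, L, C) {
  half <- (w - 1L) %/% 2L
  dXp <- matrix(0, L + 2L * half, C)
  for (j in seq_len(w)) {
    dXp[(j - 1L) + seq_len(L), ] <- dXp[(j - 1L) + seq_len(L), ] +
      dCols[, (j - 1L) * C + seq_len(C), drop = FALSE]
  }
  dXp[half + seq_len(L), , drop = FALSE]
}

.softmax_rows <- function(Z) {
  mx <- apply(Z, 1L, max)
  e <- exp(Z - mx)
  e / rowSums(e)
}

# forward pass for one protein; mask NULL means inference
.residue_forward <- function(params, cfg, X, drop_mask = NULL) {
  w <- cfg$window
  C1 <- .im2col(X, w)
  U1 <- C1 %*% params$conv1$W + rep(params$conv1$b, each = nrow(X))
  A <- pmax(U1, 0)
  Ad <- if (is.null(drop_mask)) A else A * drop_mask
  C2 <- .im2col(Ad, w)
  U2 <- C2 %*% params$conv2$W + rep(params$conv2$b, each = nrow(X))
  off <- cumsum(c(0L, cfg$heads))
  probs <- lapply(seq_along(cfg$heads), function(h) {
    .softmax_rows(U2[, (off[h] + 1L):off[h + 1L], drop = FALSE])
  })
  names(probs) <- names(cfg$heads)
  list(probs = probs, cache = list(C1 = C1, U1 = U1, Ad = Ad, C2 = C2))
}

# labels: list(ss3, ss8, disorder) of integer class ids (NA = not scored)
.residue_loss_grads <- function(params, cfg, X, labels, drop_mask,
                                denom) {
  fw <- .residue_forward(params, cfg, X, drop_mask)
  off <- cumsum(c(0L, cfg$heads))
  L <- nrow(X)
  dU2 <- matrix(0, L, sum(cfg$heads))
  loss <- 0
  for (h in seq_along(cfg$heads)) {
    y <- labels[[h]]
    v <- which(!is.na(y))
    if (length(v) == 0L) next
    P <- fw$probs[[h]]
    loss <- loss + sum(-log(pmax(P[cbind(v, y[v])], 1e-12))) / denom[h]
    G <- P
    G[cbind(v, y[v])] <- G[cbind(v, y[v])] - 1
    G[setdiff(seq_len(L), v), ] <- 0
    dU2[, (off[h] + 1L):off[h + 1L]] <- G / denom[h]
  }
  g <- list(conv1 = list(W = params$conv1$W * 0, b = params$conv1$b * 0),
            conv2 = list(W = t(fw$cache$C2) %*% dU2, b = colSums(dU2)))
  dAd <- .im2col_backward(dU2 %*% t(params$conv2$W), cfg$window, L,
                          cfg$filters)
  dA <- if (is.null(drop_mask)) dAd else dAd * drop_mask
  dU1 <- dA * (fw$cache$U1 > 0)
  g$conv1$W <- t(fw$cache$C1) %*% dU1
  g$conv1$b <- colSums(dU1)
  list(loss = loss, grads = g)
}

.encode_residue_labels <- function(ss3, ss8, disorder) {
  list(ss3 = match(strsplit(ss3, "")[[1]], SS3_CLASSES),
       ss8 = match(strsplit(ss8, "")[[1]], SS8_CLASSES),
       disorder = match(strsplit(disorder, "")[[1]], DISORDER_CLASSES))
}

#' Train the per-residue predictor
#'
#' Multi-task loss: the sum over the three heads of the cross-entropy
#' averaged over that head's scored residues in the batch. Residues with
#' undefined labels are masked out of both loss and metrics. Optimized
#' with Adam at the configured learning rate over batches of proteins;
#' a random held-out fraction of proteins provides early stopping on the
#' summed held-out loss with the configured patience (the best parameters
#' are restored). Deterministic given \code{seed}.
#'
#' @param model A \code{residue_model}.
#' @param features Named list of \code{residue_features} matrices.
#' @param labels List with character vectors \code{ss3}, \code{ss8},
#'   \code{disorder} named by record id (label strings; positions with
#'   \code{"-"} are not scored).
#' @param epochs Maximum epochs (default 30).
#' @param seed Integer seed.
#' @param verbose Print epoch losses.
#' @return The trained \code{residue_model} with a \code{history}
#'   data.frame in \code{meta}.
#' @export
train_residue_model <- function(model, features, labels, epochs = 30L,
                                seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "residue_model"))
  cfg <- model$config
  ids <- names(features)
  stopifnot(length(ids) >= 2L)
  enc <- lapply(ids, function(id) {
    if (nrow(features[[id]]) != nchar(labels$ss3[[id]])) {
      stop("feature/label length mismatch for '", id, "'")
    }
    .encode_residue_labels(labels$ss3[[id]], labels$ss8[[id]],
                           labels$disorder[[id]])
  })
  names(enc) <- ids
  if (any(vapply(features, ncol, integer(1)) != cfg$input_channels)) {
    stop("expected ", cfg$input_channels, " input channels")
  }
  # record the provenance of embedding-derived features so later
  # predictions can refuse embeddings from a different language model
  hashes <- unique(unlist(lapply(features, attr, "model_hash")))
  if (length(hashes) > 1L) {
    stop("features carry embeddings from different model checkpoints")
  }
  if (length(hashes) == 1L) model$meta$feature_hash <- hashes
  set.seed(as.integer(seed))
  n_hold <- max(1L, round(cfg$holdout * length(ids)))
  hold <- sample(ids, n_hold)
  train_ids <- setdiff(ids, hold)
  if (length(train_ids) == 0L) stop("empty training split")
  opt <- .opt_init(model$params, "adam")
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- NULL
  for (ep in seq_len(epochs)) {
    sh <- sample(train_ids)
    batches <- split(sh, ceiling(seq_along(sh) / cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      # per-head scored-residue counts over the batch (loss denominators)
      denom <- vapply(seq_len(3L), function(h) {
        max(1L, sum(vapply(batch, function(id) {
          sum(!is.na(enc[[id]][[h]]))
        }, integer(1))))
      }, numeric(1))
      total <- NULL; bloss <- 0
      for (id in batch) {
        X <- features[[id]]
        mask <- .dropout_mask(nrow(X), cfg$filters, cfg$dropout)
        lg <- .residue_loss_grads(model$params, cfg, X, enc[[id]], mask,
                                  denom)
        bloss <- bloss + lg$loss
        total <- if (is.null(total)) lg$grads else {
          .grad_add(total, lg$grads)
        }
      }
      stepped <- .opt_step(model$params, total, opt, cfg$lr)
      model$params <- stepped$params; opt <- stepped$state
      ep_loss <- ep_loss + bloss
    }
    hl <- .residue_holdout_loss(model, features[hold], enc[hold])
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   holdout_loss = hl))
    if (verbose) message(sprintf("epoch %d: holdout loss %.4f", ep, hl))
    if (hl < best$loss - 1e-9) {
      best <- list(loss = hl, params = model$params, epoch = ep)
    } else if (ep - best$epoch >= cfg$patience) {
      break
    }
  }
  model$params <- best$params
  model$meta$epochs <- best$epoch
  model$meta$history <- hist
  model$meta$holdout_ids <- hold
  model
}

.residue_holdout_loss <- function(model, features, enc) {
  cfg <- model$config
  denom <- vapply(seq_len(3L), function(h) {
    max(1L, sum(vapply(enc, function(e) sum(!is.na(e[[h]])), integer(1))))
  }, numeric(1))
  tot <- 0
  for (id in names(features)) {
    fw <- .residue_forward(model$params, cfg, features[[id]])
    for (h in seq_len(3L)) {
      y <- enc[[id]][[h]]; v <- which(!is.na(y))
      if (length(v) == 0L) next
      tot <- tot + sum(-log(pmax(fw$probs[[h]][cbind(v, y[v])], 1e-12))) /
        denom[h]
    }
  }
  tot
}

#' Predict secondary structure and disorder per residue
#'
#' Inference mode (dropout off). Each head's probability rows sum to 1.
#'
#' @param model A trained \code{residue_model}.
#' @param features A single \code{residue_features} matrix or a named list
#'   of them.
#' @return For a single matrix: list with \code{probs} (per-head matrices)
#'   and \code{labels} (argmax strings \code{ss3}, \code{ss8},
#'   \code{disorder}). For a list: a named list of such results.
#' @export
predict_residues <- function(model, features) {
  if (is.list(features) && !is.matrix(features)) {
    return(lapply(features, predict_residues, model = model))
  }
  cfg <- model$config
  if (ncol(features) != cfg$input_channels) {
    stop("scheme mismatch: model expects ", cfg$input_channels,
         " channels, features have ", ncol(features))
  }
  fh <- attr(features, "model_hash")
  if (!is.null(fh) && !is.null(model$meta$feature_hash) &&
      !identical(fh, model$meta$feature_hash)) {
    stop("embedding checkpoint mismatch: model was trained on embeddings ",
         "from checkpoint ", model$meta$feature_hash, ", got ", fh)
  }
  fw <- .residue_forward(model$params, cfg, features)
  labs <- list(
    ss3 = paste(SS3_CLASSES[max.col(fw$probs$ss3)], collapse = ""),
    ss8 = paste(SS8_CLASSES[max.col(fw$probs$ss8)], collapse = ""),
    disorder = paste(DISORDER_CLASSES[max.col(fw$probs$disorder)],
                     collapse = "")
  )
  list(probs = fw$probs, labels = labs)
}

#' Write residue predictions to TSV
#'
#' Columns: id, pos (1-based), ss3, ss8, disorder probability.
#'
#' @param predictions Named list from \code{\link{predict_residues}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_residue_predictions <- function(predictions, path) {
  rows <- lapply(names(predictions), function(id) {
    p <- predictions[[id]]
    data.frame(id = id, pos = seq_len(nrow(p$probs$ss3)),
               ss3 = strsplit(p$labels$ss3, "")[[1]],
               ss8 = strsplit(p$labels$ss8, "")[[1]],
               p_disorder = p$probs$disorder[, 2L])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
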