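# Per-protein feed-forward multi-task network: the pooled embedding is
# compressed to 32 features, then dropout, batch normalization and a
# rectifier are applied (in exactly that order), and two linear softmax
# heads predict 10-class subcellular localization and membrane vs.
# water-soluble. Free parameters: d*32 + 32 + 64 (normalization scale and
# shift) + 330 + 66.

#' Membrane-status classes of the per-protein predictor
#'
#' @export
MEMBRANE_CLASSES <- c("soluble", "membrane")

#' Configuration of the per-protein predictor
#'
#' @param input_dim Pooled-embedding dimension (1024 for the full-scale
#'   language model, 100 for the k-mer baseline).
#' @param hidden Compressed dimension (default 32).
#' @param dropout Dropout rate (default 0.25).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Proteins per batch (default 64).
#' @param holdout Early-stopping fraction (default 0.1).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param classes Localization class names (10).
#' @return An object of class \code{protein_model_config}.
#' @export
protein_model_config <- function(input_dim, hidden = 32L, dropout = 0.25,
                                 lr = 0.001, batch_size = 64L,
                                 holdout = 0.1, patience = 5L,
                                 classes = LOCALIZATION_CLASSES) {
  stopifnot(input_dim >= 1L, hidden >= 1L, length(classes) == 10L)
  structure(
    list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
         dropout = dropout, lr = lr, batch_size = as.integer(batch_size),
         holdout = holdout, patience = as.integer(patience),
         classes = classes, heads = c(loc = 10L, mem = 2L)),
    class = "protein_model_config"
  )
}

#' Build the per-protein predictor
#'
#' @param config A \code{protein_model_config}.
#' @param seed Integer seed.
#' @return An object of class \code{protein_model}. The normalization
#'   layer's running mean/variance live outside \code{params} (they are
#'   statistics, not trainable parameters).
#' @export
build_protein_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "protein_model_config"))
  set.seed(as.integer(seed))
  d <- config$input_dim; h <- config$hidden
  params <- list(
    compress = list(W = .nn_init(d, h), b = .nn_zeros(h)),
    norm = list(gamma = rep(1, h), beta = .nn_zeros(h)),
    loc = list(W = .nn_init(h, 10L), b = .nn_zeros(10L)),
    mem = list(W = .nn_init(h, 2L), b = .nn_zeros(2L))
  )
  structure(
    list(config = config, params = params,
         running = list(mean = .nn_zeros(h), var = rep(1, h)),
         meta = list(epochs = 0L, history = NULL)),
    class = "protein_model"
  )
}

.protein_forward <- function(model, X, train = FALSE, drop_mask = NULL) {
  p <- model$params; cfg <- model$config
  B <- nrow(X); eps <- 1e-5
  Z <- X %*% p$compress$W + rep(p$compress$b, each = B)
  Zd <- if (is.null(drop_mask)) Z else Z * drop_mask
  if (train) {
    mu <- colMeans(Zd)
    va <- colMeans(sweep(Zd, 2L, mu)^2)
  } else {
    mu <- model$running$mean
    va <- model$running$var
  }
  Zh <- sweep(sweep(Zd, 2L, mu), 2L, sqrt(va + eps), "/")
  Zn <- sweep(sweep(Zh, 2L, p$norm$gamma, "*"), 2L, p$norm$beta, "+")
  A <- pmax(Zn, 0)
  loc_logits <- A %*% p$loc$W + rep(p$loc$b, each = B)
  mem_logits <- A %*% p$mem$W + rep(p$mem$b, each = B)
  list(loc = .softmax_rows(loc_logits), mem = .softmax_rows(mem_logits),
       cache = list(X = X, Zd = Zd, Zh = Zh, Zn = Zn, A = A,
                    mu = mu, va = va, eps = eps))
}

# y_loc: integer 1..10; y_mem: integer 1..2 or NA (unknown -> masked)
.protein_loss_grads <- function(model, X, y_loc, y_mem, drop_mask) {
  fw <- .protein_forward(model, X, train = TRUE, drop_mask = drop_mask)
  p <- model$params; cc <- fw$cache
  B <- nrow(X)
  Gloc <- fw$loc
  Gloc[cbind(seq_len(B), y_loc)] <- Gloc[cbind(seq_len(B), y_loc)] - 1
  Gloc <- Gloc / B
  vm <- which(!is.na(y_mem))
  Gmem <- fw$mem * 0
  if (length(vm) > 0L) {
    Gmem[vm, ] <- fw$mem[vm, , drop = FALSE]
    Gmem[cbind(vm, y_mem[vm])] <- Gmem[cbind(vm, y_mem[vm])] - 1
    Gmem <- Gmem / length(vm)
  }
  loss <- sum(-log(pmax(fw$loc[cbind(seq_len(B), y_loc)], 1e-12))) / B +
    if (length(vm) > 0L) {
      sum(-log(pmax(fw$mem[cbind(vm, y_mem[vm])], 1e-12))) / length(vm)
    } else 0

  g <- list(
    compress = list(W = p$compress$W * 0, b = p$compress$b * 0),
    norm = list(gamma = p$norm$gamma * 0, beta = p$norm$beta * 0),
    loc = list(W = t(cc$A) %*% Gloc, b = colSums(Gloc)),
    mem = list(W = t(cc$A) %*% Gmem, b = colSums(Gmem))
  )
  dA <- Gloc %*% t(p$loc$W) + Gmem %*% t(p$mem$W)
  dZn <- dA * (cc$Zn > 0)
  g$norm$gamma <- colSums(dZn * cc$Zh)
  g$norm$beta <- colSums(dZn)
  dZh <- sweep(dZn, 2L, p$norm$gamma, "*")
  # batch-normalization backward (batch statistics)
  istd <- 1 / sqrt(cc$va + cc$eps)
  dvar <- colSums(dZh * sweep(cc$Zd, 2L, cc$mu)) * (-0.5) * istd^3
  dmu <- colSums(sweep(dZh, 2L, -istd, "*")) +
    dvar * (-2) * colMeans(sweep(cc$Zd, 2L, cc$mu))
  dZd <- sweep(dZh, 2L, istd, "*") +
    sweep(2 * sweep(cc$Zd, 2L, cc$mu) / B, 2L, dvar, "*") +
    matrix(dmu / B, B, length(dmu), byrow = TRUE)
  dZ <- if (is.null(drop_mask)) dZd else dZd * drop_mask
  g$compress$W <- t(cc$X) %*% dZ
  g$compress$b <- colSums(dZ)
  list(loss = loss, grads = g, batch_mean = cc$mu, batch_var = cc$va)
}

#' Train the per-protein predictor
#'
#' Loss = localization cross-entropy + membrane cross-entropy, summed
#' before backpropagation; proteins with membrane status \code{"unknown"}
#' contribute zero membrane loss (and zero membrane gradient) while still
#' training the localization head. The normalization layer's running
#' mean/variance are updated from batch statistics during training and
#' frozen at inference. Early stopping on the summed held-out loss.
#' Deterministic given \code{seed}.
#'
#' @param model A \code{protein_model}.
#' @param embeddings Named list of pooled embedding vectors, or a matrix
#'   with ids as rownames.
#' @param labels List with \code{localization} (named character vector over
#'   the 10 classes) and \code{membrane} (named vector over
#'   membrane/soluble/unknown).
#' @param epochs Maximum epochs (default 50).
#' @param seed Integer seed.
#' @param verbose Print epoch losses.
#' @return The trained \code{protein_model}.
#' @export
train_protein_model <- function(model, embeddings, labels, epochs = 50L,
                                seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "protein_model"))
  cfg <- model$config
  X <- if (is.matrix(embeddings)) embeddings else {
    do.call(rbind, lapply(embeddings, as.numeric))
  }
  ids <- rownames(X) <- if (is.matrix(embeddings)) rownames(embeddings) else {
    names(embeddings)
  }
  if (ncol(X) != cfg$input_dim) {
    stop("dim mismatch: model expects ", cfg$input_dim, ", got ", ncol(X))
  }
  y_loc <- match(labels$localization[ids], cfg$classes)
  if (anyNA(y_loc)) stop("localization label outside the 10-class vocabulary")
  memv <- labels$membrane[ids]
  if (!all(memv %in% c(MEMBRANE_CLASSES, "unknown"))) {
    stop("membrane labels must be membrane/soluble/unknown")
  }
  y_mem <- match(memv, MEMBRANE_CLASSES)  # NA for unknown

  set.seed(as.integer(seed))
  n <- nrow(X)
  n_hold <- max(1L, round(cfg$holdout * n))
  hold <- sample.int(n, n_hold)
  tr <- setdiff(seq_len(n), hold)
  if (length(tr) == 0L) stop("empty training split")
  opt <- .opt_init(model$params, "adam")
  best <- list(loss = Inf, params = model$params,
               running = model$running, epoch = 0L)
  hist <- NULL; momentum <- 0.1
  for (ep in seq_len(epochs)) {
    sh <- sample(tr)
    batches <- split(sh, ceiling(seq_along(sh) / cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      mask <- .dropout_mask(length(batch), cfg$hidden, cfg$dropout)
      lg <- .protein_loss_grads(model, X[batch, , drop = FALSE],
                                y_loc[batch], y_mem[batch], mask)
      stepped <- .opt_step(model$params, lg$grads, opt, cfg$lr)
      model$params <- stepped$params; opt <- stepped$state
      model$running$mean <- (1 - momentum) * model$running$mean +
        momentum * lg$batch_mean
      model$running$var <- (1 - momentum) * model$running$var +
        momentum * lg$batch_var
      ep_loss <- ep_loss + lg$loss
    }
    hl <- .protein_holdout_loss(model, X[hold, , drop = FALSE],
                                y_loc[hold], y_mem[hold])
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   holdout_loss = hl))
    if (verbose) message(sprintf("epoch %d: holdout loss %.4f", ep, hl))
    if (hl < best$loss - 1e-9) {
      best <- list(loss = hl, params = model$params,
                   running = model$running, epoch = ep)
    } else if (ep - best$epoch >= cfg$patience) {
      break
    }
  }
  model$params <- best$params
  model$running <- best$running
  model$meta$epochs <- best$epoch
  model$meta$history <- hist
  model
}

.protein_holdout_loss <- function(model, X, y_loc, y_mem) {
  fw <- .protein_forward(model, X, train = FALSE)
  B <- nrow(X)
  l <- sum(-log(pmax(fw$loc[cbind(seq_len(B), y_loc)], 1e-12))) / B
  vm <- which(!is.na(y_mem))
  if (length(vm) > 0L) {
    l <- l + sum(-log(pmax(fw$mem[cbind(vm, y_mem[vm])], 1e-12))) /
      length(vm)
  }
  l
}

#' Predict localization and membrane status
#'
#' Inference mode: dropout off, normalization frozen at the running
#' statistics, so the output is a deterministic function of the input.
#'
#' @param model A trained \code{protein_model}.
#' @param embedding A single pooled vector or a matrix (one row per
#'   protein, ids as rownames).
#' @return List with \code{loc_probs}, \code{mem_probs} (matrices whose
#'   rows sum to 1) and argmax \code{loc_label}, \code{mem_label}.
#' @export
predict_protein <- function(model, embedding) {
  cfg <- model$config
  X <- if (is.matrix(embedding)) embedding else {
    matrix(as.numeric(embedding), nrow = 1L,
           dimnames = list(attr(embedding, "id"), NULL))
  }
  if (ncol(X) != cfg$input_dim) {
    stop("dim mismatch: model expects ", cfg$input_dim, ", got ", ncol(X))
  }
  fw <- .protein_forward(model, X, train = FALSE)
  colnames(fw$loc) <- cfg$classes
  colnames(fw$mem) <- MEMBRANE_CLASSES
  list(loc_probs = fw$loc, mem_probs = fw$mem,
       loc_label = cfg$classes[max.col(fw$loc)],
       mem_label = MEMBRANE_CLASSES[max.col(fw$mem)])
}
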