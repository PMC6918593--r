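# Extraction of per-residue contextual embeddings from a trained biLM,
# layer combination, mean pooling to per-protein vectors, token-capped
# batch planning, and a persistent embedding store.

#' Extract per-residue contextual embeddings
#'
#' Three layers are extracted per residue: layer 0 is the context-independent
#' word-encoder output duplicated across the two direction halves; layers 1
#' and 2 are the recurrent outputs with forward and backward halves
#' concatenated (layer 2 includes the residual connection). With
#' \code{mode = "sum"} the three layer matrices are summed element-wise
#' (dimension = per-layer dim, 1024 for the paper preset); with
#' \code{mode = "concat"} they are concatenated horizontally (3x the
#' per-layer dim). No fine-tuning and no layer weighting is applied, and
#' inference runs with dropout off. Start/end tokens are excluded, so each
#' protein yields one row per residue.
#'
#' @param model A trained \code{bilm}.
#' @param records A \code{protein_records} data.frame.
#' @param mode \code{"sum"} (default) or \code{"concat"}.
#' @param token_cap Token cap for inference batches (see
#'   \code{\link{plan_batches}}).
#' @return Named list of numeric matrices (length x D), one per record id,
#'   each carrying attributes \code{mode} and \code{model_hash}.
#' @export
embed_residues <- function(model, records, mode = c("sum", "concat"),
                           token_cap = 15000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "bilm"), nrow(records) > 0L)
  cfg <- model$config; vocab <- cfg$vocab
  hash <- model_hash(model)
  tt <- .token_table_forward(model$params$char, cfg, model$geom)
  plan <- plan_batches(records, token_cap = token_cap)
  pad1 <- vocab$pad + 1L
  out <- vector("list", nrow(records))
  names(out) <- records$id
  for (batch in plan$batches) {
    idx <- match(batch, records$id)
    tl <- lapply(records$sequence[idx], function(s) tokenize(s, vocab) + 1L)
    lens <- vapply(tl, length, integer(1))
    ids_f <- .direction_ids(tl, "fwd", pad1)
    ids_b <- .direction_ids(tl, "bwd", pad1)
    sf <- .direction_states(model, .dir_params(model, "fwd"), tt$R, ids_f)
    sb <- .direction_states(model, .dir_params(model, "bwd"), tt$R, ids_b)
    for (j in seq_along(idx)) {
      L <- lens[j] - 2L  # residues only
      fpos <- 1L + seq_len(L)          # residue r_i consumed at column i+1
      bpos <- lens[j] - seq_len(L)     # and at column L-i+2 when reversed
      l0 <- tt$R[ids_f[j, fpos], , drop = FALSE]
      layer0 <- cbind(l0, l0)
      layer1 <- cbind(.rows_at(sf$H1, j, fpos), .rows_at(sb$H1, j, bpos))
      layer2 <- cbind(.rows_at(sf$H2, j, fpos), .rows_at(sb$H2, j, bpos))
      m <- if (mode == "sum") layer0 + layer1 + layer2 else {
        cbind(layer0, layer1, layer2)
      }
      attr(m, "mode") <- mode
      attr(m, "model_hash") <- hash
      out[[batch[j]]] <- m
    }
  }
  out
}

.rows_at <- function(H, b, ts) {
  do.call(rbind, lapply(ts, function(t) H[[t]][b, , drop = FALSE]))
}

#' Mean-pool residue embeddings to one protein vector
#'
#' @param embedding A residue-embedding matrix (length x D).
#' @return Numeric vector of length D: the arithmetic mean over rows, with
#'   attributes carried over.
#' @export
pool_protein <- function(embedding) {
  stopifnot(is.matrix(embedding), nrow(embedding) >= 1L)
  v <- colMeans(embedding)
  attr(v, "mode") <- attr(embedding, "mode")
  attr(v, "model_hash") <- attr(embedding, "model_hash")
  v
}

#' Plan token-capped inference batches
#'
#' Records are sorted ascending by sequence length and packed greedily into
#' batches whose total residue count stays at or below \code{token_cap};
#' a single protein longer than the cap forms a singleton batch.
#'
#' @param records A \code{protein_records} data.frame.
#' @param token_cap Maximum residues per batch (default 15000).
#' @return List with \code{batches} (list of id character vectors) and
#'   \code{token_cap}.
#' @export
plan_batches <- function(records, token_cap = 15000L) {
  stopifnot(nrow(records) > 0L, token_cap >= 1L)
  lens <- nchar(records$sequence)
  ord <- order(lens, records$id)
  batches <- list(); cur <- character(0); cur_tokens <- 0L
  for (i in ord) {
    l <- lens[i]
    if (length(cur) > 0L && cur_tokens + l > token_cap) {
      batches[[length(batches) + 1L]] <- cur
      cur <- character(0); cur_tokens <- 0L
    }
    cur <- c(cur, records$id[i]); cur_tokens <- cur_tokens + l
  }
  if (length(cur) > 0L) batches[[length(batches) + 1L]] <- cur
  list(batches = batches, token_cap = as.integer(token_cap))
}

#' Checkpoint hash of a model
#'
#' A short digest of the serialized parameters, used to guard downstream
#' predictors against embeddings from a different model.
#'
#' @param model A \code{bilm} (or any parameterized model object).
#' @return Character scalar.
#' @export
model_hash <- function(model) {
  raw <- serialize(model$params, NULL, version = 2L)
  # FNV-1a over an evenly spaced byte subsample plus the total length;
  # collision resistance is not required, only mismatch detection
  take <- unique(as.integer(round(seq(1L, length(raw),
                                      length.out = min(16384L, length(raw))))))
  b <- as.integer(raw[take])
  h <- 17
  for (chunk in split(b, ceiling(seq_along(b) / 1024L))) {
    h <- (h * 131 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  h <- (h * 131 + length(raw)) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# ---- embedding store ------------------------------------------------------
# Directory-based store: meta.json (mode, per-layer dim, model hash, ids,
# shapes) plus one little-endian float32 binary file per record.

#' Persist residue embeddings to an embedding store
#'
#' The store is a directory holding a JSON metadata file (layer-combination
#' mode, per-layer dimension, model checkpoint hash, record shapes) and one
#' float32 binary matrix per record. Round-trips are lossless at float32
#' precision.
#'
#' @param embeddings Named list of embedding matrices from
#'   \code{\link{embed_residues}}.
#' @param path Store directory (created; must not already contain a store
#'   with colliding ids unless \code{overwrite}).
#' @param overwrite Allow overwriting an existing store.
#' @return \code{path}, invisibly.
#' @export
write_store <- function(embeddings, path, overwrite = FALSE) {
  meta_path <- file.path(path, "meta.json")
  if (file.exists(meta_path) && !overwrite) {
    old <- jsonlite::read_json(meta_path)
    coll <- intersect(names(embeddings), names(old$shapes))
    if (length(coll) > 0L) {
      stop("id collision on write: ", paste(coll, collapse = ", "))
    }
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  modes <- unique(vapply(embeddings, function(m) attr(m, "mode"), ""))
  hashes <- unique(vapply(embeddings, function(m) attr(m, "model_hash"), ""))
  stopifnot(length(modes) == 1L, length(hashes) == 1L)
  shapes <- lapply(embeddings, dim)
  meta <- list(mode = modes, model_hash = hashes,
               per_layer_dim = if (modes == "sum") ncol(embeddings[[1L]])
                               else ncol(embeddings[[1L]]) %/% 3L,
               shapes = shapes)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  for (id in names(embeddings)) {
    con <- file(file.path(path, paste0(.safe_name(id), ".f32")), "wb")
    writeBin(as.numeric(t(embeddings[[id]])), con, size = 4L,
             endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read embeddings back from a store
#'
#' @param path Store directory written by \code{\link{write_store}}.
#' @param ids Record ids to read (default: all).
#' @param expect_mode If given, error unless the store was written in this
#'   layer-combination mode.
#' @return Named list of embedding matrices with \code{mode} and
#'   \code{model_hash} attributes.
#' @export
read_store <- function(path, ids = NULL, expect_mode = NULL) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("no embedding store at ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!is.null(expect_mode) && !identical(meta$mode, expect_mode)) {
    stop("mode mismatch: store holds '", meta$mode,
         "' embeddings but '", expect_mode, "' was requested")
  }
  if (is.null(ids)) ids <- names(meta$shapes)
  missing <- setdiff(ids, names(meta$shapes))
  if (length(missing) > 0L) {
    stop("id(s) not in store: ", paste(missing, collapse = ", "))
  }
  out <- lapply(ids, function(id) {
    shp <- unlist(meta$shapes[[id]])
    con <- file(file.path(path, paste0(.safe_name(id), ".f32")), "rb")
    v <- readBin(con, numeric(), n = prod(shp), size = 4L,
                 endian = "little")
    close(con)
    m <- matrix(v, nrow = shp[1L], ncol = shp[2L], byrow = TRUE)
    attr(m, "mode") <- meta$mode
    attr(m, "model_hash") <- meta$model_hash
    m
  })
  names(out) <- ids
  out
}

.safe_name <- function(id) gsub("[^A-Za-z0-9._-]", "_", id)

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file archives holding the configuration and the
#' named parameter arrays.
#'
#' @param model A model object (\code{bilm}, k-mer model, or predictor).
#' @param path Checkpoint file path.
#' @return \code{path} (write) or the model (read).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
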