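# Non-contextual input encodings: one-hot, BLOSUM65 substitution-score rows,
# 50-channel evolutionary-profile features, and a ProtVec-style overlapping
# 3-mer skip-gram embedding. Every encoder returns a residue feature matrix
# tagged with its channel scheme.

SCHEME_CHANNELS <- c(onehot20 = 20L, blosum23 = 23L, profile50 = 50L,
                     kmer100 = 100L)

#' Construct a tagged residue feature matrix
#'
#' @param m Numeric matrix (length x channels).
#' @param id Record id.
#' @param scheme Channel scheme tag. Fixed-width schemes
#'   (\code{onehot20}, \code{blosum23}, \code{profile50}, \code{kmer100})
#'   have their channel counts enforced; \code{seqvec} and concatenated
#'   schemes carry their width in the matrix itself.
#' @return The matrix with class \code{residue_features} and attributes
#'   \code{id}, \code{scheme}.
#' @export
feature_matrix <- function(m, id, scheme) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (scheme %in% names(SCHEME_CHANNELS) &&
      ncol(m) != SCHEME_CHANNELS[[scheme]]) {
    stop(sprintf("scheme '%s' requires %d channels, got %d",
                 scheme, SCHEME_CHANNELS[[scheme]], ncol(m)))
  }
  structure(m, id = id, scheme = scheme,
            class = c("residue_features", class(m)))
}

#' One-hot encode a protein sequence
#'
#' Each of the 20 standard residues maps to a unit vector over the fixed
#' alphabetical order; the rare (U, O), ambiguous (B, Z) and unknown (X)
#' codes map to all-zero rows.
#'
#' @param sequence Canonical residue string.
#' @param id Record id for the tag.
#' @return A \code{residue_features} matrix (length x 20), scheme
#'   \code{onehot20}.
#' @export
one_hot_encode <- function(sequence, id = "") {
  std <- aa_alphabet()$standard
  chars <- strsplit(sequence, "")[[1]]
  m <- matrix(0, length(chars), 20L)
  idx <- match(chars, std)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  feature_matrix(m, id = id, scheme = "onehot20")
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI/matblas layout (comment lines starting with
#' \code{#}, a header row of symbols, then one labelled score row per
#' symbol) and returns the 23 x 23 block covering the 20 standard residues
#' plus B, Z and X.
#'
#' @param path Path to the matrix file. Default: the BLOSUM65 matrix
#'   bundled with the package.
#' @param name Name tag.
#' @return An object of class \code{substitution_matrix}: integer matrix
#'   with symbol dimnames and a \code{name} attribute.
#' @export
read_substitution_matrix <- function(path = system.file(
                                       "extdata", "BLOSUM65.txt",
                                       package = "protlm"),
                                     name = "BLOSUM65") {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln)]
  ln <- ln[nzchar(trimws(ln))]
  syms <- strsplit(trimws(ln[1L]), "[[:space:]]+")[[1]]
  rows <- lapply(ln[-1L], function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  lab <- vapply(rows, `[`, "", 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1L])))
  dimnames(m) <- list(lab, syms)
  keep <- c(aa_alphabet()$standard, "B", "Z", "X")
  missing <- setdiff(keep, syms)
  if (length(missing) > 0L) {
    stop("matrix lacks symbols: ", paste(missing, collapse = ", "))
  }
  m <- m[keep, keep]
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix not symmetric")
  structure(m, name = name, class = c("substitution_matrix", class(m)))
}

#' Encode a sequence by substitution-score rows
#'
#' Row i holds the 23 raw integer substitution scores of residue i against
#' the 23 matrix symbols (20 standard + B, Z, X) in fixed order. The rare
#' residues, which substitution matrices lack, are looked up via their
#' closest biochemical parents: U (selenocysteine) as C, O (pyrrolysine)
#' as K; the aliasing is recorded in the matrix attributes.
#'
#' @param sequence Canonical residue string.
#' @param matrix A \code{substitution_matrix} (default: bundled BLOSUM65).
#' @param id Record id for the tag.
#' @return A \code{residue_features} matrix (length x 23), scheme
#'   \code{blosum23}.
#' @export
blosum_encode <- function(sequence, matrix = read_substitution_matrix(),
                          id = "") {
  chars <- strsplit(sequence, "")[[1]]
  alias <- c(U = "C", O = "K")
  lookup <- ifelse(chars %in% names(alias), alias[chars], chars)
  bad <- setdiff(unique(lookup), rownames(matrix))
  if (length(bad) > 0L) {
    stop("no substitution scores for symbol(s): ", paste(bad, collapse = ", "))
  }
  m <- matrix[lookup, , drop = FALSE]
  rownames(m) <- NULL
  out <- feature_matrix(matrix(as.numeric(m), nrow = length(chars)),
                        id = id, scheme = "blosum23")
  attr(out, "aliases") <- alias
  out
}

#' Read 50-channel profile features from TSV
#'
#' Expects columns \code{id}, \code{pos} (1-based) and 50 feature columns
#' in the documented block order [one-hot 20 | profile 20 | transitions 7 |
#' diversity 3]. The profile block is clipped to [0, 1].
#'
#' @param path TSV file path.
#' @param records A \code{protein_records} data.frame; every record must be
#'   covered with matching lengths.
#' @return Named list of \code{residue_features} matrices
#'   (scheme \code{profile50}).
#' @export
read_profile_features <- function(path, records) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("id", "pos") %in% names(tab)) || ncol(tab) != 52L) {
    stop("profile TSV must have columns id, pos and 50 feature columns")
  }
  out <- vector("list", nrow(records)); names(out) <- records$id
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    rows <- tab[tab$id == id, , drop = FALSE]
    L <- nchar(records$sequence[i])
    if (nrow(rows) == 0L) stop("no profile features for record '", id, "'")
    if (nrow(rows) != L) {
      stop(sprintf("profile length %d does not match sequence length %d for '%s'",
                   nrow(rows), L, id))
    }
    rows <- rows[order(rows$pos), ]
    m <- as.matrix(rows[, -(1:2), drop = FALSE])
    if (any(!is.finite(m))) stop("non-finite profile values for '", id, "'")
    m[, 21:40] <- pmin(pmax(m[, 21:40], 0), 1)
    dimnames(m) <- NULL
    out[[id]] <- feature_matrix(m, id = id, scheme = "profile50")
  }
  out
}

#' Write profile feature matrices to TSV
#'
#' @param profiles Named list of profile50 matrices.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_profile_features <- function(profiles, path) {
  blocks <- lapply(names(profiles), function(id) {
    m <- profiles[[id]]
    data.frame(id = id, pos = seq_len(nrow(m)), unclass(m)[,],
               check.names = FALSE)
  })
  tab <- do.call(rbind, blocks)
  names(tab) <- c("id", "pos", paste0("f", 1:50))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- ProtVec-style 3-mer skip-gram ---------------------------------------

.to_kmers <- function(sequence, k = 3L) {
  L <- nchar(sequence)
  if (L < k) stop("sequence shorter than ", k)
  substring(sequence, 1:(L - k + 1L), k:L)
}

#' Train a 3-mer skip-gram embedding (ProtVec-style)
#'
#' Splits every protein into overlapping 3-mers (stride 1) and trains
#' skip-gram with negative sampling to predict context 3-mers from the
#' center 3-mer. The resulting mapping is context-free: one vector per
#' distinct 3-mer. Deterministic given \code{seed}; 3-mers unseen during
#' training map to the zero vector at inference.
#'
#' @param records A \code{protein_records} data.frame (all lengths >= 3).
#' @param dim Embedding dimension (default 100).
#' @param window Context half-window in 3-mer positions (default 2).
#' @param negatives Negative samples per context pair (default 5).
#' @param epochs Passes over the corpus (default 3).
#' @param lr Initial learning rate, decayed linearly (default 0.05).
#' @param seed Integer seed.
#' @return An object of class \code{kmer_model}: list with \code{k},
#'   \code{dim}, \code{vocab}, \code{vectors} (V x dim input embeddings),
#'   and training metadata.
#' @export
train_kmer_skipgram <- function(records, dim = 100L, window = 2L,
                                negatives = 5L, epochs = 3L, lr = 0.05,
                                seed = 1L) {
  stopifnot(nrow(records) > 0L)
  sentences <- lapply(records$sequence, .to_kmers)
  vocab <- sort(unique(unlist(sentences)))
  V <- length(vocab)
  sent_idx <- lapply(sentences, match, table = vocab)
  freq <- tabulate(unlist(sent_idx), nbins = V)
  neg_prob <- freq^0.75; neg_prob <- neg_prob / sum(neg_prob)

  set.seed(as.integer(seed))
  Win <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
  Wout <- matrix(0, V, dim)
  n_pairs_total <- sum(vapply(sent_idx, length, integer(1))) *
    2L * window * epochs
  done <- 0L
  for (ep in seq_len(epochs)) {
    for (s in sent_idx) {
      L <- length(s)
      for (i in seq_len(L)) {
        lo <- max(1L, i - window); hi <- min(L, i + window)
        ctx <- s[setdiff(lo:hi, i)]
        if (length(ctx) == 0L) next
        cur_lr <- lr * max(1e-3, 1 - done / n_pairs_total)
        center <- s[i]
        vin <- Win[center, ]
        for (co in ctx) {
          negs <- sample.int(V, negatives, replace = TRUE, prob = neg_prob)
          targets <- c(co, negs)
          labels <- c(1, numeric(negatives))
          outs <- Wout[targets, , drop = FALSE]
          scores <- .nn_sigmoid(outs %*% vin)
          gerr <- as.numeric(labels - scores)  # d loglik / d score
          Wout[targets, ] <- outs + cur_lr * (gerr %o% vin)
          vin <- vin + cur_lr * as.numeric(crossprod(outs, gerr))
          done <- done + 1L
        }
        Win[center, ] <- vin
      }
    }
  }
  rownames(Win) <- vocab
  structure(
    list(k = 3L, dim = as.integer(dim), vocab = vocab, vectors = Win,
         meta = list(window = window, negatives = negatives,
                     epochs = epochs, seed = as.integer(seed),
                     n_records = nrow(records))),
    class = "kmer_model"
  )
}

#' Look up the vector of a single 3-mer
#'
#' @param model A \code{kmer_model}.
#' @param kmer A 3-letter string.
#' @return Numeric vector of length \code{model$dim} (zero if unseen).
#' @export
kmer_vector <- function(model, kmer) {
  i <- match(kmer, model$vocab)
  if (is.na(i)) numeric(model$dim) else unname(model$vectors[i, ])
}

#' Encode a sequence with 3-mer embeddings
#'
#' Residue level: residue i is represented by the vector of the 3-mer
#' centered at i (defined for positions 2..L-1); the terminal residues
#' replicate the first/last 3-mer. Protein level: the mean over all
#' overlapping 3-mer vectors.
#'
#' @param sequence Canonical residue string (length >= 3).
#' @param model A \code{kmer_model}.
#' @param level \code{"residue"} or \code{"protein"}.
#' @param id Record id for the tag.
#' @return A \code{residue_features} matrix (length x dim, scheme
#'   \code{kmer100} when dim = 100) or a numeric vector of length dim.
#' @export
kmer_encode <- function(sequence, model, level = c("residue", "protein"),
                        id = "") {
  level <- match.arg(level)
  kmers <- .to_kmers(sequence, model$k)
  idx <- match(kmers, model$vocab)
  vecs <- matrix(0, length(kmers), model$dim)
  ok <- !is.na(idx)
  vecs[ok, ] <- model$vectors[idx[ok], , drop = FALSE]
  if (level == "protein") return(colMeans(vecs))
  L <- nchar(sequence)
  rows <- c(1L, seq_len(L - 2L), L - 2L)  # edge replication
  m <- vecs[rows, , drop = FALSE]
  feature_matrix(m, id = id,
                 scheme = if (model$dim == 100L) "kmer100" else "kmer")
}

#' Concatenate two residue feature matrices column-wise
#'
#' @param a,b \code{residue_features} matrices for the same record with
#'   equal row counts.
#' @return A \code{residue_features} matrix with scheme
#'   \code{"<a>+<b>"} and \code{ncol(a) + ncol(b)} channels.
#' @export
concat_features <- function(a, b) {
  stopifnot(inherits(a, "residue_features"), inherits(b, "residue_features"))
  if (nrow(a) == 0L || nrow(b) == 0L) stop("cannot concatenate empty features")
  if (nrow(a) != nrow(b)) stop("length mismatch: ", nrow(a), " vs ", nrow(b))
  ida <- attr(a, "id"); idb <- attr(b, "id")
  if (nzchar(ida) && nzchar(idb) && !identical(ida, idb)) {
    stop("record id mismatch: '", ida, "' vs '", idb, "'")
  }
  feature_matrix(cbind(unclass(a)[, , drop = FALSE],
                       unclass(b)[, , drop = FALSE]),
                 id = if (nzchar(ida)) ida else idb,
                 scheme = paste0(attr(a, "scheme"), "+", attr(b, "scheme")))
}
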