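# Command-line orchestration and the 2-D projection workflow.
# Every subcommand is a thin wrapper over the package functions; artifacts
# carry a provenance record (arguments, seeds, package version).

#' Derive a component seed from a master seed
#'
#' One master seed per run is split deterministically per component so that
#' independent stages consume independent streams.
#'
#' @param seed Master integer seed.
#' @param salt Component name.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, salt) {
  s <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 48271 + s) %% 2147483647)
}

#' Project protein embeddings to two dimensions (t-SNE)
#'
#' Delegates the stochastic neighbor embedding to the scikit-learn
#' implementation through a Python subprocess, with the configured
#' perplexity, iteration count, cosine metric and seed. Defaults follow
#' the package's visualization conventions: perplexity 20 for raw pooled
#' embeddings and 15 for the predictor's 32-dimensional hidden
#' representation; 3000 iterations; cosine distance.
#'
#' @param embeddings Matrix (one protein per row, ids as rownames).
#' @param perplexity t-SNE perplexity (must be < number of points).
#' @param iterations Optimization iterations (default 3000).
#' @param metric Distance metric (default "cosine").
#' @param seed Integer seed.
#' @param python Python executable (must provide scikit-learn).
#' @return Data.frame with columns \code{id}, \code{x}, \code{y}.
#' @export
project_embeddings <- function(embeddings, perplexity = 20,
                               iterations = 3000L, metric = "cosine",
                               seed = 1L, python = "python") {
  stopifnot(is.matrix(embeddings), nrow(embeddings) >= 3L)
  if (perplexity >= nrow(embeddings)) {
    stop("perplexity must be smaller than the number of points")
  }
  td <- tempfile("tsne"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  in_csv <- file.path(td, "in.csv"); out_csv <- file.path(td, "out.csv")
  utils::write.table(embeddings, in_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- file.path(td, "tsne.py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.manifold import TSNE",
    "inp, outp, perp, it, metric, seed = sys.argv[1:7]",
    "X = np.loadtxt(inp, delimiter=',', ndmin=2)",
    "kw = dict(n_components=2, perplexity=float(perp), metric=metric,",
    "          random_state=int(seed), init='random')",
    "try:",
    "    ts = TSNE(max_iter=int(it), **kw)",
    "except TypeError:",
    "    ts = TSNE(n_iter=int(it), **kw)",
    "np.savetxt(outp, ts.fit_transform(X), delimiter=',')"
  ), script)
  status <- system2(python, c(script, in_csv, out_csv, perplexity,
                              iterations, metric, seed),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(out_csv)) {
    stop("t-SNE delegation to Python/scikit-learn failed (status ",
         status, ")")
  }
  xy <- as.matrix(utils::read.csv(out_csv, header = FALSE))
  data.frame(id = rownames(embeddings), x = xy[, 1L], y = xy[, 2L],
             stringsAsFactors = FALSE)
}

# ---- CLI ------------------------------------------------------------------

.parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

.provenance <- function(command, flags, out_dir) {
  rec <- list(command = command, flags = flags,
              package_version = as.character(utils::packageVersion("protlm")),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
}

#' Command-line entry point
#'
#' Subcommands: \code{generate-fixtures}, \code{train-lm}, \code{embed},
#' \code{train-kmer}, \code{train-residue}, \code{train-protein},
#' \code{evaluate}, \code{project}. Each is a thin wrapper over the
#' package functions; see the shipped \code{exec/protlm} script.
#'
#' @param args Character vector of command-line arguments (the subcommand
#'   followed by \code{--flag value} pairs).
#' @return Exit status (0 on success), invisibly.
#' @export
run_cli <- function(args) {
  if (length(args) == 0L) {
    message("usage: protlm <subcommand> [--flag value ...]")
    return(invisible(1L))
  }
  command <- args[1L]
  flags <- .parse_flags(args[-1L])
  seed <- as.integer(flags$seed %||% 1L)
  switch(
    command,
    "generate-fixtures" = {
      n <- as.integer(flags$n %||% 200L)
      out <- flags$out %||% "fixtures"
      fx <- generate_corpus(default_grammar(), n = n,
                            seed = derive_seed(seed, "fixtures"))
      write_fixture_set(fx, out)
      .provenance(command, flags, out)
    },
    "train-lm" = {
      rec <- read_fasta(flags$fasta)
      cfg <- bilm_config(preset = flags$preset %||% "mini")
      model <- build_bilm(cfg, seed = derive_seed(seed, "lm-init"))
      model <- train_bilm(model, rec,
                          epochs = as.integer(flags$epochs %||% 5L),
                          seed = derive_seed(seed, "lm-train"))
      save_checkpoint(model, flags$out)
      utils::write.csv(model$meta$perplexity_trace,
                       paste0(flags$out, ".perplexity.csv"),
                       row.names = FALSE)
    },
    "embed" = {
      model <- load_checkpoint(flags$checkpoint)
      rec <- read_fasta(flags$fasta)
      emb <- embed_residues(model, rec, mode = flags$mode %||% "sum")
      write_store(emb, flags$out)
      .provenance(command, flags, flags$out)
    },
    "train-kmer" = {
      rec <- read_fasta(flags$fasta)
      km <- train_kmer_skipgram(rec, seed = derive_seed(seed, "kmer"))
      save_checkpoint(km, flags$out)
    },
    "train-residue" = {
      labs <- read_residue_labels(flags$labels)
      feats <- read_store(flags$store)
      cfg <- residue_model_config(ncol(feats[[1L]]))
      model <- build_residue_model(cfg, seed = derive_seed(seed, "res-init"))
      model <- train_residue_model(
        model, feats,
        list(ss3 = labs$ss3, ss8 = labs$ss8, disorder = labs$disorder),
        epochs = as.integer(flags$epochs %||% 30L),
        seed = derive_seed(seed, "res-train"))
      save_checkpoint(model, flags$out)
    },
    "train-protein" = {
      labtab <- utils::read.delim(flags$labels)
      emb <- read_store(flags$store)
      pooled <- do.call(rbind, lapply(emb, function(m) pool_protein(m)))
      cfg <- protein_model_config(ncol(pooled))
      model <- build_protein_model(cfg, seed = derive_seed(seed, "prot-init"))
      model <- train_protein_model(
        model, pooled,
        list(localization = stats::setNames(labtab$localization, labtab$id),
             membrane = stats::setNames(labtab$membrane, labtab$id)),
        epochs = as.integer(flags$epochs %||% 50L),
        seed = derive_seed(seed, "prot-train"))
      save_checkpoint(model, flags$out)
    },
    "evaluate" = {
      res <- evaluate_residue_predictions(flags$predictions, flags$labels)
      jsonlite::write_json(res, flags$out, auto_unbox = TRUE, digits = NA)
    },
    "project" = {
      emb <- read_store(flags$store)
      pooled <- do.call(rbind, lapply(emb, function(m) pool_protein(m)))
      xy <- project_embeddings(pooled,
                               perplexity = as.numeric(flags$perplexity %||% 20),
                               iterations = as.integer(flags$iterations %||% 3000L),
                               seed = derive_seed(seed, "tsne"))
      utils::write.csv(xy, flags$out, row.names = FALSE)
    },
    stop("unknown subcommand: ", command,
         " (try generate-fixtures, train-lm, embed, train-kmer, ",
         "train-residue, train-protein, evaluate, project)")
  )
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a residue-prediction TSV against reference labels
#'
#' Computes macro Q3, Q8 and the disorder MCC/FPR from a predictions file
#' written by \code{\link{write_residue_predictions}} and a reference file
#' in the residue-label text format.
#'
#' @param predictions_path TSV from \code{\link{write_residue_predictions}}.
#' @param labels_path File in the format of
#'   \code{\link{read_residue_labels}}.
#' @return List of metric values.
#' @export
evaluate_residue_predictions <- function(predictions_path, labels_path) {
  pred <- utils::read.delim(predictions_path)
  labs <- read_residue_labels(labels_path)
  ids <- intersect(unique(pred$id), names(labs$ss3))
  p3 <- list(); t3 <- list(); p8 <- list(); t8 <- list()
  pd <- list(); td <- list()
  for (id in ids) {
    rows <- pred[pred$id == id, ]
    rows <- rows[order(rows$pos), ]
    p3[[id]] <- rows$ss3; t3[[id]] <- strsplit(labs$ss3[[id]], "")[[1]]
    p8[[id]] <- rows$ss8; t8[[id]] <- strsplit(labs$ss8[[id]], "")[[1]]
    pd[[id]] <- as.integer(rows$p_disorder > 0.5)
    td[[id]] <- as.integer(strsplit(labs$disorder[[id]], "")[[1]])
  }
  q3 <- q_accuracy(p3, t3)
  q8 <- q_accuracy(p8, t8)
  dm <- disorder_mcc(pd, td)
  fpr <- binary_mcc_and_fpr(unlist(pd), unlist(td))$fpr
  list(q3 = q3$value, q3_se = stats::sd(q3$per_protein) /
         sqrt(length(q3$per_protein)),
       q8 = q8$value, disorder_mcc = dm$mcc, disorder_fpr = fpr,
       n_proteins = length(ids))
}
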