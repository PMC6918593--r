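# Shared test helpers: small fixture corpora and independent oracles.

# independent FASTA reader: plain line concatenation, no Biostrings
oracle_read_fasta_lengths <- function(path) {
  ln <- readLines(path)
  heads <- grep("^>", ln)
  ends <- c(heads[-1L] - 1L, length(ln))
  vapply(seq_along(heads), function(i) {
    sum(nchar(ln[(heads[i] + 1L):ends[i]]))
  }, integer(1))
}

# brute-force per-protein accuracy recount
oracle_macro_accuracy <- function(pred, truth) {
  per <- mapply(function(p, t) {
    pc <- strsplit(p, "")[[1]]; tc <- strsplit(t, "")[[1]]
    n_ok <- 0L
    for (i in seq_along(tc)) if (pc[i] == tc[i]) n_ok <- n_ok + 1L
    100 * n_ok / length(tc)
  }, pred, truth)
  mean(per)
}

# binary MCC straight from a contingency table
oracle_mcc <- function(tp, fp, tn, fn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

# longest run of a character in a string
oracle_longest_run <- function(s, ch) {
  r <- rle(strsplit(s, "")[[1]] == ch)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

# small shared corpus for light-weight wiring tests
small_fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(default_grammar(), n = 40, seed = 123)
    }
    cache
  }
})

# a minimally trained mini language model shared by light-weight tests
small_bilm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- build_bilm(bilm_config("mini"), seed = 11)
      cache <<- train_bilm(m, small_fixtures()$records, epochs = 2,
                           seed = 12, trace = FALSE)
    }
    cache
  }
})

uniform_records <- function(n, len, seed, prefix = "u") {
  set.seed(seed)
  std <- aa_alphabet()$standard
  protein_records(
    sprintf("%s%04d", prefix, seq_len(n)),
    vapply(seq_len(n), function(i) {
      paste(sample(std, len, replace = TRUE), collapse = "")
    }, "")
  )
}
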