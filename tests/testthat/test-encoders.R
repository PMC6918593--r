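test_that("one-hot encoding zeroes the non-standard residues", {
  m <- one_hot_encode("A")
  expect_equal(dim(m), c(1L, 20L))
  expect_equal(sum(m), 1)
  expect_equal(which(m[1, ] == 1), 1L)
  expect_equal(sum(one_hot_encode("U")), 0)
  # row sums over the whole 25-letter alphabet are 0 or 1
  all25 <- paste(aa_alphabet()$letters, collapse = "")
  rs <- rowSums(one_hot_encode(all25))
  expect_true(all(rs %in% c(0, 1)))
  expect_equal(sum(rs), 20)  # exactly the standard residues hit
})

test_that("the bundled substitution matrix is parsed faithfully", {
  sm <- read_substitution_matrix()
  expect_equal(dim(sm), c(23L, 23L))
  expect_equal(attr(sm, "name"), "BLOSUM65")
  expect_true(isTRUE(all.equal(unclass(sm), t(unclass(sm)))))
  # independent parse of the shipped file: A row via raw text scanning
  path <- system.file("extdata", "BLOSUM65.txt", package = "protlm")
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln)]
  header <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  a_row <- strsplit(trimws(ln[which(startsWith(trimws(ln[-1]), "A "))[1] + 1]),
                    "\\s+")[[1]]
  a_scores <- as.integer(a_row[-1])
  names(a_scores) <- header
  keep <- c(aa_alphabet()$standard, "B", "Z", "X")
  expect_equal(unname(sm["A", ]), unname(a_scores[keep]))
})

test_that("BLOSUM encoding yields 23 channels and aliases U and O", {
  sm <- read_substitution_matrix()
  enc <- blosum_encode("AA", sm)
  expect_equal(dim(enc), c(2L, 23L))
  expect_equal(enc[1, ], enc[2, ])
  expect_equal(unname(unclass(blosum_encode("A", sm))[1, ]),
               unname(sm["A", ]))
  # U behaves as C, O as K
  expect_equal(unclass(blosum_encode("U", sm))[1, ],
               unclass(blosum_encode("C", sm))[1, ])
  expect_equal(unclass(blosum_encode("O", sm))[1, ],
               unclass(blosum_encode("K", sm))[1, ])
  # identical residues encode identically regardless of position/context
  e <- blosum_encode("AWA", sm)
  expect_equal(e[1, ], e[3, ])
})

test_that("profile features round-trip through TSV with checks", {
  fx <- small_fixtures()
  ids <- fx$records$id[1:3]
  profs <- lapply(ids, function(id) generate_profile_fixture(fx, id, seed = 2))
  names(profs) <- ids
  f <- tempfile(fileext = ".tsv")
  write_profile_features(profs, f)
  rec3 <- fx$records[fx$records$id %in% ids, ]
  back <- read_profile_features(f, rec3)
  for (id in ids) {
    expect_equal(unclass(back[[id]])[, ], unclass(profs[[id]])[, ],
                 tolerance = 1e-9)
    # one-hot block equals the one-hot encoder of the sequence
    expect_equal(unclass(back[[id]])[, 1:20],
                 unclass(one_hot_encode(
                   rec3$sequence[rec3$id == id]))[, 1:20],
                 tolerance = 1e-9)
  }
  # missing record
  rec4 <- protein_records("ghost", "ACDEF")
  expect_error(read_profile_features(f, rec4), "no profile features")
  # length mismatch
  rec5 <- protein_records(ids[1], "ACD")
  expect_error(read_profile_features(f, rec5), "does not match")
})

test_that("3-mer skip-gram vectors are context-free and deterministic", {
  polyA <- protein_records("p", strrep("A", 30))
  km <- train_kmer_skipgram(polyA, epochs = 1, seed = 1)
  expect_equal(km$vocab, "AAA")

  fx <- small_fixtures()
  km2 <- train_kmer_skipgram(fx$records[1:15, ], epochs = 1, seed = 5)
  km2b <- train_kmer_skipgram(fx$records[1:15, ], epochs = 1, seed = 5)
  expect_identical(km2$vectors, km2b$vectors)
  expect_equal(ncol(km2$vectors), 100L)

  # residue-level: the same 3-mer gets the same vector wherever it occurs
  s <- "AAACDEAAAC"
  enc <- kmer_encode(s, km2, "residue")
  expect_equal(dim(enc), c(10L, 100L))
  # centered 3-mers at positions 2 and 8 are both AAA
  expect_equal(enc[2, ], enc[8, ])
  # edge replication: residue 1 shares the first 3-mer, residue L the last
  expect_equal(enc[1, ], enc[2, ])
  expect_equal(enc[10, ], enc[9, ])
  # per-3-mer lookup oracle
  km3 <- substring(s, 1:8, 3:10)
  manual <- do.call(rbind, lapply(km3[c(1, 1:8, 8)], function(k) {
    kmer_vector(km2, k)
  }))
  expect_equal(unname(unclass(enc)[, ]), unname(manual))

  # protein level: mean of overlapping 3-mer vectors
  expect_equal(kmer_encode("AAAA", km2, "protein"), kmer_vector(km2, "AAA"))
  # unseen 3-mer maps to the zero vector
  all3 <- apply(expand.grid("X", c("X", "W"), c("X", "W")), 1, paste,
                collapse = "")
  unseen <- setdiff(all3, km2$vocab)[1]
  expect_equal(kmer_vector(km2, unseen), numeric(100))
  expect_error(kmer_encode("AC", km2), "shorter")

  # length-3 sequence: one 3-mer shared by all three residues
  e3 <- kmer_encode(substr(fx$records$sequence[1], 1, 3), km2)
  expect_equal(e3[1, ], e3[2, ])
  expect_equal(e3[2, ], e3[3, ])
})

test_that("co-occurring 3-mers end up closer than non-co-occurring ones", {
  # two disjoint residue dialects: 3-mers of the same dialect co-occur in
  # the training windows, 3-mers of different dialects never do
  set.seed(55)
  set_a <- c("A", "L", "E", "K"); set_b <- c("V", "I", "F", "T")
  seqs <- vapply(1:60, function(i) {
    paste(sample(if (i %% 2 == 0) set_a else set_b, 60, TRUE),
          collapse = "")
  }, "")
  rec <- protein_records(sprintf("d%02d", 1:60), seqs)
  km <- train_kmer_skipgram(rec, epochs = 3, seed = 6)
  dialect <- vapply(km$vocab, function(k) {
    all(strsplit(k, "")[[1]] %in% set_a)
  }, logical(1))
  cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  n <- length(km$vocab)
  sims_co <- c(); sims_no <- c()
  set.seed(7)
  pairs <- cbind(sample(n, 400, TRUE), sample(n, 400, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    s <- cos_sim(km$vectors[i, ], km$vectors[j, ])
    if (dialect[i] == dialect[j]) sims_co <- c(sims_co, s)
    else sims_no <- c(sims_no, s)
  }
  expect_gt(mean(sims_co), mean(sims_no))
})

test_that("feature concatenation stacks channels in order", {
  fx <- small_fixtures()
  id <- fx$records$id[1]
  s <- fx$records$sequence[1]
  prof <- generate_profile_fixture(fx, id, seed = 3)
  fake_emb <- feature_matrix(matrix(rnorm(nchar(s) * 1024), nchar(s), 1024),
                             id = id, scheme = "seqvec")
  both <- concat_features(prof, fake_emb)
  expect_equal(ncol(both), 1074L)
  expect_equal(attr(both, "scheme"), "profile50+seqvec")
  expect_equal(unclass(both)[, 1:50], unclass(prof)[, ])
  expect_equal(unclass(both)[, 51:1074], unclass(fake_emb)[, ])
  # associativity of channel order over three blocks
  oh <- one_hot_encode(s, id)
  abc1 <- concat_features(concat_features(oh, prof), fake_emb)
  abc2 <- concat_features(oh, concat_features(prof, fake_emb))
  expect_equal(unclass(abc1)[, ], unclass(abc2)[, ])
  # errors
  short <- feature_matrix(matrix(0, 2, 3), id = id, scheme = "toy")
  expect_error(concat_features(prof, short), "length mismatch")
  other <- one_hot_encode("ACDEF", "different")
  expect_error(concat_features(prof, other), "id mismatch|length mismatch")
})

test_that("the scheme/channel table is enforced", {
  expect_error(feature_matrix(matrix(0, 3, 19), "x", "onehot20"),
               "requires 20")
  expect_error(feature_matrix(matrix(0, 3, 24), "x", "blosum23"),
               "requires 23")
  expect_silent(feature_matrix(matrix(0, 3, 50), "x", "profile50"))
  expect_silent(feature_matrix(matrix(0, 3, 100), "x", "kmer100"))
})
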