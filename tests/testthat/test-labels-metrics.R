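test_that("the eight-to-three state reduction follows the convention", {
  expect_equal(map_dssp8_to_3(c("G", "H", "I")), c("H", "H", "H"))
  expect_equal(map_dssp8_to_3(c("B", "E")), c("E", "E"))
  expect_equal(map_dssp8_to_3(c("T", "S", "C", "-")), rep("O", 4))
  expect_error(map_dssp8_to_3("Q"), "eight-state")
  # total on the 8+1 alphabet, and H/E/O are fixed points through SS3
  all8 <- c("H", "G", "I", "E", "B", "T", "S", "C", "-")
  three <- map_dssp8_to_3(all8)
  expect_true(all(three %in% c("H", "E", "O")))
  expect_equal(map_dssp8_to_3_string("GHIBETSC"), "HHHEEOOO")
})

test_that("disorder labels are the negation of coordinate presence", {
  expect_equal(disorder_from_coordinates(rep(TRUE, 5)), rep(0L, 5))
  m <- c(rep(FALSE, 5), rep(TRUE, 3))
  expect_equal(disorder_from_coordinates(m), c(rep(1L, 5), rep(0L, 3)))
  set.seed(1)
  for (i in 1:20) {
    mask <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    expect_equal(disorder_from_coordinates(mask), as.integer(!mask))
  }
})

test_that("Q accuracy macro-averages over proteins", {
  expect_equal(q_accuracy(list(c("H", "H")), list(c("H", "H")))$value, 100)
  # 50% and 100% -> 75 (macro, not residue-pooled)
  expect_equal(
    q_accuracy(list(c("H", "E"), c("H", "H", "H", "H")),
               list(c("H", "H"), c("H", "H", "H", "H")))$value, 75)
  # per-protein ("items") aggregation
  expect_equal(q_accuracy(c("a", "b", "c", "d"), c("a", "b", "x", "d"),
                          aggregation = "items")$value, 75)

  set.seed(5)
  classes <- c("H", "E", "O")
  for (i in 1:20) {
    truth <- vapply(1:8, function(j) {
      paste(sample(classes, sample(5:30, 1), TRUE), collapse = "")
    }, "")
    pred <- vapply(truth, function(t) {
      ch <- strsplit(t, "")[[1]]
      flip <- runif(length(ch)) < 0.3
      ch[flip] <- sample(classes, sum(flip), TRUE)
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
    expect_equal(q_accuracy(pred, truth)$value,
                 oracle_macro_accuracy(pred, truth))
  }
})

test_that("binary MCC and FPR follow the contingency formula", {
  perfect <- binary_mcc_and_fpr(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(binary_mcc_and_fpr(c(0, 0, 1, 1), c(1, 1, 0, 0))$mcc, -1)
  # (TP,FP,TN,FN) = (4,1,3,2)
  pred <- c(rep(1, 4), 1, rep(0, 3), 0, 0)
  truth <- c(rep(1, 4), 0, rep(0, 3), 1, 1)
  r <- binary_mcc_and_fpr(pred, truth)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(4, 1, 3, 2))
  expect_equal(r$mcc, oracle_mcc(4, 1, 3, 2))
  expect_equal(r$fpr, 1 / 4)
  # degenerate marginal -> 0 with flag
  d <- binary_mcc_and_fpr(c(1, 1, 1), c(1, 1, 0))
  expect_true(d$degenerate)
  expect_equal(d$mcc, 0)
})

test_that("Gorodkin RK reduces to binary MCC on 2x2 tables", {
  expect_equal(gorodkin_mcc(diag(c(10, 20, 5)))$rk, 1)
  set.seed(11)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, 6), 2, 2)
    tp <- tab[2, 2]; tn <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]
    rk <- gorodkin_mcc(tab)
    denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (denom == 0) {
      expect_true(rk$degenerate)
    } else {
      expect_equal(rk$rk, oracle_mcc(tp, fp, tn, fn), tolerance = 1e-12)
    }
  }
})

test_that("RK vanishes for independent predictions", {
  set.seed(21)
  n <- 1e5
  truth <- sample(1:10, n, replace = TRUE)
  pred <- sample(1:10, n, replace = TRUE)
  cm <- confusion_matrix(pred, truth, classes = 1:10)
  expect_lt(abs(gorodkin_mcc(cm)$rk), 0.01)
})

test_that("confusion-matrix marginals conserve the label counts", {
  set.seed(2)
  truth <- sample(letters[1:4], 200, replace = TRUE)
  pred <- sample(letters[1:4], 200, replace = TRUE)
  cm <- confusion_matrix(pred, truth, classes = letters[1:4])
  expect_equal(sum(cm), 200L)
  expect_equal(unname(rowSums(cm)),
               unname(table(factor(truth, letters[1:4]))[letters[1:4]]),
               ignore_attr = TRUE)
  expect_equal(unname(colSums(cm)),
               unname(table(factor(pred, letters[1:4]))[letters[1:4]]),
               ignore_attr = TRUE)
  expect_error(confusion_matrix("z", "a", classes = c("a", "b")), "outside")
})

test_that("bootstrap standard errors match closed forms", {
  expect_equal(bootstrap_se(rep(42, 10), seed = 1), 0)
  # two-point scores {0, 100}: SE of the resample mean = 100*sqrt(1/8)
  se <- bootstrap_se(c(0, 100), n_boot = 20000L, seed = 3)
  expect_equal(se, 100 * sqrt(0.125), tolerance = 0.02)
  expect_identical(bootstrap_se(c(3, 1, 4, 1, 5), seed = 9),
                   bootstrap_se(c(3, 1, 4, 1, 5), seed = 9))
  expect_error(bootstrap_se(1), "at least 2")
})

test_that("disorder MCC excludes single-class proteins from the macro mean", {
  pred <- list(c(1, 0, 1), c(0, 0, 0), c(1, 1, 0))
  truth <- list(c(1, 0, 1), c(0, 0, 0), c(1, 0, 0))
  r <- disorder_mcc(pred, truth)
  expect_equal(r$n_excluded, 1L)  # second protein has one true class
  expect_length(r$per_protein, 2L)
  expect_equal(r$per_protein[1], 1)
  expect_equal(r$pooled,
               binary_mcc_and_fpr(unlist(pred), unlist(truth))$mcc)
})
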