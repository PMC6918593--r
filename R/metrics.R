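# Evaluation suite: Q accuracies, binary Matthews correlation and false
# positive rate, the Gorodkin multiclass correlation (RK), confusion
# matrices, and bootstrap standard errors.

#' Per-residue / per-protein Q accuracy
#'
#' For per-residue tasks (\code{aggregation = "macro"}), computes each
#' protein's percentage of correctly predicted valid residues and returns
#' the unweighted mean over proteins, following the convention that all
#' reported numbers are averages over proteins. Proteins without any valid
#' residue are excluded and counted. For per-protein tasks
#' (\code{aggregation = "items"}), each element of \code{pred}/\code{truth}
#' is one protein and the value is the overall fraction correct, in percent.
#'
#' @param pred,truth For \code{"macro"}: lists (or character vectors of
#'   label strings) of equal-length per-protein label sequences. For
#'   \code{"items"}: atomic vectors, one label per protein.
#' @param valid Optional list of logical vectors flagging scorable residues
#'   (default: all valid). Ignored for \code{"items"}.
#' @param aggregation \code{"macro"} or \code{"items"}.
#' @return List with \code{value} (percentage), \code{per_protein}
#'   (per-protein percentages, macro mode), and \code{n_excluded}.
#' @export
q_accuracy <- function(pred, truth, valid = NULL,
                       aggregation = c("macro", "items")) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "items") {
    stopifnot(length(pred) == length(truth), length(pred) > 0L)
    return(list(value = 100 * mean(pred == truth),
                per_protein = NULL, n_excluded = 0L))
  }
  pred <- .as_label_list(pred); truth <- .as_label_list(truth)
  stopifnot(length(pred) == length(truth))
  scores <- numeric(0); excluded <- 0L
  for (i in seq_along(pred)) {
    p <- pred[[i]]; t <- truth[[i]]
    if (length(p) != length(t)) stop("length mismatch in protein ", i)
    v <- if (is.null(valid)) rep(TRUE, length(t)) else valid[[i]]
    if (!any(v)) { excluded <- excluded + 1L; next }
    scores <- c(scores, 100 * mean(p[v] == t[v]))
  }
  if (length(scores) == 0L) stop("no scorable proteins")
  list(value = mean(scores), per_protein = scores, n_excluded = excluded)
}

.as_label_list <- function(x) {
  if (is.list(x)) return(x)
  lapply(x, function(s) strsplit(s, "")[[1]])
}

#' Binary Matthews correlation coefficient and false-positive rate
#'
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0
#' (with \code{degenerate = TRUE}) when any marginal is zero.
#' FPR = FP / (FP + TN).
#'
#' @param pred,truth Vectors coercible to 0/1 integers (1 = positive).
#' @return List with \code{mcc}, \code{fpr}, \code{degenerate} and the
#'   contingency counts.
#' @export
binary_mcc_and_fpr <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) > 0L)
  p <- as.integer(pred); t <- as.integer(truth)
  stopifnot(all(p %in% 0:1), all(t %in% 0:1))
  tp <- sum(p == 1 & t == 1); tn <- sum(p == 0 & t == 0)
  fp <- sum(p == 1 & t == 0); fn <- sum(p == 0 & t == 1)
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- denom2 == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  fpr <- if ((fp + tn) == 0) NA_real_ else fp / (fp + tn)
  list(mcc = mcc, fpr = fpr, degenerate = degenerate,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Build a K x K confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the order of
#' \code{classes}.
#'
#' @param pred,truth Vectors of class labels.
#' @param classes Class-name vector fixing the order.
#' @return Integer matrix with dimnames \code{list(truth, pred)}.
#' @export
confusion_matrix <- function(pred, truth,
                             classes = sort(unique(c(pred, truth)))) {
  stopifnot(length(pred) == length(truth))
  p <- factor(pred, levels = classes); t <- factor(truth, levels = classes)
  if (anyNA(p) || anyNA(t)) stop("labels outside the declared class set")
  m <- table(truth = t, pred = p)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(truth = classes, pred = classes))
}

#' Gorodkin multiclass correlation (RK) from a confusion matrix
#'
#' The K-category generalization of the Matthews correlation: the covariance
#' between the true and predicted indicator variables normalized by the
#' geometric mean of their variances, computed from the confusion-matrix
#' counts. Returns 0 with \code{degenerate = TRUE} when either variance
#' vanishes (all items in one true or one predicted class).
#'
#' @param cm K x K matrix of counts (rows truth, columns prediction).
#' @return List with \code{rk} and \code{degenerate}.
#' @export
gorodkin_mcc <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  cm <- cm / n  # work with proportions for numerical stability
  t_marg <- rowSums(cm)   # truth marginal
  p_marg <- colSums(cm)   # prediction marginal
  cov_tp <- sum(diag(cm)) - sum(t_marg * p_marg)
  var_t <- 1 - sum(t_marg^2)
  var_p <- 1 - sum(p_marg^2)
  if (var_t <= 0 || var_p <= 0) {
    return(list(rk = 0, degenerate = TRUE))
  }
  list(rk = cov_tp / sqrt(var_t * var_p), degenerate = FALSE)
}

#' Bootstrap standard error of a metric
#'
#' Draws \code{n_boot} resamples of the items with replacement (each of the
#' original size), recomputes the metric on each, and returns the standard
#' deviation across resamples. For per-residue tasks pass the per-protein
#' score distribution as \code{items} with \code{metric = mean}.
#'
#' @param items Vector or list of per-item values (>= 2 items).
#' @param metric Function mapping a resampled item set to a number
#'   (default \code{mean}).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Standard error (numeric scalar).
#' @export
bootstrap_se <- function(items, metric = mean, n_boot = 1000L, seed = 1L) {
  n <- if (is.list(items)) length(items) else length(items)
  if (n < 2L) stop("need at least 2 items for a bootstrap")
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(n_boot), function(b) {
    take <- sample.int(n, n, replace = TRUE)
    metric(if (is.list(items)) items[take] else items[take])
  }, numeric(1))
  stats::sd(vals)
}

#' Macro-averaged per-protein disorder MCC
#'
#' Computes the binary MCC per protein and macro-averages, excluding
#' proteins whose true labels contain a single class (MCC undefined);
#' the number excluded is reported.
#'
#' @param pred,truth Lists of per-protein 0/1 vectors.
#' @param pooled If TRUE, additionally return the MCC pooled over all
#'   residues of all proteins.
#' @return List with \code{mcc} (macro), \code{per_protein},
#'   \code{n_excluded}, and optionally \code{pooled}.
#' @export
disorder_mcc <- function(pred, truth, pooled = TRUE) {
  stopifnot(length(pred) == length(truth))
  scores <- numeric(0); excluded <- 0L
  for (i in seq_along(pred)) {
    t <- as.integer(truth[[i]])
    if (length(unique(t)) < 2L) { excluded <- excluded + 1L; next }
    scores <- c(scores, binary_mcc_and_fpr(pred[[i]], t)$mcc)
  }
  out <- list(mcc = if (length(scores)) mean(scores) else NA_real_,
              per_protein = scores, n_excluded = excluded)
  if (pooled) {
    out$pooled <- binary_mcc_and_fpr(unlist(pred), unlist(truth))$mcc
  }
  out
}
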